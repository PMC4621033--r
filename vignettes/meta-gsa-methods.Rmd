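---
title: "Concordance-weighted meta-analysis of gene-set analyses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance-weighted meta-analysis of gene-set analyses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagsa)
```

## The problem

Gene-set analysis (GSA) asks whether a predefined set of genes *GS* is
enriched with marker-phenotype association signal relative to the
remaining genes *GS'* (competitive testing) or relative to a
non-associated background (self-contained testing). A GSA returns a
one-sided p-value $p_{GS,s}$ per study $s$ and, as a rule, no effect
estimate. When several GWAS-based studies have each run a GSA on the same
gene set, the obvious way to combine them is Fisher's inverse
$\chi^2$-method on the $p_{GS,s}$ ("simple p-pooling", SPP):
$M = -2\sum_s \ln p_{GS,s} \sim \chi^2_{2 n_s}$ under the null.

SPP, however, only measures *accumulated marker significance*. Two studies
can both report a small $p_{GS,s}$ while disagreeing completely about
*which* genes drive the enrichment and in *which direction* the risk
alleles act. Pooling such p-values overstates the replication of a
finding. The method implemented here weights each study by the concordance
of its gene-level *association pattern* with the pattern common to all
studies, and tests

$$M_{n_s} = -2 \sum_{s=1}^{n_s} w_s \ln p_{GS,s}$$

against a permutation null, so that significance requires both
accumulated significance and a concordant pattern.

## Step I: directed reversed p-values (PDRs)

Marker-level results $(\theta_{m,s}, p_{m,s})$ are first aggregated to a
gene level $(p_{g,s}, d_{g,s})$ with $d$ the direction of association.
Three aggregation strategies are provided (`aggregation` argument):

* **best** -- the gene's most significant marker represents it:
  $p_{g,s}=\min_m p_{m|g,s}$. When studies select different
  representative markers, the direction is the sign of
  $\hat\theta$ times the mean signed allele correlation $r$ between this
  study's representative and every other study's representative. A
  representative in linkage equilibrium with all other choices carries no
  transferable direction: $d_{g,s}=0$ and the gene contributes nothing in
  that study, however significant. A missing cross-study LD entry is an
  error rather than an implicit $r=0$, because $r=0$ silently annihilates
  the gene.
* **all** -- the weighted Fisher sum
  $C_{g,s}=-2\sum_m v_m \ln p_{m|g,s}$ over all markers of the gene, with
  LD-block weights $v_m = 1/\sum_{m'\in\mathrm{block}(m)} r^2_{m',m}$ so
  that a block of redundant markers counts once and $\sum_m v_m$ is the
  number of independent markers. The reference distribution is
  $\chi^2$ with $2\sum v$ degrees of freedom by default (the analogy with
  unweighted Fisher, where $n$ unit-weight markers give $2n$ df); a
  strict $\sum v$ mode is available (`df_mode = "independent"`).
  The direction is the $v$-weighted mean of the marker signs, normalised
  by $\sum v$ so it stays in $[-1,1]$ -- without this normalisation the
  PDR below could leave its $[-1,1]$ scale.
* **promising** -- the same restricted to markers with $p<0.05$; a gene
  whose markers are all filtered out is assigned $p=1$, $d=0$ and
  flagged.

LD blocks are formed by greedy single-linkage clustering at
$r^2 \ge 0.5$ within a gene (configurable; blocks never span genes). The
threshold is the conventional "strong LD" midpoint; results are
insensitive to it when markers are either tightly linked or essentially
independent, which is the typical genotyping-array situation.

Directions are then *re-oriented*: for each gene the mean direction
across studies defines a reference, and genes with a negative mean have
all their per-study directions negated. A mean of exactly zero leaves the
gene unchanged -- a deterministic, direction-unbiased tie rule. The
operation is idempotent. Finally each gene in each study is condensed to
a *directed reversed p-value*

$$p'_{g,s} = d_{g,s}\,(1 - p_{g,s}) \in [-1, 1],$$

zero meaning no evidence and $\pm 1$ strong evidence for/against the
reference direction. The PDRs of the gene-set members form the
genes-by-studies *PDR profile matrix*.

## Step II: concordance and study weights

Because PDRs may be scaled differently between studies (sample size,
model, stratification), concordance is measured on ranks: all pairwise
Kendall correlations $\tau_{s,s'}$ between study PDR profiles (tie-aware
$\tau_b$; ties occur whenever a PDR is exactly zero). Pearson and
Spearman are available as alternatives, but rank-based $\tau$ is the
default. A constant profile carries no rank information and correlates 0
by convention (with a warning).

The loading of each study on the common -- hidden -- association pattern
is taken from the first principal component of the $\tau$ matrix. With
$EV_1$ the largest eigenvalue, $EV_1/n_s$ is the fraction of profile
variance explained by $PC1$, interpreted as the *effective number of
studies*: 1 under total concordance, small when the studies do not agree.
The weight of study $s$ is its normalised loading scaled by the effective
number of studies:

$$w_s = \frac{PC1_s}{\sum_j |PC1_j|}\cdot\frac{EV_1}{n_s}.$$

Whenever the loadings share one sign -- every concordant collection of
studies -- the denominator equals the plain loading sum, the weights sum
to exactly $EV_1/n_s$, and perfect concordance gives $w_s = 1/n_s$. A
study whose pattern opposes the consensus keeps a negative weight, so its
small $p_{GS,s}$ counts *against* pooled significance; $M_{n_s}$ can
therefore be negative, which is one reason no $\chi^2$ reference applies.

The absolute-value denominator is a deliberate regularisation. Normalising
by the signed sum $\sum_j PC1_j$ is algebraically natural but degenerate:
for discordance-dominated matrices the loading sum passes through zero
and the weights diverge. Two anti-correlated studies have
$PC1 = (1,-1)/\sqrt2$ exactly -- a division by zero -- and, more
damagingly, the *permutation null* below repeatedly evaluates the weight
rule on randomly composed gene sets whose $\tau$ matrices are pure noise,
where near-cancelling loadings are routine. Under the signed rule a
substantial fraction of null statistics explodes, the null upper tail is
corrupted, and the test loses its power monotonically *increasing* in
effect size. The absolute-sum rule is identical in every concordant
configuration, bounds every weight by $EV_1/n_s$, and leaves the
permutation test exact. The strict signed rule remains available
(`pca_weights(cm, normalization = "signed")`) for study.

The eigenvector sign is fixed so the loading sum is non-negative; the
weights are invariant under that flip in the concordant case and the
convention simply orients the majority positively otherwise.

## Step III: permutation significance

The observed statistic is $M_0 = -2\sum_s w_s \ln p_{GS,s}$ with the
observed GSA p-values and the observed concordance weights. Because the
weights are data-dependent, may be negative, and do not sum to one, the
$\chi^2$ theory for pre-specified weights does not apply; the null
distribution is generated by permutation. Each permutation draws
`gs_size` genes at random from the whole gene universe ($GS \cup GS'$),
recomputes the Kendall matrix and the PCA weights on that random set, and
draws fresh $p_{GS,s} \sim U(0,1)$; the resulting $M_j$ jointly embody
"no concordance beyond chance and no accumulated significance". The
p-value is the add-one estimator

$$p_{permut} = \frac{\#\{M_j \ge M_0\} + 1}{x + 1},$$

never exactly zero and uniform on its grid under the null (verified by
simulation in the test-suite). The permutation loop is implemented in
C++ (Rcpp/RcppArmadillo) with R's own RNG, so results are reproducible
from a single seed; a pure-R reference implementation is kept for
cross-checking.

Observed $p_{GS,s} = 0$ (some GSA tools truncate) would make $M_0$
infinite; inputs are clamped at $1/(2x)$, half the resolution of the
permutation grid, before taking logs.

An optional sequential stopping rule abandons hopeless gene sets in
collection-wide scans: after at least 200 permutations, stop once the
99% confidence interval of the running estimate lies entirely above
0.25. Early-stopped p-values are imprecise upward and the rule is off by
default; it is a screening device, not part of the test.

## Step IV: multiplicity

Gene sets overlap and genes are correlated, so across many sets a plain
Bonferroni correction overcorrects. The proportion of true null sets
$\pi_0$ is estimated from the collection of permutation p-values by the
bootstrap variant of the Storey-Tibshirani estimator
($\hat\pi_0(\lambda)$ over $\lambda = 0.05, \dots, 0.95$ in steps of
0.05, 100 bootstrap draws, $\lambda$ chosen to minimise the estimated
MSE around the minimum, estimate clipped to $(0,1]$ with lower bound
$1/m$), and the corrected p-value is

$$p_{meta} = \min(1,\; p_{permut}\cdot n_{GS}\cdot \pi_0).$$

With a single gene set no correction is applied ($\pi_0 = 1$,
$n_{GS} = 1$).

## Comparator methods

For the power study three comparators are implemented. The per-study GSA
is a one-sided Wilcoxon rank-sum test for enrichment of low marker
p-values in the gene set -- exact when the smaller group has at most 8
observations and no ties, otherwise the normal approximation with tie and
continuity correction. SPP is the unweighted Fisher combination of these
per-study GSA p-values. pooledGWAS-GSA switches the pooling to the marker
level: a DerSimonian-Laird random-effects meta-analysis per marker
(method-of-moments $\tau^2$ from Cochran's Q, inverse-variance weights
$1/(se^2+\tau^2)$, two-sided Wald p), then a single Wilcoxon GSA on the
pooled p-values. The DL step is written as a vectorised closed form for
speed across thousands of markers and replicates; it is cross-checked
against `metafor::rma(method = "DL")` in the test-suite.

## The simulator

`run_scenario()` emulates a multi-study case-control GWAS landscape: 100
genes with one diallelic marker each, a gene set of 10, per-study samples
of 500 cases and 500 controls, minor-allele frequency 0.30 for every
marker, population prevalence 5%, genotypes in Hardy-Weinberg
equilibrium, penetrances scaled so the prevalence constraint holds
exactly. Marker association is tested with the two-sided Cochran-Armitage
trend test; the direction is the sign of the per-allele log odds ratio
from the allele-dosage table (Haldane-Anscombe correction on zero cells),
with $d=+1$ when $OR \ge 1$. Markers deviating from HWE in controls at
$p < 10^{-7}$ (1-df goodness-of-fit $\chi^2$) are excluded; a marker is
kept only if it survives in every study, so PDR profiles stay complete.

Two generator choices deserve explanation:

* **Penetrance model.** The default is recessive,
  $f = f_0\,(1, 1, rr)$. Under the per-allele multiplicative model a
  nominal $rr = 1.5$ at this design yields a mean trend statistic around
  $z \approx 4.6$ -- essentially every associated marker is
  genome-wide-obvious in every single study, all pooling methods saturate
  at 100% power, and there is nothing left for a meta-analytic method to
  demonstrate. The recessive model places the same nominal relative
  risks in the moderate-evidence regime ($z \approx 3\,(rr-1)$, per-study
  marker power 6%-31% across $rr = 1.1$-$1.5$) where the accumulation of
  weak but concordant signals across studies -- the situation the method
  exists for -- actually occurs. The multiplicative model remains
  available (`model = "multiplicative"`).
* **Direction randomisation.** Which allele carries the risk is drawn
  once per marker per replicate and shared by all studies: the true
  direction of an association is a property of the marker, not of the
  study sampling. The draw flips the genotype coding, so every marker
  keeps MAF 0.30. A per-study independent flip is available
  (`share_directions = FALSE`) as a stress case; it leaves rank-based
  per-study methods untouched but destroys cross-study pooling of effect
  estimates, since the pooled log odds ratio of a truly associated
  marker then centres on zero.

The simulator does *not* emulate: LD between the simulated markers (each
gene has one marker; multi-marker aggregation is exercised through unit
tests with synthetic LD tables), covariates, population stratification,
imputation uncertainty, or realistic gene-set overlap. Passing the
simulation suite therefore shows the method's operating characteristics
under idealised sampling noise, not robustness to the confounding
structure of real consortium data.

The 20 scenarios of `scenario_registry()` span the null (identical
relative-risk composition in set and complement), increasing effect sizes
and study counts with signal confined to the set, and mixed compositions
where the complement itself carries signal -- including the adversarial
case of a set *dominated* by its complement, where a competitive
strategy should (and does) lose its power entirely.

## Numerical choices and problem sizes

* Permutations: 999 per replicate in simulations and the acceptance
  script (resolution 0.001 at the add-one estimator, ample at
  $\alpha=0.05$); 9999 by default for a single user-run gene set.
* Simulation size: 500 replicates per scenario in the acceptance script
  (binomial SE at most 2.3 points); 150-500 in the test-suite blocks,
  with tolerance bands widened to the corresponding binomial error.
* Test-suite property checks use scaled-down universes (30 genes, 3-4
  studies, 199 permutations, 2000 replicates for the uniformity KS
  check).
* Ties: equal minimum p-values within a gene resolve to the
  lexicographically smallest marker id; a re-orientation mean of exactly
  zero leaves the gene unchanged; an exact $OR = 1$ takes $d = +1$.
* All randomness flows from one seed; runs are serial, so results do not
  depend on worker count.

## Known limitations

* The permutation null is CPU-bound; genome-wide collections (hundreds of
  sets) multiply its cost linearly. The early-stopping screen trades
  precision on clearly non-significant sets for speed.
* The method returns p-values only -- no pooled effect estimate exists at
  the gene-set level.
* With two studies the concordance matrix has a single off-diagonal
  entry, and the weights carry little information beyond its sign;
  power with $n_s = 2$ is accordingly modest.
* When loadings are mixed-sign the weight-sum identity
  $\sum w_s = EV_1/n_s$ holds for the signed normalisation only in the
  limit of concordant loadings; the shipped rule trades the identity in
  that (pathological) regime for a well-behaved null.
* All inherited GSA biases (gene length, set size, annotation quality)
  pass through: the method pools GSA results, it does not repair them.
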