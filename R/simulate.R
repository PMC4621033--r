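#' Define a simulation scenario
#'
#' A scenario describes the "pattern of true marker-phenotype association"
#' for a case-control GWAS simulation: per-gene relative risks inside the
#' gene set of interest (GS) and in the complementary set (GS'), the number
#' of studies to combine, and the sampling design. Each gene carries exactly
#' one genotyped diallelic marker.
#'
#' @param n_studies number of independent studies to simulate.
#' @param rr_gs numeric vector of relative risks, one per GS gene (all
#'   >= 1; which allele carries the risk is randomised separately).
#' @param rr_comp relative risks for the complementary genes.
#' @param maf minor-allele frequency shared by all markers.
#' @param prevalence population prevalence of the binary phenotype.
#' @param n_cases,n_controls per-study sample sizes.
#' @param model penetrance model, see [genotype_distribution()].
#' @return an object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(10, rr_gs = c(rep(1, 5), rep(1.5, 5)), rr_comp = rep(1, 90))
#' @export
scenario_spec <- function(n_studies, rr_gs, rr_comp,
                          maf = 0.30, prevalence = 0.05,
                          n_cases = 500, n_controls = 500,
                          model = c("recessive", "multiplicative")) {
  model <- match.arg(model)
  stopifnot(n_studies >= 1, length(rr_gs) >= 1, length(rr_comp) >= 0,
            n_cases >= 1, n_controls >= 1)
  if (any(c(rr_gs, rr_comp) < 1))
    stop("all relative risks must be >= 1; direction is randomised separately")
  if (maf <= 0 || maf >= 0.5) stop("maf must lie in (0, 0.5)")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  structure(list(n_studies = as.integer(n_studies),
                 rr_gs = as.numeric(rr_gs), rr_comp = as.numeric(rr_comp),
                 maf = maf, prevalence = prevalence,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), model = model),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  fmt <- function(rr) paste(sprintf("%dx%g", as.vector(table(rr)),
                                    as.numeric(names(table(rr)))),
                            collapse = " ")
  cat("GWAS simulation scenario\n",
      "  studies:    ", x$n_studies, "\n",
      "  GS RRs:     ", fmt(x$rr_gs), "\n",
      "  GS' RRs:    ", fmt(x$rr_comp), "\n",
      "  design:     ", x$n_cases, "cases /", x$n_controls, "controls,",
      "MAF", x$maf, ", prevalence", x$prevalence, ",", x$model, "model\n")
  invisible(x)
}

#' Case and control genotype distributions under a penetrance model
#'
#' Genotypes (0/1/2 copies of the risk allele) are in Hardy-Weinberg
#' proportions \eqn{P_j} in the population. Penetrances are
#' \eqn{f_j = f_0\,r_j} with the relative-risk pattern \eqn{r_j} set by
#' the model -- `"recessive"` (the default used throughout the power
#' study): \eqn{r = (1, 1, \mathrm{rr})}; `"multiplicative"` (per-allele,
#' log-additive): \eqn{r = (1, \mathrm{rr}, \mathrm{rr}^2)} -- and the
#' baseline \eqn{f_0} solved from the prevalence constraint
#' \eqn{\sum_j f_j P_j = K}. Case genotype probabilities are then
#' \eqn{f_j P_j / K} and control probabilities \eqn{(1-f_j) P_j / (1-K)}.
#'
#' The recessive default calibrates the simulated marker-level association
#' signal to the moderate per-study evidence regime the power study
#' targets (per-allele effects of the same nominal RR are detected almost
#' surely at 500 cases / 500 controls, which leaves nothing for pooling
#' methods to disagree about); see the methods vignette.
#'
#' @param maf frequency of the risk allele (taken as the minor allele).
#' @param rr relative risk (>= 1) of the model's risk genotype class.
#' @param prevalence population prevalence K.
#' @param model penetrance model, `"recessive"` or `"multiplicative"`.
#' @return list with components `case` and `control`, each a probability
#'   vector over genotypes 0/1/2 summing to one, plus the population
#'   frequencies `pop` and penetrances `penetrance`.
#' @examples
#' genotype_distribution(0.3, 1.5, 0.05)
#' genotype_distribution(0.3, 1.5, 0.05, model = "multiplicative")
#' @export
genotype_distribution <- function(maf, rr, prevalence,
                                  model = c("recessive", "multiplicative")) {
  model <- match.arg(model)
  stopifnot(maf > 0, maf < 0.5, rr >= 1, prevalence > 0, prevalence < 1)
  pj <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  rj <- switch(model, recessive = c(1, 1, rr), multiplicative = rr^(0:2))
  f0 <- prevalence / sum(pj * rj)
  f <- f0 * rj
  if (any(f > 1))
    stop("invalid scenario: penetrance f0 * r_j exceeds 1")
  list(case = f * pj / prevalence,
       control = (1 - f) * pj / (1 - prevalence),
       pop = pj, penetrance = f)
}

#' Simulate genotype counts for one study
#'
#' Draws multinomial case/control genotype counts for every marker of a
#' scenario. For each marker the allele carrying the risk is chosen to be
#' the minor or the major allele with probability 1/2 (independently per
#' study and marker), so that association directions are random while the
#' MAF stays fixed. Genotypes are always reported as copies of the minor
#' allele.
#'
#' @param scenario a [scenario_spec()].
#' @param flip optional logical vector, one entry per marker: `TRUE` means
#'   the major allele carries the risk. The default draws it uniformly at
#'   random. Pass the same vector to every study of a replicate to model a
#'   true association direction that is a property of the marker (shared
#'   by all studies); draw it per study to model study-specific flips.
#' @return list with `cases` and `controls` (`n_markers x 3` count
#'   matrices, columns = 0/1/2 copies of the minor allele), `gene` and
#'   `marker` identifier vectors, `rr` the per-marker relative risks, and
#'   `gs` a logical flag marking GS genes.
#' @export
sample_study <- function(scenario, flip = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  rr <- c(scenario$rr_gs, scenario$rr_comp)
  n_m <- length(rr)
  if (is.null(flip)) flip <- runif(n_m) < 0.5
  stopifnot(is.logical(flip), length(flip) == n_m)
  cases <- matrix(0L, n_m, 3)
  controls <- matrix(0L, n_m, 3)
  # markers sharing (rr, flip) share genotype distributions: draw in groups
  for (r in unique(rr)) {
    gd <- genotype_distribution(scenario$maf, r, scenario$prevalence,
                                model = scenario$model)
    for (fl in c(FALSE, TRUE)) {
      idx <- which(rr == r & flip == fl)
      if (!length(idx)) next
      pc <- if (fl) rev(gd$case) else gd$case
      pk <- if (fl) rev(gd$control) else gd$control
      cases[idx, ] <- t(rmultinom(length(idx), scenario$n_cases, pc))
      controls[idx, ] <- t(rmultinom(length(idx), scenario$n_controls, pk))
    }
  }
  gene <- sprintf("g%03d", seq_len(n_m))
  list(cases = cases, controls = controls,
       gene = gene, marker = paste0(gene, "_m1"), rr = rr,
       gs = seq_len(n_m) <= length(scenario$rr_gs))
}

#' Cochran-Armitage trend test with a per-allele log odds ratio
#'
#' Two-sided Cochran-Armitage trend test with scores (0, 1, 2) on a
#' case/control genotype table, plus a per-allele log odds ratio computed
#' from the allele-dosage 2x2 table (Haldane-Anscombe 0.5 continuity
#' correction when any allele cell is zero) and the direction flag
#' d = +1 iff OR >= 1. Accepts a single pair of genotype count vectors or
#' matrices with one marker per row (vectorised).
#'
#' Monomorphic markers (a single genotype column in both arms) carry no
#' trend information: they get p = 1, theta = 0, d = +1 and are flagged.
#'
#' @param case_counts,control_counts genotype counts (0/1/2 copies of the
#'   coded allele); vectors of length 3 or `n x 3` matrices.
#' @return data.frame with columns `stat` (chi-square, 1 df), `p`, `theta`
#'   (log OR per coded allele), `se` (Woolf standard error), `d` (+1/-1)
#'   and `monomorphic`.
#' @examples
#' armitage_trend_test(c(40, 42, 18), c(49, 42, 9))
#' @export
armitage_trend_test <- function(case_counts, control_counts) {
  a <- if (is.matrix(case_counts)) case_counts else matrix(case_counts, 1)
  b <- if (is.matrix(control_counts)) control_counts else matrix(control_counts, 1)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b),
            all(a >= 0), all(b >= 0))
  x <- c(0, 1, 2)
  n <- a + b                      # genotype totals per marker
  R <- rowSums(a)                 # cases
  N <- rowSums(n)
  pbar <- R / N
  sx <- n %*% x                   # sum n_j x_j
  sxx <- n %*% x^2
  num <- (a %*% x) - pbar * sx    # sum x_j (a_j - R n_j / N)
  v <- pbar * (1 - pbar) * (sxx - sx^2 / N)
  mono <- rowSums((n > 0)) < 2
  stat <- ifelse(v > 0, num^2 / v, 0)
  p <- ifelse(mono | v <= 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  # allele-dosage 2x2: risk-coded allele counts in cases/controls
  a1 <- a[, 2] + 2 * a[, 3]; a0 <- 2 * R - a1
  b1 <- b[, 2] + 2 * b[, 3]; b0 <- 2 * rowSums(b) - b1
  cc <- (a1 == 0) | (a0 == 0) | (b1 == 0) | (b0 == 0)
  h <- ifelse(cc, 0.5, 0)
  theta <- log(((a1 + h) * (b0 + h)) / ((a0 + h) * (b1 + h)))
  se <- sqrt(1 / (a1 + h) + 1 / (a0 + h) + 1 / (b1 + h) + 1 / (b0 + h))
  theta[mono] <- 0
  se[mono] <- Inf
  d <- ifelse(theta >= 0, 1L, -1L)  # d = +1 iff OR >= 1
  data.frame(stat = as.vector(stat), p = as.vector(p), theta = theta,
             se = se, d = d, monomorphic = mono)
}

#' Hardy-Weinberg equilibrium filter for controls
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of HWE on control
#' genotype counts; markers with p below `threshold` are flagged for
#' exclusion. Monomorphic markers satisfy HWE trivially and are kept.
#'
#' @param control_counts length-3 vector or `n x 3` matrix of control
#'   genotype counts.
#' @param threshold exclusion threshold on the HWE p-value.
#' @return logical vector, `TRUE` = keep.
#' @export
hwe_filter <- function(control_counts, threshold = 1e-7) {
  b <- if (is.matrix(control_counts)) control_counts else matrix(control_counts, 1)
  stopifnot(ncol(b) == 3, all(b >= 0), threshold >= 0)
  n <- rowSums(b)
  q <- (b[, 2] + 2 * b[, 3]) / (2 * n)   # coded-allele frequency
  e <- cbind((1 - q)^2, 2 * q * (1 - q), q^2) * n
  mono <- q == 0 | q == 1
  stat <- rowSums(ifelse(e > 0, (b - e)^2 / e, 0))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  p >= threshold
}

#' Simulate one study and run the marker-level association scan
#'
#' Convenience wrapper chaining [sample_study()], [armitage_trend_test()]
#' and [hwe_filter()]: the per-study "GWAS step" of the power simulation.
#'
#' @param scenario a [scenario_spec()].
#' @param hwe_threshold HWE exclusion threshold on controls.
#' @param flip see [sample_study()].
#' @return data.frame with columns `marker`, `gene`, `gs`, `theta`, `se`,
#'   `p`, `d`, `keep` (HWE filter verdict).
#' @export
simulate_study <- function(scenario, hwe_threshold = 1e-7, flip = NULL) {
  g <- sample_study(scenario, flip = flip)
  res <- armitage_trend_test(g$cases, g$controls)
  keep <- hwe_filter(g$controls, hwe_threshold)
  data.frame(marker = g$marker, gene = g$gene, gs = g$gs,
             theta = res$theta, se = res$se, p = res$p, d = res$d,
             keep = keep)
}
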