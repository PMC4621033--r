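#' Weighted Fisher inverse chi-square statistic
#'
#' \deqn{M = -2 \sum_s w_s \ln p_{GS,s}.}
#' With pre-specified positive weights summing to one this would follow a
#' chi-square distribution; the PCA-derived study weights violate those
#' conditions (they can be negative, so M itself can be negative), which is
#' why significance is assessed by permutation instead
#' ([permutation_pvalue()]).
#'
#' @param p per-study GSA p-values, all in (0, 1\].
#' @param w numeric weight vector of the same length, or a
#'   `"study_weights"` object from [pca_weights()].
#' @return the statistic M (scalar).
#' @examples
#' weighted_fisher(c(0.05, 0.05), c(1, 1))  # 11.98
#' @export
weighted_fisher <- function(p, w) {
  if (inherits(w, "study_weights")) w <- w$weights
  if (length(p) != length(w))
    stop("p-values and weights differ in length")
  stopifnot(all(p > 0), all(p <= 1))
  -2 * sum(w * log(p))
}

# pure-R reference of the permutation null; the C++ core is the production
# path, this one backs the cross-checks in the test-suite
perm_null_r <- function(universe, gs_size, n_perm) {
  n_s <- ncol(universe)
  vapply(seq_len(n_perm), function(j) {
    rows <- sample.int(nrow(universe), gs_size)
    cm <- suppressWarnings(kendall_matrix(universe[rows, , drop = FALSE]))
    w <- pca_weights(cm)$weights
    -2 * sum(w * log(runif(n_s)))
  }, numeric(1))
}

#' Permutation p-value of the weighted Fisher statistic
#'
#' The null distribution of M is generated by permuting the allocation of
#' genes to the gene set and redrawing the GSA p-values: each permutation
#' samples `gs_size` genes from the full gene universe, recomputes the
#' Kendall concordance matrix and PCA study weights on that random set,
#' draws per-study p-values from U(0, 1), and evaluates M. The p-value is
#' the add-one estimator \eqn{(\#\{M_j \ge M_0\} + 1) / (x + 1)}, never
#' exactly zero.
#'
#' An optional sequential early-stopping rule abandons clearly
#' non-significant sets: after at least 200 permutations, stop as soon as
#' the 99% confidence interval of the running estimate lies entirely above
#' 0.25. Off by default; early-stopped p-values are upward-imprecise and
#' should only be used for screening.
#'
#' @param m0 observed statistic from [weighted_fisher()].
#' @param universe genes x studies matrix of (re-oriented) PDRs covering
#'   the whole gene universe (gene set and complement).
#' @param gs_size number of genes in the set under test.
#' @param n_perm number of permutations.
#' @param early_stop enable the sequential stopping rule?
#' @return list with `p_permut`, `n_perm_used` and `m_null` (the simulated
#'   statistics).
#' @export
permutation_pvalue <- function(m0, universe, gs_size, n_perm = 9999,
                               early_stop = FALSE) {
  universe <- unclass(universe)
  stopifnot(is.matrix(universe), !anyNA(universe), n_perm >= 1)
  if (gs_size > nrow(universe))
    stop("gene-set size exceeds the gene universe")
  if (!early_stop) {
    m_null <- perm_null_stats(universe, gs_size, n_perm)
    return(list(p_permut = (sum(m_null >= m0) + 1) / (n_perm + 1),
                n_perm_used = n_perm, m_null = m_null))
  }
  chunk <- 200L
  m_null <- numeric(0)
  while (length(m_null) < n_perm) {
    todo <- min(chunk, n_perm - length(m_null))
    m_null <- c(m_null, perm_null_stats(universe, gs_size, todo))
    n <- length(m_null)
    if (n >= 200L) {
      phat <- (sum(m_null >= m0) + 1) / (n + 1)
      lo <- phat - stats::qnorm(0.995) * sqrt(phat * (1 - phat) / n)
      if (lo > 0.25) break
    }
  }
  list(p_permut = (sum(m_null >= m0) + 1) / (length(m_null) + 1),
       n_perm_used = length(m_null), m_null = m_null)
}

#' Estimate the proportion of true null gene sets (pi0)
#'
#' Bootstrap estimator of Storey & Tibshirani (2003):
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))} over a
#' grid of lambda values; the lambda minimising the bootstrap-estimated
#' mean squared error around the minimum of \eqn{\hat\pi_0} is selected.
#' The estimate is clipped to (0, 1\] (lower bound 1/m, so a fully
#' significant collection still yields a positive pi0).
#'
#' @param p vector of (permutation) p-values, one per gene set.
#' @param lambda grid of candidate thresholds in (0, 1).
#' @param n_boot bootstrap draws.
#' @return the pi0 estimate (scalar in (0, 1\]).
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                       n_boot = 100) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1),
            all(lambda > 0 & lambda < 1))
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  pi0_min <- min(pi0_l)
  mse <- numeric(length(lambda))
  for (b in seq_len(n_boot)) {
    pb <- p[sample.int(m, m, replace = TRUE)]
    pi0_b <- vapply(lambda, function(l) sum(pb > l) / (m * (1 - l)),
                    numeric(1))
    mse <- mse + (pi0_b - pi0_min)^2
  }
  pi0 <- pi0_l[which.min(mse)]
  min(max(pi0, 1 / m), 1)
}

#' Multiplicity-corrected meta-analysis p-value
#'
#' Bonferroni-like correction tempered by the estimated proportion of true
#' null gene sets:
#' \deqn{p_{meta} = \min(1,\; p_{permut} \cdot n_{GS} \cdot \pi_0).}
#'
#' @param p_permut permutation p-value(s).
#' @param n_gs number of gene sets tested.
#' @param pi0 estimated proportion of true nulls, from [storey_pi0()].
#' @return corrected p-value(s), capped at 1.
#' @examples
#' adjust_meta_p(0.0001, 421, 1)      # 0.0421
#' adjust_meta_p(0.0001, 421, 0.748)  # ~0.0315
#' @export
adjust_meta_p <- function(p_permut, n_gs, pi0) {
  stopifnot(all(p_permut >= 0 & p_permut <= 1), n_gs >= 1,
            pi0 > 0, pi0 <= 1)
  pmin(1, p_permut * n_gs * pi0)
}

# observed statistic of one gene set: concordance -> weights -> M0
meta_gsa_stat <- function(profile, p_gs, method = "kendall") {
  cm <- kendall_matrix(profile, method = method)
  w <- pca_weights(cm)
  list(m0 = weighted_fisher(p_gs, w), weights = w)
}

#' Run META-GSA end to end
#'
#' Aggregates per-study marker statistics to gene level, re-orients
#' directions, builds PDR profiles, derives concordance-based study
#' weights, computes the weighted Fisher statistic against the per-study
#' GSA p-values, assesses significance by permutation, and corrects for
#' multiple testing across gene sets.
#'
#' @param marker_stats data.frame with columns `study`, `marker`, `gene`,
#'   `theta`, `p` (two-sided marker association results of every study).
#' @param gene_sets named list of character vectors (gene ids per set).
#' @param gsa_p matrix of per-study GSA p-values, rows = gene sets (named
#'   as in `gene_sets`), columns = studies (named as in `marker_stats`).
#' @param ld optional [ld_table()] for multi-marker genes.
#' @param aggregation marker aggregation strategy, see
#'   [gene_level_stats()].
#' @param n_perm permutations per gene set.
#' @param pi0 fix pi0 instead of estimating it; the default estimates it
#'   from the permutation p-values when more than one set is tested and
#'   uses 1 otherwise (no correction needed for a single set).
#' @param correlation concordance measure, see [kendall_matrix()].
#' @param early_stop see [permutation_pvalue()].
#' @param seed optional integer seed; results are deterministic given it.
#' @param ... passed to [gene_level_stats()].
#' @return data.frame with one row per gene set: `gene_set`, `n_genes`,
#'   `m0`, `p_permut`, `n_perm_used`, `pi0`, `p_meta`, `eff_studies`, and
#'   a `weights` attribute (list of `"study_weights"`).
#' @export
run_meta_gsa <- function(marker_stats, gene_sets, gsa_p, ld = NULL,
                         aggregation = c("best", "all", "promising"),
                         n_perm = 9999, pi0 = NULL,
                         correlation = "kendall", early_stop = FALSE,
                         seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1,
            !is.null(names(gene_sets)), is.matrix(gsa_p))
  if (!all(names(gene_sets) %in% rownames(gsa_p)))
    stop("every gene set needs a row of GSA p-values")
  gl <- gene_level_stats(marker_stats, ld, aggregation, ...)
  d_re <- reorient_directions(gl$d)
  universe <- pdr(gl$p, d_re)
  studies <- colnames(universe)
  if (!all(studies %in% colnames(gsa_p)))
    stop("GSA p-value columns do not cover all studies")
  p_floor <- 1 / (2 * n_perm)   # clamp p = 0 at the permutation resolution
  rows <- lapply(names(gene_sets), function(gs_id) {
    prof <- build_pdr_profiles(gl$p, d_re, gene_sets[[gs_id]])
    p_gs <- pmax(gsa_p[gs_id, studies], p_floor)
    st <- meta_gsa_stat(prof, p_gs, method = correlation)
    pp <- permutation_pvalue(st$m0, universe, nrow(prof), n_perm,
                             early_stop = early_stop)
    data.frame(gene_set = gs_id, n_genes = nrow(prof), m0 = st$m0,
               p_permut = pp$p_permut, n_perm_used = pp$n_perm_used,
               eff_studies = st$weights$eff_studies,
               weights = I(list(st$weights)))
  })
  res <- do.call(rbind, rows)
  pi0_hat <- if (!is.null(pi0)) pi0
             else if (nrow(res) > 1) storey_pi0(res$p_permut) else 1
  res$pi0 <- pi0_hat
  res$p_meta <- adjust_meta_p(res$p_permut, nrow(res), pi0_hat)
  w <- res$weights
  res$weights <- NULL
  res <- res[, c("gene_set", "n_genes", "m0", "p_permut", "n_perm_used",
                 "pi0", "p_meta", "eff_studies")]
  attr(res, "weights") <- stats::setNames(w, res$gene_set)
  res
}
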