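#' One-sided Wilcoxon rank-sum gene-set analysis
#'
#' Competitive GSA for one study: tests whether the marker/gene p-values of
#' the gene set of interest are stochastically smaller than those of the
#' complementary genes (enrichment of low p-values). The exact rank-sum
#' distribution is used when the smaller group has at most 8 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param gs_p p-values of the gene-set genes.
#' @param comp_p p-values of the complementary genes.
#' @return list with `es` (the rank-sum statistic W) and `p_gs` (one-sided
#'   enrichment p-value). If every value is tied across both groups there
#'   is no ordering information and p = 0.5 is returned with a warning.
#' @examples
#' wilcoxon_gsa(c(0.01, 0.02), c(0.5, 0.6, 0.7))  # exact p = 0.1
#' @export
wilcoxon_gsa <- function(gs_p, comp_p) {
  stopifnot(length(gs_p) >= 1, length(comp_p) >= 1)
  if (length(unique(c(gs_p, comp_p))) == 1L) {
    warning("all values tied across both groups; p = 0.5 by convention")
    return(list(es = length(gs_p) * length(comp_p) / 2, p_gs = 0.5))
  }
  ties <- anyDuplicated(c(gs_p, comp_p)) > 0
  exact <- min(length(gs_p), length(comp_p)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(gs_p, comp_p, alternative = "less", exact = exact,
                correct = TRUE))
  list(es = unname(wt$statistic), p_gs = wt$p.value)
}

#' Simple p-pooling (unweighted Fisher inverse chi-square)
#'
#' Combines one-sided GSA p-values of independent studies with Fisher's
#' method: \eqn{M = -2 \sum_s \ln p_s} referred to a chi-square
#' distribution with \eqn{2 n_s} degrees of freedom. For a single study
#' this is the identity \eqn{p_{SPP} = p}.
#'
#' @param p_gs per-study GSA p-values; zeros are clamped to the smallest
#'   positive double.
#' @return list with `m` (the statistic) and `p` (pooled p-value).
#' @export
spp <- function(p_gs) {
  stopifnot(length(p_gs) >= 1, all(p_gs >= 0 & p_gs <= 1))
  p_gs <- pmax(p_gs, .Machine$double.xmin)
  m <- -2 * sum(log(p_gs))
  list(m = m, p = pchisq(m, df = 2 * length(p_gs), lower.tail = FALSE))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments estimate of the between-study variance tau^2 from
#' Cochran's Q, inverse-variance pooling with weights 1/(se^2 + tau^2),
#' and a two-sided Wald test of the pooled estimate. With a single study
#' the estimate passes through unchanged (with a warning).
#'
#' @param theta per-study effect estimates (e.g. log odds ratios).
#' @param se their standard errors (finite, positive).
#' @return list with `theta` (pooled estimate), `se`, `p` (two-sided),
#'   `tau2` and `q` (heterogeneity statistic).
#' @export
random_effects_meta <- function(theta, se) {
  stopifnot(length(theta) == length(se), all(is.finite(se)), all(se > 0))
  if (length(theta) == 1L) {
    warning("single study: fixed-effect passthrough")
    return(list(theta = theta, se = se,
                p = 2 * pnorm(-abs(theta / se)), tau2 = 0, q = 0))
  }
  fit <- dl_meta_matrix(matrix(theta, 1), matrix(se, 1))
  lapply(fit, as.vector)
}

# vectorised DL: rows = markers, columns = studies
dl_meta_matrix <- function(theta, se) {
  w <- 1 / se^2
  sw <- rowSums(w)
  tf <- rowSums(w * theta) / sw
  q <- rowSums(w * (theta - tf)^2)
  cc <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (q - (ncol(theta) - 1)) / cc)
  ws <- 1 / (se^2 + tau2)
  tp <- rowSums(ws * theta) / rowSums(ws)
  sep <- sqrt(1 / rowSums(ws))
  list(theta = tp, se = sep, p = 2 * pnorm(-abs(tp / sep)),
       tau2 = tau2, q = q)
}

#' Pooled-GWAS gene-set analysis
#'
#' Comparator that switches the pooling to the marker level: each marker's
#' effect estimates are first combined across studies by a
#' DerSimonian-Laird random-effects meta-analysis, then a single one-sided
#' Wilcoxon rank-sum GSA is run on the pooled two-sided p-values.
#'
#' @param marker_stats data.frame with columns `study`, `marker`, `theta`,
#'   `se` covering the same marker panel in every study (a `p` column, if
#'   present, is used directly in the single-study case); markers missing
#'   from some study are dropped with a warning.
#' @param gs_markers character vector of markers belonging to the gene set.
#' @return list with `p_gs` and `es` as in [wilcoxon_gsa()], plus `pooled`
#'   (data.frame of per-marker pooled results).
#' @export
pooled_gwas_gsa <- function(marker_stats, gs_markers) {
  stopifnot(all(c("study", "marker", "theta", "se") %in%
                  names(marker_stats)))
  studies <- unique(as.character(marker_stats$study))
  tab <- table(as.character(marker_stats$marker))
  complete <- names(tab)[tab == length(studies)]
  if (length(complete) < length(tab))
    warning(sprintf("%d marker(s) missing in some study dropped",
                    length(tab) - length(complete)))
  ms <- marker_stats[marker_stats$marker %in% complete, ]
  ms <- ms[order(match(as.character(ms$marker), complete),
                 match(as.character(ms$study), studies)), ]
  th <- matrix(ms$theta, nrow = length(complete), byrow = TRUE)
  se <- matrix(ms$se, nrow = length(complete), byrow = TRUE)
  fit <- if (length(studies) == 1L)
    list(theta = th[, 1], se = se[, 1],
         p = if ("p" %in% names(ms)) ms$p
             else 2 * pnorm(-abs(th[, 1] / se[, 1])))
  else dl_meta_matrix(th, se)
  pooled <- data.frame(marker = complete, theta = fit$theta, p = fit$p)
  in_gs <- pooled$marker %in% gs_markers
  if (!any(in_gs)) stop("no gene-set marker left after completeness filter")
  res <- wilcoxon_gsa(pooled$p[in_gs], pooled$p[!in_gs])
  c(res, list(pooled = pooled))
}
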