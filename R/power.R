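#' Parse a relative-risk multiset string
#'
#' Encodes rows of the scenario registry, e.g. `"5x1 5x1.5"` for five genes
#' at RR = 1 and five at RR = 1.5.
#'
#' @param txt string of space-separated `<count>x<rr>` terms.
#' @return numeric vector of relative risks.
#' @export
parse_rr <- function(txt) {
  parts <- strsplit(trimws(txt), "\\s+")[[1]]
  unlist(lapply(parts, function(p) {
    kv <- strsplit(p, "x", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed RR term: ", p)
    rep(as.numeric(kv[2]), as.integer(kv[1]))
  }))
}

#' The 20 simulation scenarios of the power study
#'
#' Patterns of true marker-phenotype association for a gene set of 10
#' genes against 90 complementary genes, 500 cases and 500 controls per
#' study, MAF 0.30, prevalence 5%: null scenarios (1-3), association only
#' in the gene set with growing relative risk (4-8) or growing study count
#' (9-16), and mixed structures with associated genes in both sets
#' (17-20).
#'
#' @return list of 20 entries, each with `id`, `label` and `spec`
#'   (a [scenario_spec()]).
#' @export
scenario_registry <- function() {
  rows <- list(
    list(1L,  "10x1",           "90x1",                10L, "H0: no gene associated"),
    list(2L,  "10x1.2",         "90x1.2",              10L, "H0: all genes associated (RR 1.2)"),
    list(3L,  "10x1.5",         "90x1.5",              10L, "H0: all genes associated (RR 1.5)"),
    list(4L,  "5x1 5x1.1",      "90x1",                10L, "HA: half of GS at RR 1.1"),
    list(5L,  "5x1 5x1.2",      "90x1",                10L, "HA: half of GS at RR 1.2"),
    list(6L,  "5x1 5x1.3",      "90x1",                10L, "HA: half of GS at RR 1.3"),
    list(7L,  "5x1 5x1.4",      "90x1",                10L, "HA: half of GS at RR 1.4"),
    list(8L,  "5x1 5x1.5",      "90x1",                10L, "HA: half of GS at RR 1.5"),
    list(9L,  "5x1 5x1.5",      "90x1",                 2L, "HA: RR 1.5, 2 studies"),
    list(10L, "5x1 5x1.5",      "90x1",                 3L, "HA: RR 1.5, 3 studies"),
    list(11L, "5x1 5x1.5",      "90x1",                 4L, "HA: RR 1.5, 4 studies"),
    list(12L, "5x1 5x1.5",      "90x1",                 5L, "HA: RR 1.5, 5 studies"),
    list(13L, "5x1 5x1.5",      "90x1",                 6L, "HA: RR 1.5, 6 studies"),
    list(14L, "5x1 5x1.5",      "90x1",                 7L, "HA: RR 1.5, 7 studies"),
    list(15L, "5x1 5x1.5",      "90x1",                 8L, "HA: RR 1.5, 8 studies"),
    list(16L, "5x1 5x1.5",      "90x1",                 9L, "HA: RR 1.5, 9 studies"),
    list(17L, "5x1 4x1.2 1x1.5", "90x1",               10L, "HA: mixed GS, null complement"),
    list(18L, "5x1 4x1.2 1x1.5", "63x1 18x1.2 9x1.5",  10L, "HA: GS dominates GS'"),
    list(19L, "5x1 4x1.2 1x1.5", "41x1 32x1.2 17x1.5", 10L, "HA: GS dominated by GS'"),
    list(20L, "5x1 4x1.2 1x1.5", "45x1 36x1.2 9x1.5",  10L, "H0: same proportion associated"))
  lapply(rows, function(r)
    list(id = r[[1]], label = r[[5]],
         spec = scenario_spec(r[[4]], parse_rr(r[[2]]), parse_rr(r[[3]]))))
}

# one simulation replicate: simulate studies, GSA per study, then
# META-GSA / SPP / pooledGWAS-GSA p-values for the GS
simulate_replicate <- function(spec, n_perm, share_directions = TRUE) {
  n_s <- spec$n_studies
  n_m <- length(spec$rr_gs) + length(spec$rr_comp)
  flip <- if (share_directions) runif(n_m) < 0.5 else NULL
  studies <- lapply(seq_len(n_s),
                    function(s) simulate_study(spec, flip = flip))
  keep <- Reduce(`&`, lapply(studies, `[[`, "keep"))
  p_mat <- sapply(studies, `[[`, "p")[keep, , drop = FALSE]
  d_mat <- sapply(studies, `[[`, "d")[keep, , drop = FALSE]
  th_mat <- sapply(studies, `[[`, "theta")[keep, , drop = FALSE]
  se_mat <- sapply(studies, `[[`, "se")[keep, , drop = FALSE]
  gs <- studies[[1]]$gs[keep]
  rownames(p_mat) <- rownames(d_mat) <- studies[[1]]$gene[keep]
  # GSA step: one-sided Wilcoxon per study
  p_gsa <- vapply(seq_len(n_s), function(s)
    wilcoxon_gsa(p_mat[gs, s], p_mat[!gs, s])$p_gs, numeric(1))
  # SPP
  p_spp <- spp(p_gsa)$p
  # pooledGWAS-GSA
  fit <- dl_meta_matrix(th_mat, se_mat)
  p_pool <- wilcoxon_gsa(fit$p[gs], fit$p[!gs])$p_gs
  # META-GSA: one marker per gene, so gene level = marker level
  d_re <- reorient_directions(d_mat)
  universe <- pdr(p_mat, d_re)
  # magnitude warnings from near-cancelling loadings are routine across
  # thousands of replicates; the permutation null absorbs the behaviour
  st <- suppressWarnings(meta_gsa_stat(universe[gs, , drop = FALSE], p_gsa))
  p_meta <- permutation_pvalue(st$m0, universe, sum(gs), n_perm)$p_permut
  c(meta = p_meta, spp = p_spp, pooled = p_pool)
}

#' Run one power-study scenario
#'
#' Simulates `n_sim` replicates of a scenario. Each replicate draws
#' `n_studies` case-control GWASs, runs the one-sided Wilcoxon GSA per
#' study, and evaluates META-GSA (with its permutation p-value), simple
#' p-pooling and pooledGWAS-GSA on the gene set of interest. Rejection
#' fractions at `alpha` estimate the power (or type-I error under null
#' scenarios), and the 2x2 agreement table between META-GSA and SPP
#' verdicts is accumulated.
#'
#' @param spec a [scenario_spec()].
#' @param n_sim number of simulation replicates.
#' @param n_perm permutations per replicate for the META-GSA p-value.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @param share_directions if `TRUE` (default) the side of the risk allele
#'   is drawn once per marker per replicate and shared by all studies (the
#'   true direction is a property of the marker); if `FALSE` each study
#'   flips independently, a stress case in which cross-study pooling of
#'   effect estimates breaks down.
#' @return object of class `"power_result"`: list with `power` (named
#'   rejection fractions), `mc_se` (their binomial Monte-Carlo standard
#'   errors), `n_sim`, `alpha`, `crosstab` (META-GSA x SPP 2x2 counts) and
#'   `p` (n_sim x 3 matrix of per-replicate p-values).
#' @export
run_scenario <- function(spec, n_sim = 500, n_perm = 999, alpha = 0.05,
                         seed = NULL, share_directions = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), n_sim >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(NA_real_, n_sim, 3,
              dimnames = list(NULL, c("meta", "spp", "pooled")))
  for (i in seq_len(n_sim))
    p[i, ] <- simulate_replicate(spec, n_perm, share_directions)
  rej <- p <= alpha
  power <- colMeans(rej)
  crosstab <- matrix(0L, 2, 2,
                     dimnames = list(meta = c("sig", "ns"),
                                     spp = c("sig", "ns")))
  if (n_sim > 0) {
    crosstab[] <- c(sum(rej[, "meta"] & rej[, "spp"]),
                    sum(!rej[, "meta"] & rej[, "spp"]),
                    sum(rej[, "meta"] & !rej[, "spp"]),
                    sum(!rej[, "meta"] & !rej[, "spp"]))
    power <- colMeans(rej)
  } else power[] <- NaN
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / max(n_sim, 1)),
                 n_sim = n_sim, alpha = alpha, n_perm = n_perm,
                 crosstab = crosstab, p = p, spec = spec),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power at alpha = %.2f over %d replicates (%d permutations)\n",
              x$alpha, x$n_sim, x$n_perm))
  out <- rbind(power = x$power, mc_se = x$mc_se)
  colnames(out) <- c("META-GSA", "SPP", "pooledGWAS-GSA")
  print(round(out, 4))
  cat("\nMETA-GSA x SPP agreement:\n")
  print(x$crosstab)
  invisible(x)
}
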