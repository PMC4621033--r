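#' Between-study concordance matrix of PDR profiles
#'
#' Pairwise Kendall rank correlations (tau-b, tie-corrected; ties arise
#' naturally when PDRs are exactly 0) between the study columns of a PDR
#' profile matrix. Rank correlation is used because PDRs may be scaled
#' differently between studies (sample size, model, stratification), which
#' leaves ranks, but not magnitudes, comparable.
#'
#' @param profiles genes x studies matrix of PDRs (>= 2 studies, >= 2
#'   genes), e.g. from [build_pdr_profiles()].
#' @param method correlation measure; Kendall is the default, Pearson and
#'   Spearman are available as alternatives.
#' @return symmetric studies x studies correlation matrix with unit
#'   diagonal. A constant study column carries no rank information: its
#'   correlations are set to 0 with a warning.
#' @export
kendall_matrix <- function(profiles,
                           method = c("kendall", "pearson", "spearman")) {
  method <- match.arg(method)
  m <- unclass(profiles)
  stopifnot(is.matrix(m), ncol(m) >= 2, nrow(m) >= 2, !anyNA(m))
  cm <- suppressWarnings(cor(m, method = method))
  if (any(!is.finite(cm))) {
    warning("constant study column: undefined correlations set to 0")
    cm[!is.finite(cm)] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Study weights from the first principal component of the concordance matrix
#'
#' The loadings of the studies on the common (hidden) association pattern
#' are taken to be the first principal component PC1 of the between-study
#' concordance matrix. With EV1 the largest eigenvalue, EV1/n_s is the
#' fraction of profile variance explained by PC1 and is interpreted as the
#' *effective number of studies*. The weight of study s is its normalised
#' loading times the effective number of studies:
#' \deqn{w_s = \frac{PC1_s}{\sum_j |PC1_j|} \cdot \frac{EV1}{n_s}.}
#' Whenever all loadings share one sign -- every concordant collection of
#' studies -- this equals the signed normalisation
#' \eqn{PC1_s / \sum_j PC1_j \cdot EV1/n_s} and the weights sum exactly to
#' the effective number of studies EV1/n_s. Under perfect concordance
#' (all tau = 1) each weight is 1/n_s. A study whose pattern opposes the
#' consensus keeps a *negative* weight, so its small GSA p-value counts
#' against, not towards, the pooled significance; weights are therefore
#' not constrained to \[0, 1\], but each is bounded by EV1/n_s in
#' magnitude.
#'
#' The absolute-sum denominator is the package's regularisation of the
#' signed rule: for discordance-dominated matrices (e.g. permuted gene
#' sets, or two anti-correlated studies, where PC1 = (1, -1)/sqrt(2)) the
#' signed denominator passes through zero and the weights diverge, which
#' corrupts the permutation null. The strict signed rule is available via
#' `normalization = "signed"`; it errors when the loading sum is exactly
#' zero and warns when weights exceed 1 in magnitude.
#'
#' The eigenvector sign is fixed so the loading sum is positive; the
#' weights themselves are invariant under the sign flip.
#'
#' @param cm symmetric concordance matrix with unit diagonal, from
#'   [kendall_matrix()].
#' @param normalization `"abs"` (default) or `"signed"`, see Details.
#' @return object of class `"study_weights"`: list with `weights`, `pc1`,
#'   `ev1`, `eff_studies` (= EV1/n_s) and `n_studies`.
#' @examples
#' cm <- matrix(c(1, 0.5, 0.5, 1), 2)
#' pca_weights(cm)$weights  # 0.375 0.375
#' @export
pca_weights <- function(cm, normalization = c("abs", "signed")) {
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm),
            max(abs(cm - t(cm))) < 1e-8, all(abs(diag(cm) - 1) < 1e-8))
  n <- nrow(cm)
  e <- eigen((cm + t(cm)) / 2, symmetric = TRUE)
  ev1 <- e$values[1]
  pc1 <- e$vectors[, 1]
  if (sum(pc1) < 0) pc1 <- -pc1
  if (normalization == "abs") {
    w <- pc1 / sum(abs(pc1)) * ev1 / n
  } else {
    s <- sum(pc1)
    if (s == 0)
      stop("degenerate loadings: PC1 sums to zero, weights are undefined")
    w <- pc1 / s * ev1 / n
    if (max(abs(w)) > 1)
      warning("PC1 loadings nearly cancel: weights exceed 1 in magnitude")
  }
  structure(list(weights = stats::setNames(w, colnames(cm)), pc1 = pc1,
                 ev1 = ev1, eff_studies = ev1 / n, n_studies = n),
            class = "study_weights")
}

#' @export
print.study_weights <- function(x, ...) {
  cat("Study weights (PC1 of the concordance matrix)\n")
  cat("  EV1 =", format(x$ev1, digits = 4),
      "| effective studies =", format(x$eff_studies, digits = 4),
      "of", x$n_studies, "\n")
  print(round(x$weights, 4))
  invisible(x)
}
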