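#' Directed reversed p-value (PDR)
#'
#' Combines the significance and the direction of a gene-level association
#' into one quantity on the scale of a correlation coefficient:
#' \deqn{p' = d (1 - p),}
#' so that 0 means no evidence and +1 / -1 strong evidence of positive /
#' negative association.
#'
#' @param p gene-level p-value(s) in \[0, 1\].
#' @param d gene-level direction(s) in \[-1, 1\] (real-valued after LD
#'   averaging across markers or studies).
#' @return numeric vector of PDRs in \[-1, 1\].
#' @examples
#' pdr(0.05, 1)     # 0.95
#' pdr(0.2, -0.5)   # -0.4
#' @export
pdr <- function(p, d) {
  stopifnot(all(p >= 0 & p <= 1), all(abs(d) <= 1))
  d * (1 - p)
}

#' Signed linkage-disequilibrium table
#'
#' Stores pairwise signed allele correlations r between markers for use in
#' cross-study direction homogenisation and LD-block marker weights.
#' Symmetry and r(m, m) = 1 are implied and need not be listed.
#'
#' @param ld data.frame with columns `marker_a`, `marker_b`, `r`
#'   (|r| <= 1).
#' @return object of class `"ld_table"`.
#' @seealso [read_ld_table()] for the PLINK `.ld` dialect.
#' @export
ld_table <- function(ld) {
  stopifnot(is.data.frame(ld),
            all(c("marker_a", "marker_b", "r") %in% names(ld)))
  if (any(abs(ld$r) > 1)) stop("|r| must be <= 1")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  r <- ld$r
  names(r) <- key(as.character(ld$marker_a), as.character(ld$marker_b))
  structure(list(r = r, key = key), class = "ld_table")
}

# signed r lookup; `default` is returned for unlisted pairs (NA = unknown)
ld_r <- function(ld, a, b, default = NA_real_) {
  if (length(a) == 0L) return(numeric(0))
  out <- ifelse(a == b, 1, unname(ld$r[ld$key(a, b)]))
  out[is.na(out) & a != b] <- default
  out
}

#' LD-block marker weights within a gene
#'
#' Markers of a gene are grouped into LD blocks by greedy single-linkage
#' clustering at `r2_threshold`; each marker then receives the weight
#' \deqn{v_m = 1 / \sum_{m' \in \mathrm{block}(m)} r^2_{m',m}}
#' (the sum includes the marker itself, r^2 = 1), so that a block of fully
#' redundant markers counts as one and the weight total
#' \eqn{\sum_m v_m} equals the number of independent markers. Pairs absent
#' from the LD table are treated as unlinked (r = 0).
#'
#' @param markers character vector of marker ids of one gene.
#' @param ld an [ld_table()], or `NULL` when all markers are unlinked.
#' @param r2_threshold minimum r^2 for two markers to join a block.
#' @return named numeric vector of weights v_m.
#' @export
marker_weights <- function(markers, ld = NULL, r2_threshold = 0.5) {
  n <- length(markers)
  stopifnot(n >= 1, !anyDuplicated(markers))
  if (n == 1L) return(stats::setNames(1, markers))
  r2 <- diag(1, n)
  if (!is.null(ld)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rij <- ld_r(ld, markers[i], markers[j], default = 0)
      r2[i, j] <- r2[j, i] <- rij^2
    }
  }
  # single-linkage blocks: connected components of the r2 >= threshold graph
  block <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (r2[i, j] >= r2_threshold && block[i] != block[j]) {
        block[block == max(block[i], block[j])] <- min(block[i], block[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  v <- vapply(seq_len(n), function(i) {
    same <- block == block[i]
    1 / sum(r2[i, same])
  }, numeric(1))
  stats::setNames(v, markers)
}

#' Gene-level statistic from the most significant marker
#'
#' The "best marker" aggregation: per study, the gene's p-value is the
#' minimum marker p-value and the selected marker becomes the gene's
#' representative. When all studies select the same marker the direction is
#' simply the sign of its association estimate; otherwise the sign is
#' multiplied by the mean signed LD correlation r between this study's
#' representative and every other study's representative, so a
#' representative in linkage equilibrium with the other studies' choices
#' yields direction 0 (and hence PDR 0) regardless of its significance.
#' Ties on the minimum p-value are broken towards the lexicographically
#' smallest marker id.
#'
#' @param stats data.frame with columns `study`, `marker`, `theta`, `p`
#'   holding every marker of one gene in every study.
#' @param ld an [ld_table()]; required when representatives differ across
#'   studies. A missing cross-study pair is an error (assuming r = 0 would
#'   silently annihilate the gene's PDR).
#' @return data.frame with one row per study: `study`, `marker`
#'   (representative), `p_g`, `d_g`.
#' @export
best_marker_stat <- function(stats, ld = NULL) {
  stopifnot(all(c("study", "marker", "theta", "p") %in% names(stats)))
  studies <- unique(as.character(stats$study))
  rep_rows <- lapply(studies, function(s) {
    g <- stats[stats$study == s, , drop = FALSE]
    stopifnot(nrow(g) >= 1)
    g <- g[order(g$p, as.character(g$marker)), , drop = FALSE]
    g[1, , drop = FALSE]
  })
  sel <- vapply(rep_rows, function(r) as.character(r$marker), character(1))
  p_g <- vapply(rep_rows, function(r) r$p, numeric(1))
  sgn <- vapply(rep_rows, function(r) if (r$theta >= 0) 1 else -1, numeric(1))
  if (length(unique(sel)) == 1L) {
    d_g <- sgn
  } else {
    if (is.null(ld))
      stop("representative markers differ across studies; an LD table is required")
    d_g <- vapply(seq_along(studies), function(i) {
      others <- sel[-i]
      r <- ld_r(ld, rep(sel[i], length(others)), others)
      if (anyNA(r))
        stop(sprintf("missing LD entry for marker pair (%s, %s)",
                     sel[i], others[which(is.na(r))[1]]))
      sgn[i] * mean(r)
    }, numeric(1))
  }
  data.frame(study = studies, marker = sel, p_g = p_g, d_g = d_g)
}

#' Gene-level statistic averaging over (promising) markers
#'
#' The "all markers" aggregation: per study, marker p-values are combined
#' with the weighted Fisher inverse chi-square sum
#' \eqn{C_g = -2 \sum_m v_m \ln p_m} using the LD-block weights of
#' [marker_weights()], and referenced against a chi-square distribution
#' whose degrees of freedom are set by the number of independent markers
#' \eqn{\sum_m v_m} (`df_mode = "fisher"` uses \eqn{2\sum v}, by analogy
#' with the unweighted Fisher method; `"independent"` uses \eqn{\sum v}).
#' The direction is the v-weighted mean of the marker signs, normalised by
#' \eqn{\sum v} so that it stays within \[-1, 1\].
#'
#' With `promising_only = TRUE` only markers with p < `p_promising` enter;
#' if none survive the gene is assigned p = 1, d = 0 and flagged.
#'
#' @inheritParams best_marker_stat
#' @param promising_only restrict to promising markers?
#' @param p_promising promising-marker threshold.
#' @param df_mode `"fisher"` (df = 2 sum v, default) or `"independent"`
#'   (df = sum v).
#' @param r2_threshold LD-block threshold passed to [marker_weights()].
#' @return data.frame with one row per study: `study`, `p_g`, `d_g`,
#'   `n_markers` (markers used), `flagged`.
#' @export
averaged_gene_stat <- function(stats, ld = NULL, promising_only = FALSE,
                               p_promising = 0.05,
                               df_mode = c("fisher", "independent"),
                               r2_threshold = 0.5) {
  stopifnot(all(c("study", "marker", "theta", "p") %in% names(stats)))
  df_mode <- match.arg(df_mode)
  studies <- unique(as.character(stats$study))
  out <- lapply(studies, function(s) {
    g <- stats[stats$study == s, , drop = FALSE]
    if (promising_only) g <- g[g$p < p_promising, , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(study = s, p_g = 1, d_g = 0, n_markers = 0L,
                        flagged = TRUE))
    v <- marker_weights(as.character(g$marker), ld, r2_threshold)
    cg <- -2 * sum(v * log(pmax(g$p, .Machine$double.xmin)))
    df <- if (df_mode == "fisher") 2 * sum(v) else sum(v)
    p_g <- pchisq(cg, df = df, lower.tail = FALSE)
    d_g <- sum(v * sign(ifelse(g$theta >= 0, 1, -1))) / sum(v)
    data.frame(study = s, p_g = p_g, d_g = d_g, n_markers = nrow(g),
               flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Re-orient gene-level directions along the cross-study reference profile
#'
#' For each gene the mean direction across studies defines a reference;
#' genes whose mean is negative have all their per-study directions
#' negated, so that positive values always point towards the cross-study
#' consensus. A mean of exactly zero leaves the gene unchanged
#' (deterministic, unbiased tie-break). The operation is idempotent.
#'
#' @param d matrix of directions, rows = genes, columns = studies.
#' @return matrix of the same shape with non-negative row means.
#' @export
reorient_directions <- function(d) {
  stopifnot(is.matrix(d), !anyNA(d))
  flip <- rowMeans(d) < 0
  d[flip, ] <- -d[flip, , drop = FALSE]
  d
}

#' Build the PDR profile matrix of a gene set
#'
#' Restricts gene-level results (re-orientation already applied) to the
#' genes of one set and assembles the genes x studies matrix of PDRs that
#' feeds the concordance step. Gene order is deterministic (sorted ids).
#'
#' @param p matrix of gene-level p-values (rows = genes, named).
#' @param d matrix of re-oriented gene-level directions, same shape.
#' @param genes character vector of gene-set member ids.
#' @return matrix of PDRs (genes x studies), class `"pdr_profile"`.
#'   Genes absent from the matrices are dropped with a warning; a gene
#'   present but with missing values in some study is an error, since
#'   profiles must be complete.
#' @export
build_pdr_profiles <- function(p, d, genes) {
  stopifnot(is.matrix(p), is.matrix(d), identical(dim(p), dim(d)),
            !is.null(rownames(p)))
  genes <- sort(unique(as.character(genes)))
  absent <- setdiff(genes, rownames(p))
  if (length(absent) == length(genes))
    stop("no gene of the set is present in the gene-level results")
  if (length(absent))
    warning(sprintf("%d gene(s) absent from all studies dropped: %s",
                    length(absent), paste(absent, collapse = ", ")))
  genes <- setdiff(genes, absent)
  ps <- p[genes, , drop = FALSE]
  ds <- d[genes, , drop = FALSE]
  if (anyNA(ps) || anyNA(ds))
    stop("PDR profiles must be complete: gene missing in some studies")
  structure(pdr(ps, ds), class = c("pdr_profile", "matrix"))
}

#' Gene-level p/d matrices from per-study marker statistics
#'
#' Applies one of the three marker aggregation strategies gene by gene and
#' returns matched gene x study matrices of p-values and (not yet
#' re-oriented) directions.
#'
#' @param marker_stats data.frame with columns `study`, `marker`, `gene`,
#'   `theta`, `p`.
#' @param ld optional [ld_table()].
#' @param aggregation `"best"` ([best_marker_stat()]), `"all"` or
#'   `"promising"` ([averaged_gene_stat()]).
#' @param ... passed on to the aggregation function.
#' @return list with matrices `p` and `d` (rows = sorted genes, columns =
#'   studies in order of first appearance).
#' @export
gene_level_stats <- function(marker_stats, ld = NULL,
                             aggregation = c("best", "all", "promising"),
                             ...) {
  aggregation <- match.arg(aggregation)
  stopifnot(all(c("study", "marker", "gene", "theta", "p") %in%
                  names(marker_stats)))
  studies <- unique(as.character(marker_stats$study))
  genes <- sort(unique(as.character(marker_stats$gene)))
  p <- matrix(NA_real_, length(genes), length(studies),
              dimnames = list(genes, studies))
  d <- p
  for (g in genes) {
    gm <- marker_stats[marker_stats$gene == g, , drop = FALSE]
    st <- switch(aggregation,
                 best = best_marker_stat(gm, ld),
                 all = averaged_gene_stat(gm, ld, ...),
                 promising = averaged_gene_stat(gm, ld,
                                                promising_only = TRUE, ...))
    p[g, as.character(st$study)] <- st$p_g
    d[g, as.character(st$study)] <- st$d_g
  }
  list(p = p, d = d)
}
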