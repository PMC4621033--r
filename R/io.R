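#' Read per-study marker association statistics
#'
#' Tab-separated table with columns `study`, `marker`, `gene`, `theta`
#' (log odds ratio), `se` and `p`; the direction flag `d` (+1 iff
#' OR >= 1) is derived from `theta`.
#'
#' @param path file path.
#' @return data.frame of marker statistics.
#' @export
read_marker_stats <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("study", "marker", "gene", "theta", "se", "p")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("marker-stats file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(x$p) | x$p < 0 | x$p > 1)
  if (length(bad))
    stop("malformed p-value at line ", bad[1] + 1L)
  x$d <- ifelse(x$theta >= 0, 1L, -1L)
  x
}

#' Write per-study marker association statistics
#'
#' Inverse of [read_marker_stats()]; numeric columns are written with 17
#' significant digits so a write/read round trip is lossless.
#'
#' @param stats marker statistics data.frame.
#' @param path output path.
#' @export
write_marker_stats <- function(stats, path) {
  x <- stats[, intersect(c("study", "marker", "gene", "theta", "se", "p"),
                         names(stats))]
  for (col in c("theta", "se", "p"))
    x[[col]] <- sprintf("%.17g", x[[col]])
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set definitions (GMT)
#'
#' Standard GMT format: one set per line, tab-separated id, description,
#' then member gene ids. Sets whose gene count falls outside the size
#' window are excluded (their number is reported), guarding against
#' testing overly small or large sets.
#'
#' @param path GMT file path.
#' @param min_size,max_size inclusive size window (genes per set).
#' @return named list of character vectors; the descriptions are kept in
#'   the `"description"` attribute.
#' @export
read_gene_sets <- function(path, min_size = 15, max_size = 200) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": need id, description, >=1 gene")
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message(sum(!keep), " gene set(s) outside the size window [",
            min_size, ", ", max_size, "] excluded")
  structure(sets[keep], description = stats::setNames(desc, ids)[keep])
}

#' Read a SNP-to-gene map
#'
#' Two-column tab-separated table `marker`, `gene`.
#'
#' @param path file path.
#' @return data.frame with columns `marker` and `gene`.
#' @export
read_snp_map <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!all(c("marker", "gene") %in% names(x)))
    stop("SNP map needs columns 'marker' and 'gene'")
  x
}

#' Read a signed LD table
#'
#' Accepts a 3-column tab-separated table (`marker_a`, `marker_b`, `r`) or
#' the whitespace-separated PLINK `.ld` dialect (columns `SNP_A`, `SNP_B`
#' and `R`, or `R2` as a fallback: then the unsigned square root is used,
#' with a warning, since the sign of r is lost).
#'
#' @param path file path.
#' @return an [ld_table()].
#' @export
read_ld_table <- function(path) {
  head1 <- readLines(path, n = 1)
  if (grepl("\t", head1)) {
    x <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  } else {
    x <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  if (all(c("marker_a", "marker_b", "r") %in% names(x))) {
    return(ld_table(x))
  }
  if (all(c("SNP_A", "SNP_B") %in% names(x))) {
    if ("R" %in% names(x)) {
      r <- x$R
    } else if ("R2" %in% names(x)) {
      warning("LD table provides R2 only; using unsigned sqrt(R2) as r")
      r <- sqrt(x$R2)
    } else stop("PLINK .ld table lacks an R or R2 column")
    return(ld_table(data.frame(marker_a = x$SNP_A, marker_b = x$SNP_B,
                               r = r)))
  }
  stop("unrecognised LD table format: ", path)
}

#' Read per-study, per-set GSA p-values
#'
#' Wide tab-separated table: first column `study`, remaining columns one
#' per gene set.
#'
#' @param path file path.
#' @return matrix of p-values, rows = gene sets, columns = studies.
#' @export
read_gsa_pvalues <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (names(x)[1] != "study")
    stop("GSA p-value table must start with a 'study' column")
  m <- t(as.matrix(x[, -1, drop = FALSE]))
  colnames(m) <- x$study
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("GSA p-values outside [0, 1]")
  m
}

#' Read and validate a full study input bundle
#'
#' @param marker_stats,snp_map,gene_sets,gsa_pvalues,ld file paths
#'   (`ld` optional).
#' @param min_set_size,max_set_size gene-set size window, see
#'   [read_gene_sets()].
#' @return list with the parsed components, cross-validated: every marker
#'   in the stats must be mapped to a gene, every retained gene set keeps
#'   at least one mapped gene, and the study ids of the GSA p-values must
#'   cover those of the marker statistics.
#' @export
read_inputs <- function(marker_stats, snp_map, gene_sets, gsa_pvalues,
                        ld = NULL, min_set_size = 15, max_set_size = 200) {
  stats <- read_marker_stats(marker_stats)
  map <- read_snp_map(snp_map)
  sets <- read_gene_sets(gene_sets, min_set_size, max_set_size)
  gsa <- read_gsa_pvalues(gsa_pvalues)
  unmapped <- setdiff(unique(stats$marker), map$marker)
  if (length(unmapped))
    stop(length(unmapped), " marker(s) in the stats are not in the SNP map, e.g. ",
         unmapped[1])
  mapped_genes <- unique(map$gene)
  empty <- names(sets)[!vapply(sets, function(g)
    any(g %in% mapped_genes), logical(1))]
  if (length(empty))
    stop("gene set(s) without any mapped gene: ",
         paste(empty, collapse = ", "))
  if (!all(unique(stats$study) %in% colnames(gsa)))
    stop("study ids of marker stats and GSA p-values are inconsistent")
  list(marker_stats = stats, snp_map = map, gene_sets = sets,
       gsa_p = gsa, ld = if (!is.null(ld)) read_ld_table(ld))
}

#' Write META-GSA results
#'
#' Tab-separated output with a deterministic column order, sorted by the
#' corrected p-value and then by gene-set id; per-study weights are
#' JSON-encoded in the last column. An empty result yields a header-only
#' file.
#'
#' @param results data.frame from [run_meta_gsa()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  cols <- c("gene_set", "n_genes", "m0", "p_permut", "n_perm_used",
            "pi0", "p_meta", "eff_studies")
  x <- results[, cols, drop = FALSE]
  w <- attr(results, "weights")
  x$weights <- if (nrow(x))
    vapply(x$gene_set, function(g)
      as.character(jsonlite::toJSON(as.list(w[[g]]$weights),
                                    auto_unbox = TRUE, digits = NA)), character(1))
  else character(0)
  x <- x[order(x$p_meta, x$gene_set), , drop = FALSE]
  for (col in c("m0", "p_permut", "pi0", "p_meta", "eff_studies"))
    x[[col]] <- sprintf("%.17g", x[[col]])
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
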