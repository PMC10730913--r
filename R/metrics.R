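#' Median gene sensitivity
#'
#' Sensitivity of each gene is its mean count per cell; the summary statistic
#' is the median of these per-gene means, so high expressors do not dominate.
#' Control features (per the matrix's `feature_categories` attribute) are
#' excluded.
#'
#' @param m cells x features count matrix.
#' @return median over genes of mean counts per cell.
#' @export
median_gene_sensitivity <- function(m) {
  m <- gene_matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix")
  stats::median(Matrix::colMeans(m))
}

#' Library complexity: genes covering a fraction of total counts
#'
#' The smallest number of genes whose summed counts reach `fraction` of the
#' grand total; a low value means a few genes dominate the library.
#'
#' @param m cells x features count matrix.
#' @param fraction target fraction of total counts (default 0.5).
#' @return gene count (integer).
#' @export
complexity_genes_for_fraction <- function(m, fraction = 0.5) {
  m <- gene_matrix(m)
  tot <- Matrix::colSums(m)
  g <- sum(tot)
  if (g <= 0) stop("total counts are zero")
  cs <- cumsum(sort(tot, decreasing = TRUE))
  as.integer(which(cs >= fraction * g)[1])
}

#' Per-cell QC summary
#'
#' Transcripts per cell (row sums), genes detected per cell (row-wise nonzero
#' counts) and their 10th/50th/90th percentiles. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param m cells x features count matrix (control columns excluded via
#'   [gene_matrix()]).
#' @return a `qc_summary` list.
#' @export
per_cell_stats <- function(m) {
  m <- gene_matrix(m)
  if (nrow(m) == 0L) stop("no cells")
  tx <- Matrix::rowSums(m)
  genes <- Matrix::rowSums(m > 0)
  q <- stats::quantile(tx, c(0.1, 0.5, 0.9), type = 7)
  structure(list(
    total_cells = nrow(m),
    total_transcripts = sum(tx),
    transcripts_per_cell_p10 = unname(q[1]),
    transcripts_per_cell_median = unname(q[2]),
    transcripts_per_cell_p90 = unname(q[3]),
    genes_per_cell_median = unname(stats::median(genes))),
    class = "qc_summary")
}

#' Control category rates among filtered transcripts
#'
#' Fraction of (quality-filtered) transcript calls falling in each control
#' category: negative control probes estimate assay-level non-specific
#' binding, negative control codewords estimate decoder false assignments.
#'
#' @param decoded a `decoded_transcripts` data.frame (already quality
#'   filtered).
#' @param codebook the `codebook` (categories must be represented).
#' @return named numeric vector of per-category fractions (all four
#'   categories).
#' @export
control_rates <- function(decoded, codebook) {
  n <- nrow(decoded)
  if (n == 0L) stop("no transcripts")
  vapply(codebook_categories(), function(cat) {
    sum(decoded$category == cat) / n
  }, numeric(1))
}

#' Downsample a count matrix by binomial thinning
#'
#' Applies independent binomial thinning with a single global retention
#' probability `p = target_mean_per_cell * n_cells / grand_total`, so the
#' expected grand total equals `target_mean_per_cell * n_cells`. Zero entries
#' stay zero exactly.
#'
#' @param m cells x features count matrix.
#' @param target_mean_per_cell desired mean counts per cell after thinning.
#' @param seed integer seed.
#' @return thinned sparse matrix of the same shape.
#' @export
downsample_counts <- function(m, target_mean_per_cell, seed = 1L) {
  g <- sum(m)
  cur <- g / nrow(m)
  if (target_mean_per_cell > cur) stop("target exceeds current mean per cell")
  p <- target_mean_per_cell / cur
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  out@x <- as.numeric(stats::rbinom(length(out@x), size = as.integer(out@x), prob = p))
  out <- Matrix::drop0(out)
  attr(out, "feature_categories") <- attr(m, "feature_categories")
  out
}

#' Replicate concordance (squared Pearson correlation of pseudobulk)
#'
#' Per-gene totals of the two datasets are compared on the log scale:
#' `r^2` of `log10(total + 1)` over shared features (or raw totals with
#' `log_scale = FALSE`).
#'
#' @param m1,m2 cells x features count matrices sharing feature names.
#' @param log_scale compare log10(total+1) (default) or raw totals.
#' @return squared Pearson correlation.
#' @export
replicate_concordance <- function(m1, m2, log_scale = TRUE) {
  shared <- intersect(colnames(m1), colnames(m2))
  if (length(shared) < 2L) stop("need at least 2 shared features")
  t1 <- Matrix::colSums(m1[, shared, drop = FALSE])
  t2 <- Matrix::colSums(m2[, shared, drop = FALSE])
  if (log_scale) { t1 <- log10(t1 + 1); t2 <- log10(t2 + 1) }
  if (stats::sd(t1) == 0 || stats::sd(t2) == 0) stop("zero variance in pseudobulk totals")
  stats::cor(t1, t2)^2
}

#' Full QC report
#'
#' Combines per-cell statistics, sensitivity, complexity and control rates
#' into one summary (the numbers a run report would print).
#'
#' @param m cells x features count matrix (with control columns).
#' @param decoded quality-filtered `decoded_transcripts` (for control rates);
#'   optional.
#' @param codebook the `codebook`; required with `decoded`.
#' @return a `qc_summary` list.
#' @export
qc_report <- function(m, decoded = NULL, codebook = NULL) {
  out <- per_cell_stats(m)
  out$median_gene_sensitivity <- median_gene_sensitivity(m)
  out$complexity_genes_50pct <- complexity_genes_for_fraction(m, 0.5)
  if (!is.null(decoded)) {
    if (is.null(codebook)) stop("codebook required to compute control rates")
    cr <- control_rates(decoded, codebook)
    out$neg_control_probe_fraction <- unname(cr["negative_control_probe"])
    out$neg_control_codeword_fraction <- unname(cr["negative_control_codeword"])
  }
  class(out) <- "qc_summary"
  out
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC summary\n")
  for (f in names(x)) cat(sprintf("  %-32s %s\n", f, format(x[[f]], digits = 6)))
  invisible(x)
}

#' Write a QC summary as JSON
#' @param x a `qc_summary`.
#' @param path output path.
#' @export
write_qc_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
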