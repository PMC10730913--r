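#' Calibrate raw Q-scores against negative control codewords
#'
#' Raw Phred scores are calibrated bin-wise by the rate at which the decoder
#' calls negative control codewords (codebook entries with no matching probe):
#' within each raw-Q bin the per-control-codeword false-call rate is
#' `(n_ncc + pseudocount) / N_ncc_codes`, the implied false discovery rate
#' among gene calls is `min(1, rate * N_gene_codes / max(1, n_gene_calls))`,
#' and the bin's calibrated score is `min(q_cap, -10*log10(FDR))`. A weighted
#' pool-adjacent-violators pass enforces that calibrated quality is
#' non-decreasing in raw quality. Bins with fewer than `min_bin_calls` calls
#' are merged with their neighbor before estimation.
#'
#' @param decoded a `decoded_transcripts` data.frame from [decode_ml()].
#' @param codebook the `codebook` used to decode (must contain at least one
#'   negative control codeword).
#' @param n_bins equal-width bins over `[0, q_cap]` (default 20).
#' @param q_cap Phred cap (default 40).
#' @param min_bin_calls minimum calls per bin before merging (default 50).
#' @param pseudocount added to the control-codeword count in each bin; keeps
#'   empty bins finite and conservative (default 1).
#' @return list with `table` (a `calibration_table` data.frame: bin_lo, bin_hi,
#'   n_total, n_ncc, n_gene, fdr, qv) and `decoded` with `qv` filled.
#' @export
calibrate <- function(decoded, codebook, n_bins = 20L, q_cap = 40,
                      min_bin_calls = 50L, pseudocount = 1) {
  n_ncc_codes <- sum(codebook$categories == "negative_control_codeword")
  if (n_ncc_codes == 0L) stop("codebook has no negative control codewords")
  if (nrow(decoded) == 0L) stop("no decoded transcripts to calibrate")
  n_gene_codes <- sum(codebook$categories == "gene")

  edges <- seq(0, q_cap, length.out = n_bins + 1L)
  bin <- findInterval(decoded$raw_q, edges, rightmost.closed = TRUE, all.inside = TRUE)

  # merge sparse bins left-to-right until each group reaches min_bin_calls
  counts <- tabulate(bin, nbins = n_bins)
  group <- integer(n_bins)
  g <- 1L; acc <- 0L
  for (b in seq_len(n_bins)) {
    group[b] <- g
    acc <- acc + counts[b]
    if (acc >= min_bin_calls && b < n_bins) { g <- g + 1L; acc <- 0L }
  }
  # fold a trailing underfull group into its predecessor
  if (g > 1L && acc < min_bin_calls) group[group == g] <- g - 1L
  ids <- sort(unique(group))
  gid <- match(group[bin], ids)
  k <- length(ids)

  is_ncc <- decoded$category == "negative_control_codeword"
  is_gene <- decoded$category == "gene"
  n_total <- tabulate(gid, nbins = k)
  n_ncc <- tabulate(gid[is_ncc], nbins = k)
  n_gene <- tabulate(gid[is_gene], nbins = k)

  rate <- (n_ncc + pseudocount) / n_ncc_codes
  fdr <- pmin(1, rate * n_gene_codes / pmax(1, n_gene))
  qv <- pmin(q_cap, -10 * log10(fdr))

  # weighted PAVA: qv non-decreasing in raw_q
  qv <- pava_increasing(qv, w = pmax(n_total, 1))
  qv <- pmin(q_cap, qv)

  lo <- edges[ids]
  hi <- edges[vapply(ids, function(g) max(which(group == g)), integer(1)) + 1L]
  table <- data.frame(bin_lo = lo, bin_hi = hi, n_total = n_total,
                      n_ncc = n_ncc, n_gene = n_gene, fdr = fdr, qv = qv)
  class(table) <- c("calibration_table", "data.frame")
  decoded$qv <- qv[gid]
  list(table = table, decoded = decoded)
}

# Weighted pool-adjacent-violators for a non-decreasing fit.
pava_increasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1L) return(y)
  val <- numeric(0); wt <- numeric(0); len <- integer(0)
  for (i in seq_len(n)) {
    val <- c(val, y[i]); wt <- c(wt, w[i]); len <- c(len, 1L)
    k <- length(val)
    while (k > 1L && val[k - 1L] > val[k] + 1e-12) {
      nv <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / (wt[k - 1L] + wt[k])
      val <- c(val[seq_len(k - 2L)], nv)
      wt <- c(wt[seq_len(k - 2L)], wt[k - 1L] + wt[k])
      len <- c(len[seq_len(k - 2L)], len[k - 1L] + len[k])
      k <- length(val)
    }
  }
  rep(val, len)
}

#' Apply calibrated quality to a new set of transcripts
#'
#' Looks each transcript's raw Q up in an existing calibration table; applying
#' the table is idempotent and independent of which transcripts were used to
#' estimate it.
#'
#' @param decoded a `decoded_transcripts` data.frame.
#' @param table a `calibration_table`.
#' @return `decoded` with `qv` filled from the table.
#' @export
apply_calibration <- function(decoded, table) {
  edges <- c(table$bin_lo, table$bin_hi[nrow(table)])
  gid <- findInterval(decoded$raw_q, edges, rightmost.closed = TRUE, all.inside = TRUE)
  decoded$qv <- table$qv[gid]
  decoded
}

#' Filter transcripts by calibrated quality
#'
#' Downstream analyses (cell-feature matrix, metrics, integration) use only
#' transcripts whose calibrated Phred quality meets the threshold; the default
#' threshold of 20 corresponds to a nominal 1% decoding error.
#'
#' @param decoded a `decoded_transcripts` data.frame with `qv` filled.
#' @param threshold Phred threshold (default 20).
#' @return the subset with `qv >= threshold`, order preserved.
#' @export
apply_q_filter <- function(decoded, threshold = 20) {
  if (anyNA(decoded$qv)) stop("qv missing: run calibrate() first")
  decoded[decoded$qv >= threshold, , drop = FALSE]
}
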