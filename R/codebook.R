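#' Build a combinatorial fluorescence codebook
#'
#' Constructs a constant-weight binary codebook over a `n_cycles` x `n_channels`
#' bit grid by seeded randomized greedy search with rejection. Each code turns
#' exactly `weight` bits on and every pair of codes differs in at least
#' `min_hamming` bit positions, so that single-bit dropouts or spurious signals
#' cannot convert one codeword into another. Besides gene codes, three control
#' classes are carried: negative control probes (real probes targeting
#' non-biological sequence; structurally identical to gene codes), negative
#' control codewords (codebook entries with no matching probe, used to estimate
#' the decoder's false-assignment rate and to calibrate quality scores) and
#' unassigned codewords (unused spare codes).
#'
#' Bits are flattened row-major, cycle-then-channel, with 0-based cycle and
#' channel indices: bit `k` (1-based column of the code matrix) corresponds to
#' cycle `(k-1) %/% n_channels` and channel `(k-1) %% n_channels`.
#'
#' @param n_genes number of gene codes.
#' @param n_neg_probe number of negative control probe codes.
#' @param n_neg_codeword number of negative control codewords.
#' @param n_unassigned number of unassigned (spare) codewords.
#' @param n_cycles imaging cycles (default 15).
#' @param n_channels color channels per cycle (default 4).
#' @param weight on-bits per code (default 4).
#' @param min_hamming minimum pairwise Hamming distance (default 4).
#' @param seed integer seed; the search is bitwise reproducible given the seed.
#' @param gene_names optional character vector of gene names (length `n_genes`).
#' @param max_attempts cap on total random draws before declaring the
#'   configuration infeasible.
#' @return An object of class `codebook`: a list with `codes` (0/1 integer
#'   matrix, one row per code, `n_cycles * n_channels` columns), `names`,
#'   `categories` (factor with levels gene, negative_control_probe,
#'   negative_control_codeword, unassigned), and the geometry parameters.
#' @export
build_codebook <- function(n_genes,
                           n_neg_probe = 0L,
                           n_neg_codeword = 0L,
                           n_unassigned = 0L,
                           n_cycles = 15L,
                           n_channels = 4L,
                           weight = 4L,
                           min_hamming = 4L,
                           seed = 1L,
                           gene_names = NULL,
                           max_attempts = NULL) {
  n_bits <- n_cycles * n_channels
  if (weight > n_bits) stop("weight exceeds number of bits (n_cycles * n_channels)")
  if (weight < 1L) stop("weight must be >= 1")
  n_codes <- n_genes + n_neg_probe + n_neg_codeword + n_unassigned
  if (n_codes < 1L) stop("at least one code must be requested")
  if (is.null(max_attempts)) max_attempts <- 500L * n_codes

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  codes <- matrix(0L, nrow = n_codes, ncol = n_bits)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_codes && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- integer(n_bits)
    cand[sample.int(n_bits, weight)] <- 1L
    if (accepted > 0L) {
      # Hamming distance to accepted codes; constant weight makes this cheap
      d <- rowSums(abs(codes[seq_len(accepted), , drop = FALSE] -
                         matrix(cand, accepted, n_bits, byrow = TRUE)))
      if (min(d) < min_hamming) next
    }
    accepted <- accepted + 1L
    codes[accepted, ] <- cand
  }
  if (accepted < n_codes) {
    stop(sprintf(
      "codebook infeasible: placed %d of %d codes within %d attempts (weight=%d, min_hamming=%d, bits=%d)",
      accepted, n_codes, max_attempts, weight, min_hamming, n_bits))
  }

  categories <- factor(
    rep(c("gene", "negative_control_probe", "negative_control_codeword", "unassigned"),
        times = c(n_genes, n_neg_probe, n_neg_codeword, n_unassigned)),
    levels = codebook_categories())
  if (is.null(gene_names)) {
    gene_names <- sprintf("Gene%03d", seq_len(n_genes))
  } else if (length(gene_names) != n_genes) {
    stop("gene_names must have length n_genes")
  }
  names_all <- c(gene_names,
                 sprintf("NegControlProbe_%05d", seq_len(n_neg_probe)),
                 sprintf("NegControlCodeword_%05d", seq_len(n_neg_codeword)),
                 sprintf("UnassignedCodeword_%05d", seq_len(n_unassigned)))
  if (anyDuplicated(names_all)) stop("feature names must be unique")

  structure(
    list(codes = codes, names = names_all, categories = categories,
         n_cycles = as.integer(n_cycles), n_channels = as.integer(n_channels),
         weight = as.integer(weight), min_hamming = as.integer(min_hamming),
         seed = as.integer(seed)),
    class = "codebook")
}

codebook_categories <- function() {
  c("gene", "negative_control_probe", "negative_control_codeword", "unassigned")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d codes over %d cycles x %d channels (weight %d, min Hamming %d)\n",
              nrow(x$codes), x$n_cycles, x$n_channels, x$weight, x$min_hamming))
  print(table(x$categories))
  invisible(x)
}

#' Minimum pairwise Hamming distance of a codebook
#'
#' Validator for the constraint that every pair of codewords (gene and control
#' alike) is separated by the codebook's declared minimum distance.
#'
#' @param codebook a `codebook` object (>= 2 codes).
#' @return the minimum Hamming distance over all unordered code pairs.
#' @export
min_pairwise_hamming <- function(codebook) {
  codes <- codebook$codes
  n <- nrow(codes)
  if (n < 2L) stop("min_pairwise_hamming needs at least 2 codes")
  # For 0/1 codes, d(i,j) = w_i + w_j - 2 <c_i, c_j>
  g <- tcrossprod(codes)
  w <- diag(g)
  d <- outer(w, w, "+") - 2 * g
  min(d[upper.tri(d)])
}

#' Serialize a codebook to JSON
#'
#' The on-disk format mirrors a gene-panel JSON: a header with the grid
#' geometry and one entry per code with its name, category and on-bit list as
#' `[cycle, channel]` pairs (0-based).
#'
#' @param codebook a `codebook`.
#' @param path output file path.
#' @export
write_codebook_json <- function(codebook, path) {
  entries <- lapply(seq_len(nrow(codebook$codes)), function(i) {
    on <- which(codebook$codes[i, ] == 1L) - 1L
    list(name = codebook$names[i],
         category = as.character(codebook$categories[i]),
         code = lapply(on, function(k) {
           c(k %/% codebook$n_channels, k %% codebook$n_channels)
         }))
  })
  obj <- list(
    header = list(n_cycles = codebook$n_cycles, n_channels = codebook$n_channels,
                  weight = codebook$weight, min_hamming = codebook$min_hamming,
                  seed = codebook$seed),
    entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a codebook from JSON
#'
#' @param path a file written by [write_codebook_json()].
#' @return a `codebook`.
#' @export
read_codebook_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- obj$header
  n_bits <- h$n_cycles * h$n_channels
  n <- length(obj$entries)
  codes <- matrix(0L, n, n_bits)
  nms <- character(n)
  cats <- character(n)
  for (i in seq_len(n)) {
    e <- obj$entries[[i]]
    nms[i] <- e$name
    cats[i] <- e$category
    for (cc in e$code) {
      k <- as.integer(cc[[1]]) * h$n_channels + as.integer(cc[[2]]) + 1L
      codes[i, k] <- 1L
    }
  }
  structure(
    list(codes = codes, names = nms,
         categories = factor(cats, levels = codebook_categories()),
         n_cycles = as.integer(h$n_cycles), n_channels = as.integer(h$n_channels),
         weight = as.integer(h$weight), min_hamming = as.integer(h$min_hamming),
         seed = as.integer(h$seed)),
    class = "codebook")
}

# Save/restore the global RNG stream so seeded helpers do not perturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
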