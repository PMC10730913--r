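# Independent naive oracles used to cross-check the vectorized implementations.

# Naive per-observation, per-code decoder: explicit loop over codes with
# per-bit Gaussian log-density summation, posterior by direct softmax.
oracle_decode <- function(obs, cb, model, q_cap = 40, floor = 1e-6) {
  n <- length(obs$x)
  out_code <- integer(n)
  out_q <- numeric(n)
  for (i in seq_len(n)) {
    y <- log(pmax(obs$intensity[i, ], floor))
    ll <- numeric(nrow(cb$codes))
    for (k in seq_len(nrow(cb$codes))) {
      mu <- ifelse(cb$codes[k, ] == 1, model$mu_on, model$mu_off)
      sd <- ifelse(cb$codes[k, ] == 1, model$sigma_on, model$sigma_off)
      ll[k] <- sum(dnorm(y, mu, sd, log = TRUE))
    }
    best <- which(ll == max(ll))[1]
    p <- exp(ll - max(ll))
    p <- p / sum(p)
    out_code[i] <- best
    out_q[i] <- min(q_cap, -10 * log10(max(1 - p[best], 0)))
  }
  list(code_id = out_code, raw_q = out_q)
}

# Vector-space nearest-nucleus assignment operating on the same nucleus masks
# the raster pipeline sees: brute-force exact Euclidean distance from each
# point to every nucleus pixel center (um), cap at `cap`, ties to lower label.
oracle_nearest_nucleus <- function(x, y, nuclei, cap = 15, chunk = 500L) {
  px <- nuclei$pixel_size
  idx <- which(nuclei$labels > 0L, arr.ind = TRUE)
  sx <- (idx[, 2] - 0.5) * px
  sy <- (idx[, 1] - 0.5) * px
  lab <- nuclei$labels[idx]
  n <- length(x)
  out <- integer(n)
  for (start in seq(1, n, by = chunk)) {
    sel <- start:min(n, start + chunk - 1L)
    d2 <- outer(x[sel]^2 + y[sel]^2, sx^2 + sy^2, "+") -
      2 * (outer(x[sel], sx) + outer(y[sel], sy))
    for (ii in seq_along(sel)) {
      md <- min(d2[ii, ])
      out[sel[ii]] <- if (sqrt(max(md, 0)) <= cap) min(lab[d2[ii, ] <= md + 1e-9]) else 0L
    }
  }
  out
}

oracle_median_sensitivity <- function(m) {
  m <- as.matrix(m)
  means <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, j]
    means[j] <- s / nrow(m)
  }
  median(means)
}

oracle_complexity <- function(m, fraction = 0.5) {
  tot <- sort(colSums(as.matrix(m)), decreasing = TRUE)
  target <- fraction * sum(tot)
  acc <- 0
  for (k in seq_along(tot)) {
    acc <- acc + tot[k]
    if (acc >= target) return(k)
  }
  length(tot)
}

# Small fixtures -------------------------------------------------------------

tiny_codebook <- function(n_genes = 20, n_ncp = 2, n_ncc = 5, n_un = 2, seed = 3) {
  build_codebook(n_genes, n_neg_probe = n_ncp, n_neg_codeword = n_ncc,
                 n_unassigned = n_un, seed = seed)
}

tiny_config <- function(cb, seed = 7, n_cells = 15, field = c(150, 150),
                        mean_tx = 50, p_dropout = 0.02, p_spurious = 0.005,
                        background_rate = 5, n_types = 2) {
  types <- make_cell_types(cb$names[cb$categories == "gene"], n_types = n_types)
  sim_config(seed = seed, field_um = field, n_cells = n_cells,
             cell_types = types,
             transcripts_per_cell = c(mean = mean_tx, size = 3),
             background_rate = background_rate,
             noise = list(mu_on = log(1000), sigma_on = 0.4,
                          mu_off = log(50), sigma_off = 0.4,
                          p_dropout = p_dropout, p_spurious = p_spurious))
}

# One punctum_obs batch built directly from codewords (no simulator), with
# exact on/off intensities; useful for noise-free contracts.
exact_obs <- function(cb, code_ids, mu_on = log(1000), mu_off = log(50),
                      x = NULL, y = NULL) {
  n <- length(code_ids)
  inten <- matrix(exp(mu_off), n, ncol(cb$codes))
  for (i in seq_len(n)) inten[i, cb$codes[code_ids[i], ] == 1] <- exp(mu_on)
  structure(list(x = if (is.null(x)) runif(n, 0, 100) else x,
                 y = if (is.null(y)) runif(n, 0, 100) else y,
                 z = rep(0, n), intensity = inten, true_code = code_ids,
                 n_cycles = cb$n_cycles, n_channels = cb$n_channels),
            class = "punctum_obs")
}
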