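#' Log-intensity noise model for bit states
#'
#' Independent Gaussian model on log-intensity: an "on" bit (the fluorophore
#' for this cycle/channel is bound) emits `exp(N(mu_on, sigma_on^2))` photons,
#' an "off" bit `exp(N(mu_off, sigma_off^2))`. Decoding scores each codeword by
#' the product of per-bit densities under the states the codeword dictates.
#'
#' @param mu_on,sigma_on log-intensity mean and sd of on bits.
#' @param mu_off,sigma_off log-intensity mean and sd of off bits.
#' @return a `noise_model`.
#' @export
noise_model <- function(mu_on, sigma_on, mu_off, sigma_off) {
  if (sigma_on <= 0 || sigma_off <= 0) stop("sigmas must be positive")
  if (mu_on <= mu_off) stop("mu_on must exceed mu_off")
  structure(list(mu_on = mu_on, sigma_on = sigma_on,
                 mu_off = mu_off, sigma_off = sigma_off),
            class = "noise_model")
}

#' Noise model from a simulation configuration
#' @param config a `sim_config`.
#' @return a `noise_model` with the config's log-intensity parameters.
#' @export
noise_model_from_config <- function(config) {
  nz <- config$noise
  noise_model(nz$mu_on, nz$sigma_on, nz$mu_off, nz$sigma_off)
}

#' Estimate a noise model from observed intensities
#'
#' Two-component moment matching on the pooled log-intensities: a 2-means
#' split separates on from off bits, and each component's mean/sd become the
#' model parameters. Useful when the acquisition parameters are unknown.
#'
#' @param intensity matrix of positive intensities (observations x bits).
#' @return a `noise_model`.
#' @export
estimate_noise_model <- function(intensity) {
  y <- log(pmax(as.numeric(intensity), .Machine$double.eps))
  km <- stats::kmeans(y, centers = range(y), iter.max = 50)
  hi <- which.max(km$centers)
  on <- y[km$cluster == hi]; off <- y[km$cluster != hi]
  noise_model(mean(on), max(stats::sd(on), 1e-3),
              mean(off), max(stats::sd(off), 1e-3))
}

#' Log-likelihood of one codeword for one observation
#'
#' Sum over all cycle/channel bits of the Gaussian log-density of the
#' observed log-intensity under the on/off state the codeword dictates.
#'
#' @param intensity numeric vector (flattened cycles x channels, row-major
#'   cycle-then-channel) or matrix of one observation's intensities.
#' @param code 0/1 vector or matrix of the same length.
#' @param model a `noise_model`.
#' @param floor intensity floor applied before taking logs.
#' @return scalar log-likelihood.
#' @export
loglik_code <- function(intensity, code, model, floor = 1e-6) {
  intensity <- as.numeric(intensity)
  code <- as.numeric(code)
  if (length(intensity) != length(code)) stop("dimension mismatch between intensity and code")
  y <- log(pmax(intensity, floor))
  sum(ifelse(code == 1,
             stats::dnorm(y, model$mu_on, model$sigma_on, log = TRUE),
             stats::dnorm(y, model$mu_off, model$sigma_off, log = TRUE)))
}

#' Decode puncta to transcripts by maximum likelihood
#'
#' Scores every codebook entry (genes and all control classes, uniform prior)
#' for every observation and assigns the maximizer; ties broken by lowest code
#' id. The raw Phred-style quality is derived from the posterior probability of
#' the winning codeword, `raw_q = min(q_cap, -10*log10(1 - p_best))`, where
#' `p_best` is the softmax of the per-code log-likelihoods. A confident call
#' (large likelihood margin over the runner-up) approaches `q_cap`; an
#' observation exactly ambiguous between two codes gets
#' `-10*log10(0.5) ~ 3.01`.
#'
#' @param obs a `punctum_obs` batch (see [simulate_signals()] /
#'   [detect_puncta()]).
#' @param codebook a `codebook`.
#' @param model a `noise_model`.
#' @param q_cap Phred cap for raw quality (default 40).
#' @param floor intensity floor before logs.
#' @return a `decoded_transcripts` data.frame: transcript_id, code_id, feature,
#'   category, x, y, z, raw_q, qv (NA until calibration), cell_id (NA until
#'   assignment), and true_code when present in `obs`.
#' @export
decode_ml <- function(obs, codebook, model, q_cap = 40, floor = 1e-6) {
  if (nrow(codebook$codes) == 0L) stop("empty codebook")
  n <- length(obs$x)
  n_bits <- ncol(codebook$codes)
  if (n > 0L && ncol(obs$intensity) != n_bits)
    stop("observation intensity dimensions do not match codebook geometry")
  if (n == 0L) {
    out <- data.frame(transcript_id = integer(0), code_id = integer(0),
                      feature = character(0), category = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      raw_q = numeric(0), qv = numeric(0), cell_id = integer(0))
    class(out) <- c("decoded_transcripts", "data.frame")
    return(out)
  }
  y <- log(pmax(obs$intensity, floor))
  A <- stats::dnorm(y, model$mu_on, model$sigma_on, log = TRUE)    # on-state per bit
  B <- stats::dnorm(y, model$mu_off, model$sigma_off, log = TRUE)  # off-state per bit
  # loglik(i, k) = sum_b B[i,b] + sum_b (A-B)[i,b] * code[k,b]
  L <- rowSums(B) + (A - B) %*% t(codebook$codes)
  best <- max.col(L, ties.method = "first")
  m <- L[cbind(seq_len(n), best)]
  lse_all <- m + log(rowSums(exp(L - m)))
  # log(1 - p_best) computed from the runner-up mass for numerical stability
  Lo <- L
  Lo[cbind(seq_len(n), best)] <- -Inf
  m2 <- apply(Lo, 1, max)
  lse_others <- ifelse(is.finite(m2), m2 + log(rowSums(exp(Lo - m2))), -Inf)
  log10_1mp <- (lse_others - lse_all) / log(10)
  raw_q <- pmin(q_cap, -10 * log10_1mp)
  out <- data.frame(
    transcript_id = seq_len(n),
    code_id = best,
    feature = codebook$names[best],
    category = as.character(codebook$categories[best]),
    x = obs$x, y = obs$y, z = obs$z,
    raw_q = raw_q, qv = NA_real_, cell_id = NA_integer_,
    stringsAsFactors = FALSE)
  if (!is.null(obs$true_code)) out$true_code <- obs$true_code
  class(out) <- c("decoded_transcripts", "data.frame")
  out
}
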