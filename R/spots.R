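#' Detect puncta and estimate sub-pixel centers and per-bit intensities
#'
#' Candidate puncta are local maxima of the max-projection over all cycles and
#' channels that rise at least `min_prominence` above the local background
#' (the median of the fit-window perimeter). Each candidate is refined by a
#' least-squares 2D isotropic Gaussian fit (amplitude, center, sigma, offset)
#' in a `fit_window` pixel window; fits that fail to converge or whose sigma
#' exceeds `max_sigma` are discarded as non-punctate. Per-bit intensities are
#' the weighted least-squares Gaussian amplitudes read from every
#' cycle/channel plane at the fitted center.
#'
#' @param stack numeric array, dim c(n_cycles, n_channels, H, W) (nonnegative).
#' @param pixel_size micrometers per pixel.
#' @param min_prominence detection threshold above local background.
#' @param fit_window odd window size in pixels (default 7).
#' @param max_sigma maximum fitted sigma, pixels (default 3).
#' @return a `punctum_obs` batch with sub-pixel `x`, `y` in micrometers,
#'   `intensity` (n x n_bits amplitude matrix), and per-detection `fit_sigma`
#'   and `fit_residual`.
#' @export
detect_puncta <- function(stack, pixel_size, min_prominence,
                          fit_window = 7L, max_sigma = 3) {
  d <- dim(stack)
  if (length(d) != 4L) stop("stack must be a 4D array (cycles x channels x H x W)")
  if (any(stack < 0)) stop("stack must be nonnegative")
  if (fit_window < 3L || fit_window %% 2L == 0L) stop("fit_window must be odd and >= 3")
  nc <- d[1]; nch <- d[2]; H <- d[3]; W <- d[4]
  if (H == 0L || W == 0L) stop("empty stack")
  n_bits <- nc * nch
  mp <- apply(stack, c(3, 4), max)
  half <- fit_window %/% 2L

  # local maxima of the max-projection (8-neighborhood), vectorized by shifts
  is_max <- matrix(FALSE, H, W)
  if (H > 2L && W > 2L) {
    core_r <- 2:(H - 1); core_c <- 2:(W - 1)
    center <- mp[core_r, core_c]
    ok <- matrix(TRUE, H - 2L, W - 2L)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      ok <- ok & (center >= mp[core_r + dr, core_c + dc])
    }
    is_max[core_r, core_c] <- ok & (center >= min_prominence)
  }
  cand <- which(is_max, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (r <= half || c <= half || r > H - half || c > W - half) next
    win <- mp[(r - half):(r + half), (c - half):(c + half)]
    bg <- stats::median(window_perimeter(win))
    keep[i] <- (mp[r, c] - bg) >= min_prominence
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- dedupe_plateaus(cand)

  xs <- numeric(0); ys <- numeric(0); sig <- numeric(0); res <- numeric(0)
  amps <- NULL
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rows <- (r - half):(r + half); cols <- (c - half):(c + half)
    win <- mp[rows, cols]
    fit <- fit_gauss2d(win, max_sigma = max_sigma)
    if (is.null(fit)) next
    # fitted center in pixel coordinates (pixel centers at k - 0.5)
    cy <- (rows[1] - 1) + fit$y0
    cx <- (cols[1] - 1) + fit$x0
    # per-plane WLS amplitude at the fitted center/sigma
    gy <- exp(-((seq_along(rows) - 0.5) - fit$y0)^2 / (2 * fit$sigma^2))
    gx <- exp(-((seq_along(cols) - 0.5) - fit$x0)^2 / (2 * fit$sigma^2))
    g <- outer(gy, gx)
    gs2 <- sum(g^2)
    a <- numeric(n_bits)
    for (b in seq_len(n_bits)) {
      cyc <- (b - 1L) %/% nch + 1L; chan <- (b - 1L) %% nch + 1L
      pw <- stack[cyc, chan, rows, cols]
      bg_b <- stats::median(window_perimeter(pw))
      a[b] <- max(sum(g * (pw - bg_b)) / gs2, 1e-6)
    }
    xs <- c(xs, cx * pixel_size); ys <- c(ys, cy * pixel_size)
    sig <- c(sig, fit$sigma); res <- c(res, fit$residual)
    amps <- rbind(amps, a)
  }
  if (is.null(amps)) amps <- matrix(numeric(0), 0, n_bits)
  structure(list(x = xs, y = ys, z = rep(0, length(xs)),
                 intensity = unname(amps), fit_sigma = sig, fit_residual = res,
                 n_cycles = nc, n_channels = nch),
            class = "punctum_obs")
}

# Keep one representative per connected plateau of equal-valued maxima.
dedupe_plateaus <- function(cand, min_sep = 2) {
  if (nrow(cand) <= 1L) return(cand)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand) - 1L)) {
    if (!keep[i]) next
    j <- (i + 1L):nrow(cand)
    close <- abs(cand[j, 1] - cand[i, 1]) <= min_sep &
      abs(cand[j, 2] - cand[i, 2]) <= min_sep
    keep[j[close]] <- FALSE
  }
  cand[keep, , drop = FALSE]
}

window_perimeter <- function(win) {
  n <- nrow(win); m <- ncol(win)
  c(win[1, ], win[n, ], win[2:(n - 1), 1], win[2:(n - 1), m])
}

# Least-squares isotropic 2D Gaussian fit on a small window.
# Returns NULL when the optimizer fails or the fitted sigma is out of range.
fit_gauss2d <- function(win, max_sigma) {
  n <- nrow(win); m <- ncol(win)
  yy <- matrix(seq_len(n) - 0.5, n, m)
  xx <- matrix(rep(seq_len(m) - 0.5, each = n), n, m)
  bg0 <- stats::median(window_perimeter(win))
  peak <- which.max(win)
  a0 <- max(win[peak] - bg0, 1e-3)
  y00 <- yy[peak]; x00 <- xx[peak]
  obj <- function(p) {
    a <- p[1]; x0 <- p[2]; y0 <- p[3]; s <- p[4]; b <- p[5]
    mu <- b + a * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * s^2))
    sum((win - mu)^2)
  }
  fit <- try(stats::optim(c(a0, x00, y00, 1, bg0), obj, method = "L-BFGS-B",
                          lower = c(1e-6, 0, 0, 0.3, -Inf),
                          upper = c(Inf, m, n, max(n, m), Inf)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) return(NULL)
  p <- fit$par
  if (p[4] > max_sigma) return(NULL)
  list(amplitude = p[1], x0 = p[2], y0 = p[3], sigma = p[4], offset = p[5],
       residual = sqrt(fit$value / (n * m)))
}
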