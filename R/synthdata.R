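#' Simulation configuration
#'
#' Bundles the parameters of the forward simulator: field geometry, cell-type
#' expression profiles, per-cell transcript abundance, optical noise and the
#' point-spread function. The defaults describe a dense epithelial tissue
#' imaged at high magnification: ~5 um nuclei inside ~10 um cells, a
#' negative-binomial transcript load with mean 166 per cell, log-normal on/off
#' bit intensities well separated in log space, and a small rate of
#' non-specific background puncta.
#'
#' @param seed integer seed governing all randomness downstream.
#' @param field_um field of view, c(width, height) in micrometers.
#' @param pixel_size micrometers per pixel (default 0.5).
#' @param n_cells number of cells to place.
#' @param cell_types list of cell types; each a list with `name`, `profile`
#'   (named nonnegative numeric vector of mean expression per gene) and
#'   `proportion`. Proportions must sum to 1.
#' @param nucleus_radius c(mean, sd) of nucleus radius, um.
#' @param cell_radius c(mean, sd) of cell radius, um.
#' @param transcripts_per_cell c(mean, size) of the negative binomial
#'   transcript count per cell (`size` is the NB dispersion parameter).
#' @param background_rate expected false puncta per 100x100 um tile.
#' @param noise list with log-intensity parameters `mu_on`, `sigma_on`,
#'   `mu_off`, `sigma_off` and per-bit flip probabilities `p_dropout`
#'   (on-bit lost) and `p_spurious` (off-bit lit).
#' @param psf_sigma point-spread function sigma in pixels.
#' @param loc_sd localization jitter applied to punctum positions, um.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       field_um = c(500, 500),
                       pixel_size = 0.5,
                       n_cells = 100L,
                       cell_types = NULL,
                       nucleus_radius = c(mean = 5, sd = 0.5),
                       cell_radius = c(mean = 10, sd = 1),
                       transcripts_per_cell = c(mean = 166, size = 3),
                       background_rate = 5,
                       noise = list(mu_on = log(1000), sigma_on = 0.4,
                                    mu_off = log(50), sigma_off = 0.4,
                                    p_dropout = 0.02, p_spurious = 0.005),
                       psf_sigma = 1.0,
                       loc_sd = 0.05) {
  stopifnot(pixel_size > 0, all(field_um > 0), psf_sigma > 0)
  if (!is.null(cell_types)) {
    props <- vapply(cell_types, `[[`, numeric(1), "proportion")
    if (abs(sum(props) - 1) > 1e-8) stop("cell type proportions must sum to 1")
    for (ct in cell_types) {
      if (any(ct$profile < 0)) stop("expression profiles must be nonnegative")
    }
  }
  if (noise$mu_on <= noise$mu_off) stop("mu_on must exceed mu_off")
  if (background_rate < 0) stop("background_rate must be >= 0")
  structure(list(seed = as.integer(seed), field_um = field_um,
                 pixel_size = pixel_size, n_cells = as.integer(n_cells),
                 cell_types = cell_types, nucleus_radius = nucleus_radius,
                 cell_radius = cell_radius,
                 transcripts_per_cell = transcripts_per_cell,
                 background_rate = background_rate, noise = noise,
                 psf_sigma = psf_sigma, loc_sd = loc_sd),
            class = "sim_config")
}

#' Well-separated default cell-type profiles
#'
#' Convenience builder for simulations: assigns each type a disjoint block of
#' marker genes expressed at `marker_level` on top of a uniform baseline.
#'
#' @param gene_names gene names to spread markers over.
#' @param n_types number of cell types.
#' @param marker_level mean expression of a type's markers.
#' @param baseline mean expression of non-marker genes.
#' @param markers_per_type markers per type.
#' @return list suitable for `sim_config(cell_types=)`.
#' @export
make_cell_types <- function(gene_names, n_types = 3L, marker_level = 20,
                            baseline = 0.2, markers_per_type = 10L) {
  n_genes <- length(gene_names)
  if (n_types * markers_per_type > n_genes)
    stop("not enough genes for the requested marker blocks")
  lapply(seq_len(n_types), function(t) {
    prof <- stats::setNames(rep(baseline, n_genes), gene_names)
    idx <- ((t - 1L) * markers_per_type + 1L):(t * markers_per_type)
    prof[idx] <- marker_level
    list(name = sprintf("Type%02d", t), profile = prof,
         proportion = 1 / n_types)
  })
}

#' Simulate a dissociated single-cell reference
#'
#' Emulates a whole-transcriptome (here: panel-restricted) single-cell
#' reference: each cell draws a type by the configured proportions and then,
#' independently per gene, a negative binomial count around the type mean.
#' The NB `size` is taken from `config$transcripts_per_cell["size"]`.
#'
#' @param config a `sim_config` with at least one cell type.
#' @param n_ref_cells number of reference cells.
#' @return list with `counts` (cells x genes sparse dgCMatrix) and `labels`
#'   (character vector of type names).
#' @export
simulate_reference <- function(config, n_ref_cells) {
  if (is.null(config$cell_types) || length(config$cell_types) == 0L)
    stop("config$cell_types is empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  types <- config$cell_types
  gene_names <- names(types[[1]]$profile)
  props <- vapply(types, `[[`, numeric(1), "proportion")
  size <- unname(config$transcripts_per_cell["size"])
  type_idx <- sample.int(length(types), n_ref_cells, replace = TRUE, prob = props)
  counts <- matrix(0L, n_ref_cells, length(gene_names),
                   dimnames = list(sprintf("refcell%05d", seq_len(n_ref_cells)),
                                   gene_names))
  for (t in seq_along(types)) {
    rows <- which(type_idx == t)
    if (!length(rows)) next
    mu <- types[[t]]$profile
    draw <- vapply(mu, function(m) {
      if (m == 0) integer(length(rows))
      else as.integer(stats::rnbinom(length(rows), mu = m, size = size))
    }, integer(length(rows)))
    if (length(rows) == 1L) draw <- matrix(draw, nrow = 1L)
    counts[rows, ] <- draw
  }
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       labels = vapply(types, `[[`, character(1), "name")[type_idx])
}

#' Simulate a ground-truth tissue
#'
#' Places `n_cells` non-overlapping circular cells (concentric circular nuclei)
#' in the field by bounded rejection sampling, draws each cell's transcript
#' count from the configured negative binomial and scatters the transcripts
#' uniformly inside the cell boundary, with genes drawn in proportion to the
#' cell type's expression profile. Background (non-specific) puncta are
#' scattered uniformly over the field at `background_rate` per 100x100 um,
#' drawing their feature uniformly from gene plus negative-control-probe codes.
#'
#' @param config a `sim_config`.
#' @param codebook optional `codebook`; needed only to include negative control
#'   probes in the background draw.
#' @return a `ground_truth` list with `cells` (data.frame: cell_id, type, x, y,
#'   nucleus_radius, cell_radius) and `transcripts` (data.frame:
#'   transcript_id, gene, x, y, z, cell_id; cell_id 0 = background).
#' @export
simulate_tissue <- function(config, codebook = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  W <- config$field_um[1]; H <- config$field_um[2]
  n <- config$n_cells
  types <- config$cell_types
  if (n > 0L && (is.null(types) || length(types) == 0L))
    stop("config$cell_types is empty")

  cells <- data.frame(cell_id = integer(0), type = character(0),
                      x = numeric(0), y = numeric(0),
                      nucleus_radius = numeric(0), cell_radius = numeric(0))
  if (n > 0L) {
    props <- vapply(types, `[[`, numeric(1), "proportion")
    type_idx <- sample.int(length(types), n, replace = TRUE, prob = props)
    rn <- pmax(1, stats::rnorm(n, config$nucleus_radius["mean"], config$nucleus_radius["sd"]))
    rc <- pmax(rn + 0.5, stats::rnorm(n, config$cell_radius["mean"], config$cell_radius["sd"]))
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      i <- placed + 1L
      x <- stats::runif(1, rc[i], W - rc[i])
      y <- stats::runif(1, rc[i], H - rc[i])
      ok <- TRUE
      if (placed > 0L) {
        j <- seq_len(placed)
        ok <- all((xs[j] - x)^2 + (ys[j] - y)^2 >= (rc[j] + rc[i])^2)
      }
      if (ok) { xs[i] <- x; ys[i] <- y; placed <- i }
    }
    if (placed < n) stop(sprintf("placement failed: %d of %d cells after %d attempts",
                                 placed, n, max_attempts))
    cells <- data.frame(
      cell_id = seq_len(n),
      type = vapply(types, `[[`, character(1), "name")[type_idx],
      x = xs, y = ys, nucleus_radius = rn, cell_radius = rc,
      stringsAsFactors = FALSE)
  }

  tx_list <- vector("list", n + 1L)
  mu <- unname(config$transcripts_per_cell["mean"])
  size <- unname(config$transcripts_per_cell["size"])
  if (n > 0L) {
    n_tx <- stats::rnbinom(n, mu = mu, size = size)
    for (i in seq_len(n)) {
      k <- n_tx[i]
      if (k == 0L) next
      # uniform in the cell disc
      r <- cells$cell_radius[i] * sqrt(stats::runif(k))
      th <- stats::runif(k, 0, 2 * pi)
      prof <- types[[match(cells$type[i], vapply(types, `[[`, character(1), "name"))]]$profile
      genes <- if (sum(prof) == 0) character(0) else
        sample(names(prof), k, replace = TRUE, prob = prof)
      if (!length(genes)) next
      tx_list[[i]] <- data.frame(
        gene = genes,
        x = cells$x[i] + r * cos(th), y = cells$y[i] + r * sin(th),
        z = 0, cell_id = i, stringsAsFactors = FALSE)
    }
  }
  # background false puncta
  n_bg <- stats::rpois(1, config$background_rate * (W / 100) * (H / 100))
  if (n_bg > 0L) {
    bg_features <- if (!is.null(codebook)) {
      codebook$names[codebook$categories %in% c("gene", "negative_control_probe")]
    } else if (!is.null(types)) names(types[[1]]$profile) else character(0)
    if (length(bg_features)) {
      tx_list[[n + 1L]] <- data.frame(
        gene = sample(bg_features, n_bg, replace = TRUE),
        x = stats::runif(n_bg, 0, W), y = stats::runif(n_bg, 0, H),
        z = 0, cell_id = 0L, stringsAsFactors = FALSE)
    }
  }
  tx <- do.call(rbind, tx_list[!vapply(tx_list, is.null, logical(1))])
  if (is.null(tx)) tx <- data.frame(gene = character(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    cell_id = integer(0))
  if (nrow(tx)) tx <- cbind(transcript_id = seq_len(nrow(tx)), tx)
  else tx <- cbind(transcript_id = integer(0), tx)
  structure(list(cells = cells, transcripts = tx, field_um = config$field_um),
            class = "ground_truth")
}

#' Rasterize nuclei to a label image
#'
#' Produces the nucleus label image the segmentation stage takes as input
#' (the equivalent of a DAPI-based nucleus segmentation): pixel (row, col)
#' covers the half-open square `[col, col+1) x [row, row+1)` in pixel units,
#' x rightward, y downward, origin at (0, 0) um. A pixel is labeled with a
#' nucleus id if its center lies inside that nucleus.
#'
#' @param truth a `ground_truth`.
#' @param config the `sim_config` used to build it (for field and pixel size).
#' @return a `nucleus_label_image`: list(labels = integer matrix (rows = y),
#'   pixel_size).
#' @export
rasterize_nuclei <- function(truth, config) {
  px <- config$pixel_size
  W <- ceiling(config$field_um[1] / px)
  H <- ceiling(config$field_um[2] / px)
  labels <- matrix(0L, H, W)
  cx <- (seq_len(W) - 0.5) * px
  cy <- (seq_len(H) - 0.5) * px
  for (i in seq_len(nrow(truth$cells))) {
    r <- truth$cells$nucleus_radius[i]
    jx <- which(abs(cx - truth$cells$x[i]) <= r)
    jy <- which(abs(cy - truth$cells$y[i]) <= r)
    if (!length(jx) || !length(jy)) next
    d2 <- outer(cy[jy] - truth$cells$y[i], cx[jx] - truth$cells$x[i],
                function(a, b) a^2 + b^2)
    inside <- d2 <= r^2
    sub <- labels[jy, jx, drop = FALSE]
    sub[inside] <- i  # nuclei are disjoint by construction (cells do not overlap)
    labels[jy, jx] <- sub
  }
  structure(list(labels = labels, pixel_size = px), class = "nucleus_label_image")
}

#' Simulate cycle-by-channel optical signals
#'
#' The forward model the decoder inverts: each ground-truth transcript emits
#' one punctum whose bit states start from its codeword; each on-bit is lost
#' with probability `p_dropout` and each off-bit lit with `p_spurious`.
#' Per-bit intensities are log-normal around `mu_on`/`mu_off`, positions are
#' jittered by isotropic Gaussian localization noise.
#'
#' @param truth a `ground_truth`.
#' @param codebook a `codebook` covering every feature in `truth`.
#' @param config a `sim_config`.
#' @return a `punctum_obs` batch: list with `x`, `y`, `z` (um), `intensity`
#'   (n_obs x n_bits matrix), `true_code` (row index into the codebook) and
#'   the grid geometry.
#' @export
simulate_signals <- function(truth, codebook, config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)
  tx <- truth$transcripts
  code_idx <- match(tx$gene, codebook$names)
  if (anyNA(code_idx)) {
    stop("unknown gene name(s): ", paste(utils::head(unique(tx$gene[is.na(code_idx)])), collapse = ", "))
  }
  n <- nrow(tx)
  n_bits <- ncol(codebook$codes)
  nz <- config$noise
  bits <- codebook$codes[code_idx, , drop = FALSE]
  flip_on <- matrix(stats::runif(n * n_bits) < nz$p_dropout, n, n_bits)
  flip_off <- matrix(stats::runif(n * n_bits) < nz$p_spurious, n, n_bits)
  state <- bits
  state[bits == 1L & flip_on] <- 0L
  state[bits == 0L & flip_off] <- 1L
  logi <- matrix(stats::rnorm(n * n_bits, mean = ifelse(state == 1L, nz$mu_on, nz$mu_off),
                              sd = ifelse(state == 1L, nz$sigma_on, nz$sigma_off)),
                 n, n_bits)
  structure(list(
    x = tx$x + stats::rnorm(n, 0, config$loc_sd),
    y = tx$y + stats::rnorm(n, 0, config$loc_sd),
    z = rep(0, n),
    intensity = exp(logi),
    true_code = code_idx,
    n_cycles = codebook$n_cycles, n_channels = codebook$n_channels),
    class = "punctum_obs")
}

#' Render observations to an image stack
#'
#' Draws each punctum as an isotropic 2D Gaussian (sigma = `config$psf_sigma`
#' pixels, peak amplitude = the punctum's per-bit intensity) summed onto a
#' cycles x channels x H x W stack. With `shot_noise = TRUE`, pixel values are
#' replaced by Poisson draws.
#'
#' @param obs a `punctum_obs` batch.
#' @param config a `sim_config`.
#' @param shot_noise add Poisson shot noise (default FALSE).
#' @return numeric array, dim c(n_cycles, n_channels, H, W).
#' @export
render_image_stack <- function(obs, config, shot_noise = FALSE) {
  px <- config$pixel_size
  if (px <= 0) stop("pixel_size must be positive")
  W <- ceiling(config$field_um[1] / px)
  H <- ceiling(config$field_um[2] / px)
  nc <- obs$n_cycles; nch <- obs$n_channels
  stack <- array(0, dim = c(nc, nch, H, W))
  n <- length(obs$x)
  if (n == 0L) return(stack)
  s <- config$psf_sigma
  halfw <- max(3L, ceiling(4 * s))
  # punctum centers in pixel coordinates (pixel centers at k - 0.5)
  pxx <- obs$x / px; pyy <- obs$y / px
  for (i in seq_len(n)) {
    j0 <- floor(pxx[i]) + 1L; i0 <- floor(pyy[i]) + 1L
    jj <- max(1L, j0 - halfw):min(W, j0 + halfw)
    ii <- max(1L, i0 - halfw):min(H, i0 + halfw)
    if (!length(jj) || !length(ii)) next
    gx <- exp(-((jj - 0.5) - pxx[i])^2 / (2 * s^2))
    gy <- exp(-((ii - 0.5) - pyy[i])^2 / (2 * s^2))
    g <- outer(gy, gx)
    for (b in seq_len(nc * nch)) {
      amp <- obs$intensity[i, b]
      if (amp <= 0) next
      cyc <- (b - 1L) %/% nch + 1L; chan <- (b - 1L) %% nch + 1L
      stack[cyc, chan, ii, jj] <- stack[cyc, chan, ii, jj] + amp * g
    }
  }
  if (shot_noise) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed + 3L)
    stack[] <- stats::rpois(length(stack), stack)
  }
  stack
}

#' Simulate landmark pairs under a known transform
#'
#' Generates paired coordinates for registration benchmarks: inliers satisfy
#' `dst = transform(src) + N(0, jitter)`; outliers receive uniformly random
#' destinations over the destination bounding field.
#'
#' @param transform a `coord_transform` (see [make_similarity_transform()]).
#' @param n number of pairs.
#' @param outlier_fraction fraction in `[0, 1)` of outlier pairs.
#' @param jitter isotropic Gaussian jitter sd, um.
#' @param seed integer seed.
#' @param field c(width, height) um of the source field.
#' @return list with `src`, `dst` (n x 2 matrices) and `inlier` (logical).
#' @export
simulate_landmarks <- function(transform, n, outlier_fraction = 0,
                               jitter = 0, seed = 1L, field = c(1000, 1000)) {
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  if (n < 4L) stop("need at least 4 landmark pairs")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  src <- cbind(stats::runif(n, 0, field[1]), stats::runif(n, 0, field[2]))
  dst <- apply_transform(transform, src)
  n_out <- round(n * outlier_fraction)
  inlier <- rep(TRUE, n)
  if (jitter > 0) dst <- dst + matrix(stats::rnorm(2 * n, 0, jitter), n, 2)
  if (n_out > 0L) {
    idx <- sample.int(n, n_out)
    inlier[idx] <- FALSE
    rng_x <- range(dst[, 1]); rng_y <- range(dst[, 2])
    dst[idx, 1] <- stats::runif(n_out, rng_x[1], rng_x[2])
    dst[idx, 2] <- stats::runif(n_out, rng_y[1], rng_y[2])
  }
  list(src = src, dst = dst, inlier = inlier)
}
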