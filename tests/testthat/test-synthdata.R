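test_that("simulated reference matches configured negative-binomial means", {
  gene_names <- sprintf("Gene%03d", 1:40)
  types <- list(
    list(name = "A", profile = setNames(c(rep(10, 20), rep(0, 20)), gene_names),
         proportion = 0.5),
    list(name = "B", profile = setNames(c(rep(0, 20), rep(10, 20)), gene_names),
         proportion = 0.5))
  cfg <- sim_config(seed = 4, cell_types = types,
                    transcripts_per_cell = c(mean = 100, size = 3))
  ref <- simulate_reference(cfg, 1000)
  expect_equal(dim(ref$counts), c(1000, 40))
  z_all <- numeric(0)
  for (ty in c("A", "B")) {
    rows <- ref$labels == ty
    prof <- types[[match(ty, c("A", "B"))]]$profile
    mean_obs <- Matrix::colMeans(ref$counts[rows, ])
    # NB variance mu + mu^2/size; standard error of the sample mean
    se <- sqrt((prof + prof^2 / 3) / sum(rows))
    expect_true(all(mean_obs[prof == 0] == 0))
    z_all <- c(z_all, abs(mean_obs[prof > 0] - prof[prof > 0]) / se[prof > 0])
  }
  # 40 marker comparisons: most within 3 SE, none beyond 4.5 SE
  expect_gte(mean(z_all <= 3), 0.9)
  expect_lt(max(z_all), 4.5)
  # determinism
  ref2 <- simulate_reference(cfg, 1000)
  expect_identical(as.matrix(ref$counts), as.matrix(ref2$counts))
})

test_that("all-zero profiles give an all-zero reference", {
  types <- list(list(name = "Z", profile = setNames(rep(0, 5), paste0("g", 1:5)),
                     proportion = 1))
  cfg <- sim_config(seed = 1, cell_types = types)
  ref <- simulate_reference(cfg, 20)
  expect_equal(sum(ref$counts), 0)
  cfg_empty <- sim_config(seed = 1, cell_types = NULL)
  expect_error(simulate_reference(cfg_empty, 10), "empty")
})

test_that("simulated tissue respects geometry and abundance", {
  cb <- tiny_codebook()
  # empty tissue
  cfg0 <- tiny_config(cb, n_cells = 0, background_rate = 0)
  t0 <- simulate_tissue(cfg0, cb)
  expect_equal(nrow(t0$transcripts), 0)
  # single cell: containment by construction
  cfg1 <- tiny_config(cb, n_cells = 1, mean_tx = 100, background_rate = 0)
  t1 <- simulate_tissue(cfg1, cb)
  d <- sqrt((t1$transcripts$x - t1$cells$x)^2 + (t1$transcripts$y - t1$cells$y)^2)
  expect_true(all(d <= t1$cells$cell_radius + 1e-9))
  # many cells: mean transcripts per cell within 3 SE of the NB mean
  cfg2 <- tiny_config(cb, n_cells = 200, field = c(900, 900), mean_tx = 60,
                      background_rate = 0)
  t2 <- simulate_tissue(cfg2, cb)
  per_cell <- tabulate(t2$transcripts$cell_id, nbins = 200)
  se <- sqrt((60 + 60^2 / 3) / 200)
  expect_lt(abs(mean(per_cell) - 60), 3 * se)
  # nuclei disjoint: raster labels never collide
  nuc <- rasterize_nuclei(t2, cfg2)
  expect_true(all(nuc$labels >= 0))
  # cells do not overlap, so every transcript is inside its own cell only
  own <- sqrt((t2$transcripts$x - t2$cells$x[t2$transcripts$cell_id])^2 +
                (t2$transcripts$y - t2$cells$y[t2$transcripts$cell_id])^2)
  expect_true(all(own <= t2$cells$cell_radius[t2$transcripts$cell_id] + 1e-9))
})

test_that("signal simulation reproduces codewords in the noise-free limit and flips bits at the configured rates", {
  cb <- tiny_codebook()
  cfg <- tiny_config(cb, n_cells = 10, mean_tx = 40, background_rate = 0,
                     p_dropout = 0, p_spurious = 0)
  cfg$noise$sigma_on <- 1e-9; cfg$noise$sigma_off <- 1e-9
  truth <- simulate_tissue(cfg, cb)
  obs <- simulate_signals(truth, cb, cfg)
  expect_equal(length(obs$x), nrow(truth$transcripts))
  thresh <- exp((cfg$noise$mu_on + cfg$noise$mu_off) / 2)
  bits <- (obs$intensity > thresh) + 0L
  expect_equal(unname(bits), unname(cb$codes[obs$true_code, ]))

  # dropout rate: fraction of puncta with >= 1 dropped on-bit ~ 1 - (1-p)^w
  cfg2 <- tiny_config(cb, seed = 12, n_cells = 60, field = c(400, 400),
                      mean_tx = 80, background_rate = 0,
                      p_dropout = 0.05, p_spurious = 0)
  cfg2$noise$sigma_on <- 1e-9; cfg2$noise$sigma_off <- 1e-9
  truth2 <- simulate_tissue(cfg2, cb)
  obs2 <- simulate_signals(truth2, cb, cfg2)
  bits2 <- (obs2$intensity > thresh) + 0L
  n_on <- rowSums(bits2 * cb$codes[obs2$true_code, ])
  frac_dropped <- mean(n_on < 4)
  p_exp <- 1 - 0.95^4
  n <- length(obs2$x)
  expect_lt(abs(frac_dropped - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # degenerate limit: total dropout leaves no on-bits
  cfg3 <- tiny_config(cb, n_cells = 5, mean_tx = 20, background_rate = 0,
                      p_dropout = 1, p_spurious = 0)
  cfg3$noise$sigma_on <- 1e-9; cfg3$noise$sigma_off <- 1e-9
  truth3 <- simulate_tissue(cfg3, cb)
  obs3 <- simulate_signals(truth3, cb, cfg3)
  expect_true(all(obs3$intensity < thresh))

  expect_error(simulate_signals(list(transcripts = data.frame(
    gene = "NotAGene", x = 1, y = 1, z = 0, cell_id = 1)), cb, cfg),
    "unknown gene")
})

test_that("count conservation: observations = cell transcripts + background puncta", {
  cb <- tiny_codebook()
  cfg <- tiny_config(cb, n_cells = 30, field = c(300, 300), background_rate = 20)
  truth <- simulate_tissue(cfg, cb)
  obs <- simulate_signals(truth, cb, cfg)
  n_bg <- sum(truth$transcripts$cell_id == 0)
  n_cellular <- sum(truth$transcripts$cell_id > 0)
  expect_gt(n_bg, 0)
  expect_equal(length(obs$x), n_bg + n_cellular)
})

test_that("pseudobulk gene proportions converge to the configured mixture", {
  gene_names <- sprintf("g%02d", 1:30)
  types <- make_cell_types(gene_names, n_types = 3, markers_per_type = 10,
                           marker_level = 15, baseline = 0.5)
  cfg <- sim_config(seed = 31, cell_types = types,
                    transcripts_per_cell = c(mean = 100, size = 5))
  ref <- simulate_reference(cfg, 1000)  # ~1e5 transcripts
  obs_prop <- Matrix::colSums(ref$counts) / sum(ref$counts)
  # expected proportions: equal-weight mixture of type profiles
  mix <- Reduce(`+`, lapply(types, function(t) t$profile * t$proportion))
  exp_prop <- mix / sum(mix)
  # per-gene total variance under the NB mixture (law of total variance):
  # E_t[var NB] + Var_t(mu), per cell, summed over cells
  within <- Reduce(`+`, lapply(types, function(t) {
    t$proportion * (t$profile + t$profile^2 / 5)
  }))
  between <- Reduce(`+`, lapply(types, function(t) {
    t$proportion * (t$profile - mix)^2
  }))
  n_cells <- nrow(ref$counts)
  sd_tot <- sqrt(n_cells * (within + between))
  se_prop <- sd_tot / sum(ref$counts)
  expect_true(all(abs(obs_prop - exp_prop) <= 3 * se_prop + 1e-3))
})

test_that("rendered stacks place Gaussians with the configured total intensity", {
  cb <- tiny_codebook()
  cfg <- tiny_config(cb, n_cells = 0, background_rate = 0)
  cfg$field_um <- c(30, 30)
  empty <- structure(list(x = numeric(0), y = numeric(0), z = numeric(0),
                          intensity = matrix(0, 0, 60), true_code = integer(0),
                          n_cycles = 15, n_channels = 4), class = "punctum_obs")
  st0 <- render_image_stack(empty, cfg)
  expect_equal(sum(st0), 0)

  one <- exact_obs(cb, 1L, x = 14.3, y = 17.7)
  st <- render_image_stack(one, cfg)
  on_bits <- which(cb$codes[1, ] == 1)
  for (b in on_bits) {
    cyc <- (b - 1) %/% 4 + 1; chan <- (b - 1) %% 4 + 1
    plane <- st[cyc, chan, , ]
    pk <- which(plane == max(plane), arr.ind = TRUE)[1, ]
    # argmax pixel within 1 pixel of the true position
    expect_lt(abs((pk[2] - 0.5) * cfg$pixel_size - 14.3), 1 * cfg$pixel_size)
    expect_lt(abs((pk[1] - 0.5) * cfg$pixel_size - 17.7), 1 * cfg$pixel_size)
    # integrated intensity ~ amplitude * 2*pi*sigma^2 within 1%
    expect_lt(abs(sum(plane) - exp(log(1000)) * 2 * pi * cfg$psf_sigma^2) /
                (exp(log(1000)) * 2 * pi * cfg$psf_sigma^2), 0.01)
  }
})

test_that("landmark simulation satisfies its construction guarantees", {
  ident <- make_similarity_transform(0, 1, c(0, 0))
  lm0 <- simulate_landmarks(ident, 50, outlier_fraction = 0, jitter = 0, seed = 2)
  expect_equal(lm0$src, lm0$dst)
  t <- make_similarity_transform(2.58, 1, c(10, -5))
  lm <- simulate_landmarks(t, 100, outlier_fraction = 0.3, jitter = 0.5, seed = 8)
  pred <- apply_transform(t, lm$src)
  resid <- sqrt(rowSums((pred - lm$dst)^2))
  expect_equal(sum(lm$inlier), 70)
  expect_true(all(resid[lm$inlier] <= 3 * 0.5))
  lm2 <- simulate_landmarks(t, 100, outlier_fraction = 0.3, jitter = 0.5, seed = 8)
  expect_identical(lm, lm2)
  expect_error(simulate_landmarks(t, 2, seed = 1), "at least 4")
  expect_error(simulate_landmarks(t, 50, outlier_fraction = 1, seed = 1),
               "outlier_fraction")
})
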