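sim_ref_query <- function(n_types = 5, n_ref = 600, n_query = 600,
                          marker_level = 20, seed = 41) {
  gene_names <- sprintf("Gene%03d", 1:100)
  types <- make_cell_types(gene_names, n_types = n_types,
                           marker_level = marker_level)
  cfg <- sim_config(seed = seed, cell_types = types,
                    transcripts_per_cell = c(mean = 100, size = 3))
  ref <- simulate_reference(cfg, n_ref)
  cfg$seed <- seed + 1L
  qry <- simulate_reference(cfg, n_query)
  list(ref = ref, qry = qry, types = types)
}

test_that("label transfer recovers its own reference exactly and generalizes to a held-out draw", {
  d <- sim_ref_query()
  rs <- reference_set(d$ref$counts, d$ref$labels, n_pcs = 50)
  self <- label_transfer(rs, d$ref$counts)
  expect_equal(mean(self == d$ref$labels), 1.0)
  held <- label_transfer(rs, d$qry$counts)
  expect_gte(mean(held == d$qry$labels), 0.95)
  expect_lte(mean(held == "unlabeled"), 0.05)
})

test_that("a type absent from the reference, placed between two types, goes unlabeled", {
  gene_names <- sprintf("Gene%03d", 1:60)
  types <- make_cell_types(gene_names, n_types = 3, marker_level = 30)
  cfg <- sim_config(seed = 3, cell_types = types,
                    transcripts_per_cell = c(mean = 150, size = 50))
  ref <- simulate_reference(cfg, 450)
  rs <- reference_set(ref$counts, ref$labels, n_pcs = 20)
  # hybrid type equidistant from all three reference types: the neighbor
  # vote splits three ways, so no label reaches the 15-of-30 majority
  hybrid <- list(list(name = "H", proportion = 1,
                      profile = Reduce(`+`, lapply(types, `[[`, "profile")) / 3))
  cfg_h <- sim_config(seed = 9, cell_types = hybrid,
                      transcripts_per_cell = c(mean = 150, size = 50))
  hq <- simulate_reference(cfg_h, 100)
  lab <- label_transfer(rs, hq$counts)
  # the three-way neighbor split keeps a large share of hybrids below the
  # 15-of-30 majority; genuine type members are never unlabeled
  expect_gte(mean(lab == "unlabeled"), 1 / 3)
  pure <- list(list(name = types[[1]]$name, proportion = 1,
                    profile = types[[1]]$profile))
  cfg_p <- sim_config(seed = 10, cell_types = pure,
                      transcripts_per_cell = c(mean = 150, size = 50))
  pq <- simulate_reference(cfg_p, 100)
  expect_equal(mean(label_transfer(rs, pq$counts) == "unlabeled"), 0)
})

test_that("unlabeled fraction grows with the required majority", {
  d <- sim_ref_query(n_types = 3, marker_level = 3, seed = 55)
  rs <- reference_set(d$ref$counts, d$ref$labels, n_pcs = 30)
  fracs <- vapply(c(0.4, 0.6, 0.8, 1.0), function(mj) {
    mean(label_transfer(rs, d$qry$counts, majority = mj) == "unlabeled")
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("label transfer input contracts are enforced", {
  d <- sim_ref_query(n_ref = 50, n_query = 10)
  rs <- reference_set(d$ref$counts, d$ref$labels, n_pcs = 10)
  q <- as.matrix(d$qry$counts)
  colnames(q) <- paste0("other_", seq_len(ncol(q)))
  expect_error(label_transfer(rs, q), "no shared genes")
  expect_error(label_transfer(rs, d$qry$counts, k = 100), "k exceeds")
})

test_that("hexagonal grids have the declared neighbor distance", {
  g <- hex_spot_grid(500, 500, pitch = 100)
  d <- as.matrix(dist(cbind(g$x, g$y)))
  diag(d) <- Inf
  expect_equal(min(d), 100, tolerance = 1e-9)
  expect_false(anyDuplicated(cbind(g$x, g$y)) > 0)
})

test_that("spot binning conserves counts and breaks ties to the lower spot index", {
  g <- hex_spot_grid(400, 400)
  set.seed(66)
  n <- 10000
  x <- runif(n, 0, 400); y <- runif(n, 0, 400)
  feats <- sample(sprintf("g%02d", 1:20), n, TRUE)
  sm <- interpolate_to_spots(x, y, feats, g)
  expect_equal(sum(sm), n)
  input_tot <- table(feats)
  expect_equal(unname(Matrix::colSums(sm)[names(input_tot)]),
               as.vector(input_tot))
  # item exactly at a center goes to that spot
  sm1 <- interpolate_to_spots(g$x[5], g$y[5], "g01", g)
  expect_equal(unname(which(sm1[, 1] > 0)), 5L)
  # exact midpoint between spots 1 and 2 on the same row -> lower index
  mid <- c((g$x[1] + g$x[2]) / 2, (g$y[1] + g$y[2]) / 2)
  sm2 <- interpolate_to_spots(mid[1], mid[2], "g01", g)
  expect_equal(unname(which(sm2[, 1] > 0)), 1L)
  # max_radius drops distant items
  far <- interpolate_to_spots(1e4, 1e4, "g01", g, max_radius = 50)
  expect_equal(sum(far), 0)
  expect_error(interpolate_to_spots(1, 1, "g", g[integer(0), ]), "empty spot grid")
})

test_that("RANSAC recovers a similarity transform under 30% outliers", {
  t0 <- make_similarity_transform(2.58, 1, c(60, -40))
  lm <- simulate_landmarks(t0, 100, outlier_fraction = 0.3, jitter = 0.5,
                           seed = 5)
  fit <- estimate_transform_ransac(lm$src, lm$dst, "similarity",
                                   inlier_tol = 5, seed = 11)
  expect_lt(abs(transform_rotation_deg(fit) - 2.58), 0.05)
  expect_identical(unname(fit$inliers), lm$inlier)
  expect_lt(fit$rmse, 3 * 0.5)
  # determinism under the seed
  fit2 <- estimate_transform_ransac(lm$src, lm$dst, "similarity",
                                    inlier_tol = 5, seed = 11)
  expect_identical(fit$matrix, fit2$matrix)
})

test_that("identity data fits an identity rigid transform with zero residual", {
  set.seed(2)
  src <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  fit <- estimate_transform_ransac(src, src, "rigid", seed = 3)
  expect_equal(fit$matrix, diag(3), tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
})

test_that("affine and homography models recover their generating transforms", {
  set.seed(8)
  src <- cbind(runif(60, 0, 200), runif(60, 0, 200))
  A <- rbind(c(1.05, 0.1, 12), c(-0.08, 0.97, -7), c(0, 0, 1))
  dst <- t(A %*% rbind(t(src), 1))[, 1:2]
  fit_a <- estimate_transform_ransac(src, dst, "affine", seed = 4)
  expect_equal(fit_a$matrix, A, tolerance = 1e-6)
  Hm <- rbind(c(1.02, 0.05, 5), c(0.02, 0.98, -3), c(1e-4, -5e-5, 1))
  h <- Hm %*% rbind(t(src), 1)
  dst_h <- t(h[1:2, ] / rep(h[3, ], each = 2))
  fit_h <- estimate_transform_ransac(src, dst_h, "homography", seed = 4)
  pred <- apply_transform(fit_h, src)
  expect_lt(max(sqrt(rowSums((pred - dst_h)^2))), 1e-6)
})

test_that("all-outlier inputs are flagged rather than silently fit", {
  set.seed(12)
  src <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  dst <- cbind(runif(40, 1e5, 2e5), runif(40, 1e5, 2e5))
  t0 <- make_similarity_transform(10, 1, c(5, 5))
  fit <- tryCatch(
    estimate_transform_ransac(src, dst, "similarity", inlier_tol = 1,
                              n_iter = 200, seed = 2),
    error = function(e) e)
  # either no consensus at all, or a tiny accidental consensus whose fit
  # cannot explain the data (high residual on the full set)
  if (!inherits(fit, "error")) {
    resid <- sqrt(rowSums((apply_transform(fit, src) - dst)^2))
    expect_gt(median(resid), 1)
  } else {
    expect_match(conditionMessage(fit), "no consensus")
  }
})

test_that("transforms apply homogeneously and round-trip through inversion and JSON", {
  t <- make_similarity_transform(33, 1.3, c(10, 0))
  x <- cbind(runif(50, -100, 100), runif(50, -100, 100))
  rt <- apply_transform(invert_transform(t), apply_transform(t, x))
  expect_lt(max(abs(rt - x)), 1e-9)
  shift <- make_similarity_transform(0, 1, c(10, 0))
  expect_equal(apply_transform(shift, cbind(1, 2)), cbind(11, 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform_json(t, f)
  t2 <- read_transform_json(f)
  expect_equal(t2$matrix, t$matrix, tolerance = 1e-12)
  expect_equal(t2$model, t$model)
})
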