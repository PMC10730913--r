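#' Build a label-transfer reference from a single-cell count matrix
#'
#' Normalization pipeline: size-normalize each cell to the reference median
#' total count, `log1p`, z-score each gene across cells, then PCA. The
#' per-gene statistics and PC loadings are retained so query cells can be
#' projected into the same space.
#'
#' @param counts cells x genes matrix (sparse or dense).
#' @param labels per-cell type labels.
#' @param n_pcs number of principal components (default 50).
#' @return a `reference_set`: gene stats, PC loadings, reference PC scores and
#'   labels.
#' @export
reference_set <- function(counts, labels, n_pcs = 50L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(labels)) stop("labels must match rows of counts")
  n_pcs <- min(n_pcs, ncol(counts), nrow(counts) - 1L)
  totals <- rowSums(counts)
  target <- stats::median(totals)
  norm <- log1p(counts / pmax(totals, 1) * target)
  mu <- colMeans(norm)
  sd <- apply(norm, 2, stats::sd)
  sd[sd < 1e-8] <- 1e-8
  z <- sweep(sweep(norm, 2, mu), 2, sd, "/")
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = n_pcs)
  structure(list(genes = colnames(counts), gene_mean = mu, gene_sd = sd,
                 size_target = target, loadings = pca$rotation,
                 scores = pca$x, labels = labels, n_pcs = n_pcs),
            class = "reference_set")
}

#' Transfer cell-type labels by kNN majority vote in PC space
#'
#' Query cells are restricted to the genes shared with the reference,
#' normalized with the reference statistics (same size target, same per-gene
#' mean/sd), projected onto the reference PC loadings, and labeled by their
#' `k` nearest reference cells: a cell receives the most frequent neighbor
#' label if that label accounts for at least `majority` of the neighbors
#' (>= ceiling(majority * k) votes) and the mode is unique; otherwise it is
#' classified "unlabeled".
#'
#' @param ref a `reference_set`.
#' @param query cells x genes count matrix.
#' @param k neighbors (default 30).
#' @param majority required vote fraction (default 0.5).
#' @return character vector of labels ("unlabeled" where the vote fails).
#' @export
label_transfer <- function(ref, query, k = 30L, majority = 0.5) {
  query <- as.matrix(query)
  shared <- intersect(ref$genes, colnames(query))
  if (!length(shared)) stop("no shared genes between reference and query")
  if (k > nrow(ref$scores)) stop("k exceeds reference size")
  gidx <- match(shared, ref$genes)
  totals <- rowSums(query)
  norm <- log1p(query[, shared, drop = FALSE] / pmax(totals, 1) * ref$size_target)
  z <- sweep(sweep(norm, 2, ref$gene_mean[gidx]), 2, ref$gene_sd[gidx], "/")
  qs <- z %*% ref$loadings[gidx, , drop = FALSE]
  rs <- ref$scores
  # squared Euclidean distances query x reference
  d2 <- outer(rowSums(qs^2), rowSums(rs^2), "+") - 2 * tcrossprod(qs, rs)
  need <- ceiling(majority * k)
  out <- character(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(ref$labels[nn])
    top <- max(tab)
    winners <- names(tab)[tab == top]
    out[i] <- if (top >= need && length(winners) == 1L) winners else "unlabeled"
  }
  out
}

#' Hexagonal spot grid
#'
#' Spot centers of a standard capture array: rows `pitch * sqrt(3)/2` apart,
#' odd rows offset by half a pitch, so nearest-neighbor center distance equals
#' `pitch` (default 100 um with 55 um spot diameter).
#'
#' @param width,height extent of the capture area, um.
#' @param pitch center-to-center distance, um (default 100).
#' @param diameter spot diameter, um (default 55; metadata only).
#' @return a `spot_grid` data.frame: spot_id, x, y, array_row, array_col.
#' @export
hex_spot_grid <- function(width, height, pitch = 100, diameter = 55) {
  dy <- pitch * sqrt(3) / 2
  rows <- seq(0, floor(height / dy))
  out <- do.call(rbind, lapply(rows, function(r) {
    x0 <- if (r %% 2 == 1) pitch / 2 else 0
    xs <- seq(x0, width, by = pitch)
    data.frame(x = xs, y = r * dy, array_row = r,
               array_col = seq_along(xs) - 1L)
  }))
  out <- cbind(spot_id = seq_len(nrow(out)), out)
  attr(out, "pitch") <- pitch
  attr(out, "diameter") <- diameter
  class(out) <- c("spot_grid", "data.frame")
  out
}

#' Bin transcripts or cells into spots by proximity
#'
#' Each item is assigned to the nearest spot center (Euclidean; exact ties to
#' the lower spot index). With `max_radius = NULL` every item is binned and
#' total counts are conserved exactly; otherwise items farther than
#' `max_radius` from every center are dropped.
#'
#' @param x,y item coordinates, um.
#' @param feature per-item feature name.
#' @param grid a `spot_grid`.
#' @param max_radius optional capture radius, um.
#' @return sparse spots x features count matrix (rows follow `grid$spot_id`).
#' @export
interpolate_to_spots <- function(x, y, feature, grid, max_radius = NULL) {
  if (nrow(grid) == 0L) stop("empty spot grid")
  n <- length(x)
  feats <- sort(unique(feature))
  if (n == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nrow(grid), length(feats)),
                                dimnames = list(sprintf("spot%05d", grid$spot_id), feats)))
  }
  # nearest spot center per item; ties to lower spot index
  d2 <- outer(x^2 + y^2, grid$x^2 + grid$y^2, "+") -
    2 * (outer(x, grid$x) + outer(y, grid$y))
  nearest <- max.col(-d2, ties.method = "first")
  keep <- rep(TRUE, n)
  if (!is.null(max_radius)) {
    keep <- sqrt(pmax(d2[cbind(seq_len(n), nearest)], 0)) <= max_radius
  }
  Matrix::sparseMatrix(i = nearest[keep], j = match(feature[keep], feats), x = 1,
                       dims = c(nrow(grid), length(feats)),
                       dimnames = list(sprintf("spot%05d", grid$spot_id), feats))
}

#' Construct a similarity transform
#'
#' @param rotation_deg rotation angle, degrees (counterclockwise).
#' @param scale isotropic scale factor.
#' @param translation c(tx, ty), um.
#' @return a `coord_transform` with a 3x3 homogeneous matrix.
#' @export
make_similarity_transform <- function(rotation_deg = 0, scale = 1,
                                      translation = c(0, 0)) {
  th <- rotation_deg * pi / 180
  m <- rbind(c(scale * cos(th), -scale * sin(th), translation[1]),
             c(scale * sin(th),  scale * cos(th), translation[2]),
             c(0, 0, 1))
  new_transform(m, "similarity")
}

new_transform <- function(matrix, model, inliers = NULL, rmse = NA_real_) {
  dimnames(matrix) <- NULL
  if (abs(det(matrix)) < 1e-12) stop("transform matrix is not invertible")
  structure(list(model = model, matrix = matrix, inliers = inliers, rmse = rmse),
            class = "coord_transform")
}

#' Apply a coordinate transform
#'
#' Homogeneous application (with perspective division for homographies);
#' round-trips with the inverse transform to numerical precision.
#'
#' @param t a `coord_transform`.
#' @param coords n x 2 matrix of coordinates.
#' @return transformed n x 2 matrix.
#' @export
apply_transform <- function(t, coords) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  h <- t$matrix %*% rbind(t(coords), 1)
  t(h[1:2, , drop = FALSE] / rep(h[3, ], each = 2))
}

#' Invert a coordinate transform
#' @param t a `coord_transform`.
#' @return the inverse `coord_transform`.
#' @export
invert_transform <- function(t) new_transform(solve(t$matrix), t$model)

#' Rotation angle of a transform
#' @param t a `coord_transform` (rigid/similarity).
#' @return rotation angle in degrees.
#' @export
transform_rotation_deg <- function(t) {
  atan2(t$matrix[2, 1], t$matrix[1, 1]) * 180 / pi
}

# Closed-form least-squares similarity/rigid fit (Umeyama).
fit_similarity <- function(src, dst, fix_scale = FALSE) {
  ms <- colMeans(src); md <- colMeans(dst)
  s0 <- sweep(src, 2, ms); d0 <- sweep(dst, 2, md)
  S <- crossprod(d0, s0) / nrow(src)
  sv <- svd(S)
  D <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% D %*% t(sv$v)
  sc <- if (fix_scale) 1 else sum(diag(D) * sv$d) / mean(rowSums(s0^2))
  tr <- md - sc * as.numeric(R %*% ms)
  rbind(cbind(sc * R, tr), c(0, 0, 1))
}

fit_affine <- function(src, dst) {
  A <- cbind(src, 1)
  cf <- tryCatch(solve(crossprod(A), crossprod(A, dst)), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  rbind(t(cf), c(0, 0, 1))
}

# Normalized direct linear transform for a homography.
fit_homography <- function(src, dst) {
  norm_pts <- function(p) {
    m <- colMeans(p); s <- mean(sqrt(rowSums(sweep(p, 2, m)^2)))
    if (s < 1e-12) return(NULL)
    T <- rbind(c(sqrt(2) / s, 0, -sqrt(2) / s * m[1]),
               c(0, sqrt(2) / s, -sqrt(2) / s * m[2]), c(0, 0, 1))
    list(T = T, p = t(T %*% rbind(t(p), 1))[, 1:2, drop = FALSE])
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  if (is.null(ns) || is.null(nd)) return(NULL)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    xy <- c(ns$p[i, ], 1); uv <- nd$p[i, ]
    A[2 * i - 1, ] <- c(-xy, 0, 0, 0, uv[1] * xy)
    A[2 * i, ] <- c(0, 0, 0, -xy, uv[2] * xy)
  }
  # null vector of A = eigenvector of A'A with smallest eigenvalue
  ev <- eigen(crossprod(A), symmetric = TRUE)
  Hn <- matrix(ev$vectors[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

transform_min_samples <- function(model) {
  switch(model, rigid = 2L, similarity = 2L, affine = 3L, homography = 4L,
         stop("unknown transform model: ", model))
}

fit_model <- function(src, dst, model) {
  out <- switch(model,
                rigid = fit_similarity(src, dst, fix_scale = TRUE),
                similarity = fit_similarity(src, dst),
                affine = fit_affine(src, dst),
                homography = fit_homography(src, dst))
  if (is.null(out) || any(!is.finite(out)) || abs(det(out)) < 1e-12) return(NULL)
  out
}

collinear <- function(p, tol = 1e-6) {
  if (nrow(p) < 3L) {
    return(sum((p[1, ] - p[2, ])^2) < tol^2)
  }
  d <- sweep(p, 2, colMeans(p))
  svd(d)$d[2] < tol
}

#' Estimate a coordinate transform by RANSAC over landmark pairs
#'
#' Repeats minimal-sample fits (2 points for rigid/similarity, 3 affine,
#' 4 homography; degenerate samples skipped), scores each by the consensus of
#' pairs with residual at most `inlier_tol`, and refits the best consensus by
#' least squares on all its inliers.
#'
#' @param src,dst n x 2 matrices of paired coordinates.
#' @param model one of "rigid", "similarity", "affine", "homography".
#' @param inlier_tol residual tolerance, um (default 5).
#' @param n_iter RANSAC iterations (default 1000).
#' @param seed integer seed (sampling is deterministic given the seed).
#' @return a `coord_transform` with `inliers` (logical) and `rmse` on inliers.
#' @export
estimate_transform_ransac <- function(src, dst, model = "similarity",
                                      inlier_tol = 5, n_iter = 1000L,
                                      seed = 1L) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  mreq <- transform_min_samples(model)
  if (n < mreq) stop("insufficient landmark pairs for model ", model)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  best_inl <- NULL; best_n <- -1L; best_rss <- Inf
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, mreq)
    if (collinear(src[idx, , drop = FALSE])) next
    M <- fit_model(src[idx, , drop = FALSE], dst[idx, , drop = FALSE], model)
    if (is.null(M)) next
    pred <- apply_transform(new_transform(M, model), src)
    resid <- sqrt(rowSums((pred - dst)^2))
    inl <- resid <= inlier_tol
    ni <- sum(inl)
    if (ni > best_n || (ni == best_n && sum(resid[inl]^2) < best_rss)) {
      best_n <- ni; best_inl <- inl; best_rss <- sum(resid[inl]^2)
    }
  }
  if (is.null(best_inl) || best_n < mreq)
    stop("RANSAC found no consensus: all pairs appear to be outliers")
  M <- fit_model(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE], model)
  if (is.null(M)) stop("degenerate consensus set")
  t <- new_transform(M, model)
  pred <- apply_transform(t, src)
  resid <- sqrt(rowSums((pred - dst)^2))
  inl <- resid <= inlier_tol
  t$inliers <- inl
  t$rmse <- sqrt(mean(resid[inl]^2))
  t
}

#' Serialize a transform to JSON
#' @param t a `coord_transform`.
#' @param path output path.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(list(model = t$model, matrix = t$matrix, rmse = t$rmse),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a transform from JSON
#' @param path a file written by [write_transform_json()].
#' @return a `coord_transform`.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$matrix), 3, 3)
  new_transform(m, obj$model, rmse = obj$rmse)
}
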