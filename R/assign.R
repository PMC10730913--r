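#' Expand nuclei into distance-capped cell territories
#'
#' Distance-capped generalized Voronoi expansion on the raster: every
#' background pixel within `max_expansion` micrometers (Euclidean distance
#' between pixel centers) of at least one nucleus mask takes the label of the
#' nearest mask; expansion therefore stops at either the distance cap or the
#' territory of a nearer nucleus, and territories never overlap. Distance is
#' measured to the nucleus boundary (the mask), not the centroid. Equidistant
#' ties resolve to the lower label id; pixels farther than the cap from every
#' nucleus stay 0. Nucleus pixels always keep their own label.
#'
#' @param nuclei a `nucleus_label_image` (list with integer `labels` matrix,
#'   rows = y, and `pixel_size` in um/pixel), e.g. from [rasterize_nuclei()].
#' @param max_expansion expansion cap in micrometers (default 15).
#' @return a `cell_segmentation`: list(labels, dist_um (distance of each pixel
#'   to its nucleus), pixel_size, max_expansion).
#' @export
expand_nuclei <- function(nuclei, max_expansion = 15) {
  px <- nuclei$pixel_size
  if (is.null(px) || px <= 0) stop("pixel_size must be positive")
  labels <- nuclei$labels
  if (length(labels) == 0L) stop("empty label image")
  res <- edt_label_capped(labels, max_expansion / px)
  structure(list(labels = res$label, dist_um = sqrt(res$dist2) * px,
                 pixel_size = px, max_expansion = max_expansion),
            class = "cell_segmentation")
}

#' Assign transcripts to cells via a segmentation raster
#'
#' Each transcript receives the label of the raster pixel containing its
#' (x, y) position (half-open pixel intervals, origin at 0 um); positions in
#' background or outside the raster get cell id 0 (unassigned).
#'
#' @param decoded a `decoded_transcripts` data.frame.
#' @param seg a `cell_segmentation`.
#' @return `decoded` with `cell_id` filled.
#' @export
assign_transcripts <- function(decoded, seg) {
  px <- seg$pixel_size
  H <- nrow(seg$labels); W <- ncol(seg$labels)
  col <- floor(decoded$x / px) + 1L
  row <- floor(decoded$y / px) + 1L
  ok <- !is.na(col) & !is.na(row) & col >= 1L & col <= W & row >= 1L & row <= H
  cell <- integer(nrow(decoded))
  cell[ok] <- seg$labels[cbind(row[ok], col[ok])]
  decoded$cell_id <- cell
  decoded
}

#' Build the cell-feature count matrix
#'
#' Tabulates assigned transcripts into a sparse cells x features count matrix
#' covering every codebook feature (gene and control categories alike; control
#' columns are kept for QC and can be dropped with [gene_matrix()]). Unassigned
#' transcripts (cell id 0) are excluded, so the grand total equals the number
#' of assigned transcripts.
#'
#' @param decoded a `decoded_transcripts` data.frame with `cell_id` and `qv`
#'   filled (apply [apply_q_filter()] upstream).
#' @param codebook the `codebook` defining the feature set.
#' @param n_cells number of cell rows; defaults to the largest cell id seen.
#' @return a `cell_feature_matrix`: sparse dgCMatrix (cells x features) with
#'   a `feature_categories` attribute.
#' @export
build_cell_feature_matrix <- function(decoded, codebook, n_cells = NULL) {
  if (anyNA(decoded$cell_id)) stop("cell_id missing: run assign_transcripts() first")
  if (anyDuplicated(decoded$transcript_id)) stop("duplicate transcript ids")
  if (is.null(n_cells)) n_cells <- max(0L, decoded$cell_id)
  keep <- decoded$cell_id > 0L
  fidx <- match(decoded$feature[keep], codebook$names)
  m <- Matrix::sparseMatrix(i = decoded$cell_id[keep], j = fidx, x = 1,
                            dims = c(n_cells, length(codebook$names)),
                            dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                            codebook$names))
  m <- methods::as(m, "CsparseMatrix")
  attr(m, "feature_categories") <- stats::setNames(as.character(codebook$categories),
                                                   codebook$names)
  class(m) <- class(m)  # dgCMatrix with attribute
  m
}

#' Subset a cell-feature matrix to gene features
#'
#' @param m a matrix from [build_cell_feature_matrix()], or any matrix with a
#'   `feature_categories` attribute.
#' @return the columns whose category is `gene`.
#' @export
gene_matrix <- function(m) {
  cats <- attr(m, "feature_categories")
  if (is.null(cats)) return(m)
  out <- m[, names(cats)[cats == "gene"], drop = FALSE]
  attr(out, "feature_categories") <- cats[cats == "gene"]
  out
}

#' Per-cell summary table for a segmentation
#'
#' Centroids and areas of nuclei and expanded territories, in micrometer
#' units, for export alongside the cell-feature matrix.
#'
#' @param nuclei a `nucleus_label_image`.
#' @param seg the matching `cell_segmentation`.
#' @return data.frame: cell_id, x_centroid, y_centroid, nucleus_area, cell_area.
#' @export
cell_summary <- function(nuclei, seg) {
  px <- seg$pixel_size
  n <- max(0L, max(nuclei$labels))
  if (n == 0L) {
    return(data.frame(cell_id = integer(0), x_centroid = numeric(0),
                      y_centroid = numeric(0), nucleus_area = numeric(0),
                      cell_area = numeric(0)))
  }
  idx <- which(nuclei$labels > 0L, arr.ind = TRUE)
  lab <- nuclei$labels[idx]
  xc <- tapply((idx[, 2] - 0.5) * px, lab, mean)
  yc <- tapply((idx[, 1] - 0.5) * px, lab, mean)
  na <- tabulate(lab, nbins = n) * px^2
  ca <- tabulate(seg$labels[seg$labels > 0L], nbins = n) * px^2
  ids <- as.integer(names(xc))
  out <- data.frame(cell_id = seq_len(n), x_centroid = NA_real_,
                    y_centroid = NA_real_, nucleus_area = na, cell_area = ca)
  out$x_centroid[ids] <- as.numeric(xc)
  out$y_centroid[ids] <- as.numeric(yc)
  out
}
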