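#' Write pipeline outputs in the 10x-style on-disk dialect
#'
#' Produces the files a downstream analyst expects from an in situ run:
#' `transcripts.csv` (transcript_id, cell_id, overlaps_nucleus, feature_name,
#' x_location, y_location, z_location, qv), a MatrixMarket MEX triplet
#' (`matrix.mtx`, `features.tsv` with columns id/name/type, `barcodes.tsv`;
#' features as rows, cells as columns) and `cells.csv` (centroids and areas).
#'
#' @param dir output directory (created if missing).
#' @param decoded a `decoded_transcripts` data.frame with `qv` and `cell_id`.
#' @param m a `cell_feature_matrix` (cells x features).
#' @param cells optional cells data.frame from [cell_summary()].
#' @param codebook optional `codebook`, written as `codebook.json`.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(dir, decoded, m, cells = NULL, codebook = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- data.frame(
    transcript_id = decoded$transcript_id,
    cell_id = ifelse(decoded$cell_id > 0L, decoded$cell_id, -1L),
    overlaps_nucleus = rep(0L, nrow(decoded)),
    feature_name = decoded$feature,
    x_location = decoded$x, y_location = decoded$y, z_location = decoded$z,
    qv = decoded$qv)
  data.table::fwrite(tx, file.path(dir, "transcripts.csv"))
  write_mex(m, dir)
  if (!is.null(cells)) data.table::fwrite(cells, file.path(dir, "cells.csv"))
  if (!is.null(codebook)) write_codebook_json(codebook, file.path(dir, "codebook.json"))
  invisible(dir)
}

mex_type_for_category <- function(cat) {
  c(gene = "Gene Expression",
    negative_control_probe = "Negative Control Probe",
    negative_control_codeword = "Negative Control Codeword",
    unassigned = "Unassigned Codeword")[cat]
}

mex_category_for_type <- function(type) {
  c("Gene Expression" = "gene",
    "Negative Control Probe" = "negative_control_probe",
    "Negative Control Codeword" = "negative_control_codeword",
    "Unassigned Codeword" = "unassigned")[type]
}

#' Write a cell-feature matrix as a MEX triplet
#'
#' @param m cells x features sparse matrix with a `feature_categories`
#'   attribute.
#' @param dir output directory.
#' @export
write_mex <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cats <- attr(m, "feature_categories")
  if (is.null(cats)) cats <- stats::setNames(rep("gene", ncol(m)), colnames(m))
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  feat <- data.frame(id = colnames(m), name = colnames(m),
                     type = unname(mex_type_for_category(cats[colnames(m)])))
  data.table::fwrite(feat, file.path(dir, "features.tsv"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(data.frame(barcode = rownames(m)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     col.names = FALSE)
  invisible(dir)
}

# fread with transparent gzip support (no extra decompression dependency).
read_table_file <- function(path, sep = "auto", header = TRUE) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    as.data.frame(data.table::fread(text = lines, sep = sep, header = header))
  } else {
    as.data.frame(data.table::fread(path, sep = sep, header = header))
  }
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing file: none of ", paste(names, collapse = ", "), " found in ", dir)
}

#' Read 10x-style in situ outputs
#'
#' Reads the transcripts table, the MEX cell-feature triplet and (when
#' present) the cells table from a run directory. Gzipped variants are read
#' transparently. The unassigned cell sentinel (-1 or "UNASSIGNED") is
#' normalized to 0.
#'
#' @param dir run directory.
#' @return list with `transcripts` (data.frame), `matrix` (cells x features
#'   sparse matrix with `feature_categories` attribute) and `cells`
#'   (data.frame or NULL).
#' @export
read_10x_outputs <- function(dir) {
  tx_path <- first_existing(dir, c("transcripts.csv", "transcripts.csv.gz"))
  tx <- read_table_file(tx_path)
  need <- c("feature_name", "x_location", "y_location", "qv", "cell_id")
  missing_cols <- setdiff(need, names(tx))
  if (length(missing_cols)) {
    stop("column mismatch in ", tx_path, ": missing ",
         paste(missing_cols, collapse = ", "), "; found header: ",
         paste(names(tx), collapse = ", "))
  }
  cid <- tx$cell_id
  if (is.character(cid)) {
    cid[cid %in% c("UNASSIGNED", "-1", "")] <- "0"
    suppressWarnings(cid <- as.integer(cid))
    cid[is.na(cid)] <- 0L
  } else {
    cid[is.na(cid) | cid < 0] <- 0L
  }
  tx$cell_id <- as.integer(cid)

  mtx_path <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  mm <- tryCatch(withCallingHandlers(
    Matrix::readMM(if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else mtx_path),
    warning = function(w) stop(conditionMessage(w))),
    error = function(e) stop("failed to parse ", mtx_path, ": ",
                             conditionMessage(e)))
  feat_path <- first_existing(dir, c("features.tsv", "features.tsv.gz"))
  feat <- read_table_file(feat_path, sep = "\t", header = FALSE)
  bc_path <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  bc <- read_table_file(bc_path, sep = "\t", header = FALSE)
  if (nrow(feat) != nrow(mm)) {
    stop("feature count in ", feat_path, " (", nrow(feat),
         ") does not match matrix rows (", nrow(mm), ")")
  }
  m <- methods::as(Matrix::t(mm), "CsparseMatrix")
  dimnames(m) <- list(bc[[1]], feat[[2]])
  if (ncol(feat) >= 3) {
    attr(m, "feature_categories") <-
      stats::setNames(unname(mex_category_for_type(feat[[3]])), feat[[2]])
  }
  cells <- NULL
  cells_path <- file.path(dir, "cells.csv")
  if (!file.exists(cells_path)) cells_path <- file.path(dir, "cells.csv.gz")
  if (file.exists(cells_path)) cells <- read_table_file(cells_path)
  list(transcripts = tx, matrix = m, cells = cells)
}

#' Write an image stack as a multi-page TIFF
#'
#' Pages are cycle-major (cycle 1 channel 1, cycle 1 channel 2, ...). Pixels
#' are stored as 16-bit with a global linear scale chosen from the stack
#' maximum; the scale and grid geometry are recorded in a JSON sidecar
#' (`<path>.json`) so intensities round-trip to within half a grey level.
#'
#' @param stack numeric array, dim c(n_cycles, n_channels, H, W).
#' @param path output TIFF path.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack)
  mx <- max(stack, 1e-12)
  pages <- vector("list", d[1] * d[2])
  for (cyc in seq_len(d[1])) for (chan in seq_len(d[2])) {
    pages[[(cyc - 1L) * d[2] + chan]] <- stack[cyc, chan, , ] / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(n_cycles = d[1], n_channels = d[2],
                            height = d[3], width = d[4], scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path TIFF path (the JSON sidecar must sit next to it).
#' @return numeric array, dim c(n_cycles, n_channels, H, W).
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(meta$n_cycles, meta$n_channels, meta$height, meta$width))
  for (cyc in seq_len(meta$n_cycles)) for (chan in seq_len(meta$n_channels)) {
    stack[cyc, chan, , ] <- pages[[(cyc - 1L) * meta$n_channels + chan]] * meta$scale
  }
  stack
}

run_config_keys <- function() {
  c("seed", "field_width", "field_height", "pixel_size", "n_cells", "n_genes",
    "n_neg_probe", "n_neg_codeword", "n_unassigned", "n_cycles", "n_channels",
    "weight", "min_hamming", "n_cell_types", "transcripts_per_cell_mean",
    "transcripts_per_cell_size", "background_rate", "mu_on", "sigma_on",
    "mu_off", "sigma_off", "p_dropout", "p_spurious", "psf_sigma", "loc_sd",
    "q_cap", "n_bins", "q_threshold", "max_expansion", "n_pcs", "knn",
    "majority", "spot_pitch", "spot_diameter", "inlier_tol", "ransac_iter")
}

#' Read a plain-text run configuration
#'
#' `key = value` lines (comments with `#`); unknown keys are rejected so
#' typos fail loudly. Values are numeric.
#'
#' @param path config file path.
#' @return named list of parameters.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% run_config_keys()) stop("unknown config key: ", key)
    out[[key]] <- as.numeric(trimws(kv[2]))
  }
  out
}

#' Write a run configuration
#' @param config named list of parameters (keys must be known).
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  bad <- setdiff(names(config), run_config_keys())
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, character(1), digits = 17)), path)
  invisible(path)
}
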