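# Plain-text readers/writers for the pipeline's artifacts.

#' Write / read a trial table as TSV
#'
#' Columns: `trial`, `session`, `odor`, `onset_frame`.
#'
#' @param trials trial table data.frame.
#' @param path file path.
#' @return `read_trial_table` returns the data.frame.
#' @export
write_trial_table <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read the planted ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element of an experiment.
#' @param path file path.
#' @return `read_ground_truth` returns the list.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a metric map and atlas as a per-voxel TSV table
#'
#' @param map a `metric_map`.
#' @param coords voxels x 3 coordinates.
#' @param atlas region label per voxel.
#' @param path file path.
#' @export
write_metric_map <- function(map, coords, atlas, path) {
  df <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   region = atlas, value = map$values, valid = map$mask)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a connectivity network as an edge-list TSV
#'
#' @param fc an `fc_matrix`.
#' @param path file path.
#' @export
write_edge_list <- function(fc, path) {
  write.table(fc$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a voxels-x-frames channel volume as multi-page TIFF
#'
#' One page per frame, reshaped to the grid. Requires the `tiff` package.
#'
#' @param mat voxels x frames matrix.
#' @param grid_shape integer(3) voxel grid.
#' @param path file path.
#' @param scale values are divided by `scale` before writing (TIFF stores
#'   unit-range floats) and re-multiplied on reading.
#' @return `read_volume_tiff` returns the voxels x frames matrix.
#' @export
write_volume_tiff <- function(mat, grid_shape, path, scale = max(mat)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  pages <- lapply(seq_len(ncol(mat)), function(t) {
    array(mat[, t] / scale, dim = grid_shape)[, , 1:grid_shape[3]]
  })
  # flatten z into rows: store each frame as (x, y*z) image
  imgs <- lapply(pages, function(p)
    matrix(p, nrow = grid_shape[1], ncol = grid_shape[2] * grid_shape[3]))
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path, grid_shape, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  imgs <- tiff::readTIFF(path, all = TRUE)
  mat <- vapply(imgs, function(m) as.vector(m), numeric(prod(grid_shape)))
  mat * scale
}
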