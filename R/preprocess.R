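#' Sliding-baseline dF/F extraction
#'
#' For each frame, the baseline `F0` is the mean of the lowest
#' `ceil(fraction * w)` intensities among the `w = min(window, available)`
#' preceding frames, and `dF/F = (F - F0) / F0`. The first frame has no
#' preceding data and returns 0; early frames use all available preceding
#' frames (warm-up rule). The defaults — lower 30% of the previous 200 frames
#' — correspond to a ~87 s baseline window at the 2.3 Hz analysis rate.
#'
#' @param trace positive fluorescence trace (vector), or a voxels x frames
#'   matrix processed row-wise.
#' @param window baseline window length in frames.
#' @param fraction fraction of lowest intensities averaged into `F0`,
#'   in (0, 1].
#' @return dF/F vector (or matrix) of the same shape as the input.
#' @export
compute_dff <- function(trace, window = 200, fraction = 0.3) {
  stopifnot(window >= 1, fraction > 0, fraction <= 1)
  if (is.matrix(trace))
    return(dff_sliding_matrix_cpp(trace, as.integer(window), fraction))
  if (length(trace) < 1) stop("trace must have at least one frame")
  dff_sliding_cpp(as.numeric(trace), as.integer(window), fraction)
}

#' Build a dF/F tensor for one channel of an experiment
#'
#' @param experiment an `odor_experiment`.
#' @param channel channel name.
#' @param window,fraction baseline parameters passed to [compute_dff()].
#' @return An object of class `dff_tensor`: list with `values` (voxels x
#'   frames dF/F matrix), `voxel_coords`, `region_id`, `frame_rate`.
#' @export
dff_tensor <- function(experiment, channel, window = 200, fraction = 0.3) {
  stopifnot(inherits(experiment, "odor_experiment"))
  mat <- experiment$channels[[channel]]
  if (is.null(mat)) stop("unknown channel: ", channel)
  structure(list(values = compute_dff(mat, window, fraction),
                 voxel_coords = experiment$voxel_coords,
                 region_id = experiment$atlas,
                 frame_rate = experiment$frame_rate),
            class = "dff_tensor")
}

#' @export
print.dff_tensor <- function(x, ...) {
  cat("dF/F tensor:", nrow(x$values), "voxels x", ncol(x$values),
      "frames at", x$frame_rate, "Hz\n")
  invisible(x)
}

#' Cut trial windows out of a dF/F tensor
#'
#' Trial `t`, window frame `k` (0-based) holds dF/F at
#' `onset_frame(t) - pre_frames + k`; the window length is
#' `pre_frames + post_frames` and offset 0 is the first frame at/after odor
#' onset.
#'
#' @param dff a `dff_tensor` (or a plain voxels x frames matrix).
#' @param trials trial table with `onset_frame`, `odor`, `session`.
#' @param pre_frames frames before onset included in the window.
#' @param post_frames frames from onset onwards included in the window.
#' @return An object of class `trial_tensor`: `values` is a
#'   trials x voxels x frames array; `window_offsets` gives each window
#'   frame's offset from odor onset; `odor` and `session` label trials.
#' @export
extract_trials <- function(dff, trials, pre_frames = 0, post_frames = 20) {
  vals <- if (inherits(dff, "dff_tensor")) dff$values else dff
  stopifnot(pre_frames >= 0, post_frames >= 1)
  len <- pre_frames + post_frames
  n_frames <- ncol(vals)
  out <- array(NA_real_, dim = c(nrow(trials), nrow(vals), len))
  for (i in seq_len(nrow(trials))) {
    start <- trials$onset_frame[i] - pre_frames
    stop_ <- start + len - 1
    if (start < 1 || stop_ > n_frames)
      stop("bounds error: window of trial ", trials$trial[i],
           " (frames ", start, "-", stop_, ") exceeds the recording")
    out[i, , ] <- vals[, start:stop_, drop = FALSE]
  }
  structure(list(values = out,
                 window_offsets = seq(-pre_frames, post_frames - 1),
                 odor = trials$odor, session = trials$session,
                 frame_rate = if (inherits(dff, "dff_tensor")) dff$frame_rate else NA_real_),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("Trial tensor:", d[1], "trials x", d[2], "voxels x", d[3], "frames",
      "(offsets", min(x$window_offsets), "..", max(x$window_offsets), ")\n")
  invisible(x)
}

#' Region-averaged traces
#'
#' Unweighted mean dF/F over the member voxels of each atlas region, per
#' frame. Label 0 marks unassigned voxels and is excluded; regions with no
#' voxels are reported in the `absent_regions` attribute rather than as
#' zero rows.
#'
#' @param dff a `dff_tensor` or voxels x frames matrix.
#' @param atlas integer region label per voxel (0 = unassigned); defaults to
#'   the tensor's own `region_id`.
#' @return regions x frames matrix with region ids as rownames.
#' @export
region_average <- function(dff, atlas = NULL) {
  vals <- if (inherits(dff, "dff_tensor")) dff$values else dff
  if (is.null(atlas) && inherits(dff, "dff_tensor")) atlas <- dff$region_id
  if (length(atlas) != nrow(vals))
    stop("shape error: atlas labels (", length(atlas),
         ") do not match voxels (", nrow(vals), ")")
  keep <- atlas > 0
  grp <- factor(atlas[keep])
  sums <- rowsum(vals[keep, , drop = FALSE], grp)
  counts <- as.vector(table(grp))
  out <- sums / counts
  rownames(out) <- levels(grp)
  all_regions <- seq_len(max(atlas))
  attr(out, "absent_regions") <- setdiff(all_regions, as.integer(levels(grp)))
  out
}

#' Block-mean downsampling
#'
#' Means of consecutive non-overlapping blocks of `factor` frames; a trailing
#' partial block is dropped. Matrices are downsampled along columns (frames).
#'
#' @param trace numeric vector or voxels x frames matrix.
#' @param factor integer >= 1.
#' @return downsampled vector/matrix.
#' @export
downsample <- function(trace, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(trace)
  if (is.matrix(trace)) {
    nb <- ncol(trace) %/% factor
    if (nb == 0) return(trace[, 0, drop = FALSE])
    idx <- rep(seq_len(nb), each = factor)
    t(rowsum(t(trace[, seq_len(nb * factor), drop = FALSE]), idx) / factor)
  } else {
    nb <- length(trace) %/% factor
    if (nb == 0) return(numeric(0))
    colMeans(matrix(trace[seq_len(nb * factor)], nrow = factor))
  }
}
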