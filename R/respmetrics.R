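#' Per-voxel metric map
#'
#' Lightweight container for per-voxel scalar maps (responsiveness,
#' intensity, tuning, decoding accuracy, ...) with a validity mask.
#'
#' @param values per-voxel numeric values.
#' @param mask logical validity flag per voxel.
#' @param metric_name label.
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(values, mask = !is.na(values), metric_name = "metric") {
  structure(list(values = values, mask = mask & !is.na(values),
                 metric_name = metric_name), class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat("Metric map '", x$metric_name, "': ", length(x$values), " voxels, ",
      sum(x$mask), " valid\n", sep = "")
  invisible(x)
}

#' Responsiveness map: stimulus-locked correlation per voxel
#'
#' Pearson correlation between each voxel's dF/F and the binary stimulus
#' sequence; voxels whose two-sided p-value is not below `alpha` (or whose
#' trace has zero variance) are masked invalid.
#'
#' @param dff voxels x frames dF/F matrix (or `dff_tensor`), aligned with
#'   `stimulus`.
#' @param stimulus binary vector, one value per frame; must not be constant.
#' @param alpha significance level for the mask.
#' @return a `metric_map` of correlations.
#' @export
responsiveness_map <- function(dff, stimulus, alpha = 0.05) {
  vals <- if (inherits(dff, "dff_tensor")) dff$values else dff
  stopifnot(ncol(vals) == length(stimulus))
  if (var(stimulus) == 0) stop("stimulus must not be constant")
  ct <- row_cor_test(vals, as.numeric(stimulus))
  metric_map(unname(ct$r), mask = unname(!is.na(ct$p) & ct$p < alpha),
             "responsiveness")
}

#' Region-level responsiveness: mean of the top valid correlations
#'
#' @param map a `metric_map` of voxel responsiveness.
#' @param atlas region label per voxel (0 excluded).
#' @param top_fraction fraction of the highest valid values averaged.
#' @return named numeric vector, one value per region with at least one valid
#'   voxel (regions without valid voxels are absent).
#' @export
region_responsiveness <- function(map, atlas, top_fraction = 0.2) {
  stopifnot(inherits(map, "metric_map"), top_fraction > 0, top_fraction <= 1)
  out <- c()
  for (reg in sort(unique(atlas[atlas > 0]))) {
    v <- map$values[atlas == reg & map$mask]
    if (length(v) == 0) next
    k <- ceiling(top_fraction * length(v))
    out[as.character(reg)] <- mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }
  out
}

#' Response intensity map
#'
#' Per-trial standard deviation (default) or area under the curve of dF/F
#' within the response window, averaged across trials.
#'
#' @param trials a `trial_tensor`; the window should be the channel's
#'   response window (frames at/after onset).
#' @param statistic `"sd"` or `"auc"`; AUC is the frame sum times the frame
#'   interval (dF/F * seconds).
#' @param frame_rate Hz, used for AUC; defaults to the tensor's rate.
#' @return a `metric_map` of intensities.
#' @export
response_intensity <- function(trials, statistic = c("sd", "auc"),
                               frame_rate = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(trials, "trial_tensor"))
  sel <- which(trials$window_offsets >= 0)
  if (length(sel) == 0) stop("empty response window")
  x <- trials$values[, , sel, drop = FALSE]
  d <- dim(x)
  if (statistic == "sd") {
    m <- apply(x, c(1, 2), sd)
  } else {
    rate <- frame_rate %||% trials$frame_rate
    if (is.na(rate)) stop("frame_rate required for AUC")
    m <- apply(x, c(1, 2), sum) / rate
  }
  metric_map(colMeans(m), metric_name = paste0("intensity_", statistic))
}

#' Phase delay and pulse width of a trial-averaged response
#'
#' Phase delay is the time from odor onset to the response peak; pulse width
#' is the full width at half maximum, with linear interpolation between
#' samples at the half-maximum crossings. Traces without a positive peak are
#' flagged undefined (both values `NA`).
#'
#' @param trace trial-averaged dF/F values over the response window.
#' @param frame_rate Hz.
#' @param offsets frame offsets from odor onset for each sample of `trace`
#'   (0 = first frame at/after onset).
#' @return list with `phase_delay` and `pulse_width` in seconds, and
#'   `defined` flag.
#' @export
response_dynamics <- function(trace, frame_rate,
                              offsets = seq_along(trace) - 1) {
  stopifnot(length(trace) == length(offsets), frame_rate > 0)
  times <- offsets / frame_rate
  ipk <- which.max(trace)
  peak <- trace[ipk]
  if (!is.finite(peak) || peak <= 0)
    return(list(phase_delay = NA_real_, pulse_width = NA_real_, defined = FALSE))
  half <- peak / 2
  cross_left <- function() {
    below <- which(trace[seq_len(ipk)] < half)
    if (length(below) == 0) return(times[1])
    i <- max(below)
    times[i] + (half - trace[i]) / (trace[i + 1] - trace[i]) *
      (times[i + 1] - times[i])
  }
  cross_right <- function() {
    n <- length(trace)
    below <- which(trace[ipk:n] < half)
    if (length(below) == 0) return(times[n])
    j <- ipk + min(below) - 1
    times[j - 1] + (trace[j - 1] - half) / (trace[j - 1] - trace[j]) *
      (times[j] - times[j - 1])
  }
  list(phase_delay = times[ipk], pulse_width = cross_right() - cross_left(),
       defined = TRUE)
}

# Per-trial AUC (dF/F * s) over the response window, trials x voxels.
trial_auc <- function(trials, frame_rate = NULL) {
  sel <- which(trials$window_offsets >= 0)
  rate <- frame_rate %||% trials$frame_rate
  if (is.na(rate)) stop("frame_rate required for AUC")
  x <- trials$values[, , sel, drop = FALSE]
  apply(x, c(1, 2), sum) / rate
}

#' Odor tuning map
#'
#' Tuning of each voxel to `odor` is the difference between its mean
#' per-trial response AUC on trials of that odor and on all other trials
#' pooled. Significance per voxel comes from a two-sided Mann-Whitney U test
#' between the two AUC groups, Benjamini-Hochberg corrected across voxels;
#' non-significant voxels are masked.
#'
#' @param trials a `trial_tensor` with at least 2 trials per odor.
#' @param odor target odor label.
#' @param alpha significance level on the adjusted p-values.
#' @param frame_rate Hz (for AUC); defaults to the tensor's rate.
#' @return a `metric_map` of tuning values (dF/F * s), with the adjusted
#'   p-values in the `p_adjusted` attribute.
#' @export
odor_tuning <- function(trials, odor, alpha = 0.05, frame_rate = NULL) {
  stopifnot(inherits(trials, "trial_tensor"))
  if (!odor %in% trials$odor) stop("missing odor class: ", odor)
  is_target <- trials$odor == odor
  if (sum(is_target) < 2 || sum(!is_target) < 2)
    stop("at least 2 trials per group required")
  auc <- trial_auc(trials, frame_rate)
  tuning <- colMeans(auc[is_target, , drop = FALSE]) -
    colMeans(auc[!is_target, , drop = FALSE])
  p <- vapply(seq_len(ncol(auc)), function(v) {
    a <- auc[is_target, v]; b <- auc[!is_target, v]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  m <- metric_map(tuning, mask = !is.na(padj) & padj < alpha,
                  paste0("tuning_", odor))
  attr(m, "p_adjusted") <- padj
  m
}

#' Standardized tuned-voxel ratio per region
#'
#' Fraction of voxels in each region significantly tuned to the odor,
#' z-scored across the included regions (typically the regions of the
#' community holding most olfactory regions).
#'
#' @param tuning a `metric_map` from [odor_tuning()].
#' @param atlas region label per voxel.
#' @param regions region ids to include; empty regions are excluded.
#' @return named numeric vector of z-scores per region.
#' @export
standardized_tuned_ratio <- function(tuning, atlas, regions) {
  stopifnot(inherits(tuning, "metric_map"))
  fracs <- c()
  for (reg in regions) {
    n <- sum(atlas == reg)
    if (n == 0) next
    fracs[as.character(reg)] <- sum(tuning$mask[atlas == reg]) / n
  }
  if (length(fracs) < 2) stop("at least 2 non-empty regions required")
  s <- sd(fracs)
  if (s == 0) return(fracs * 0)
  (fracs - mean(fracs)) / s
}
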