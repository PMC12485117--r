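#' Project trials into the discriminant (LDA) manifold space
#'
#' Applies each cross-validation fold's fitted transforms to the full trial
#' window (conventionally 2 s before odor onset to 33 s after), projecting
#' every trial with the transforms of the fold in which it was a *test*
#' trial, so no trial is projected by maps fitted on itself. Folds are then
#' aligned with [align_folds()] before geometric analysis.
#'
#' @param result a `decode_result` from [multiregion_classify()] (or
#'   [region_classify()]).
#' @param full_trials a `trial_tensor` (or list per channel) covering the
#'   full manifold window; trials must match the decoded ones.
#' @return An object of class `manifold_traces`: `coords`
#'   (trials x frames x dims), `time_axis` (seconds relative to odor
#'   onset), `odor`, `session`, `fold_ids`.
#' @export
project_manifold <- function(result, full_trials) {
  stopifnot(inherits(result, "decode_result"))
  if (inherits(full_trials, "trial_tensor")) full_trials <- list(full_trials)
  rate <- full_trials[[1]]$frame_rate
  if (result$tier == "multiregion") {
    sub <- lapply(seq_along(full_trials), function(c) {
      tt <- full_trials[[c]]
      tt$values <- tt$values[, result$masks[[c]], , drop = FALSE]
      tt
    })
    tt <- combine_channels(sub)
  } else {
    tt <- combine_channels(full_trials)
  }
  X <- tt$values
  n <- dim(X)[1]
  all_frames <- seq_len(dim(X)[3])
  nF <- length(all_frames)
  n_dims <- ncol(result$transforms[[1]]$lda$scaling)
  coords <- array(NA_real_, dim = c(n, nF, n_dims))
  for (f in seq_along(result$transforms)) {
    te <- which(result$folds == f)
    if (length(te) == 0) next
    tf <- result$transforms[[f]]
    if (result$tier == "multiregion") {
      P <- do.call(cbind, lapply(names(tf$block_cols), function(b) {
        Xb <- X[, tf$block_cols[[b]], , drop = FALSE]
        pca_transform(tf$block_pcas[[b]], flatten_rows(Xb, te, all_frames))
      }))
      S <- pca_transform(tf$gpca, P)
    } else {
      S <- pca_transform(tf$pca, flatten_rows(X, te, all_frames))
    }
    L <- lda_transform(tf$lda, S)
    coords[te, , ] <- array(L, dim = c(length(te), nF, n_dims))
  }
  structure(list(coords = coords,
                 time_axis = tt$window_offsets / rate,
                 odor = as.character(tt$odor), session = tt$session,
                 fold_ids = result$folds),
            class = "manifold_traces")
}

#' Plot manifold trajectories in the first two discriminant dimensions
#'
#' Thin per-trial trajectories plus thick per-odor mean trajectories.
#'
#' @param x a `manifold_traces`.
#' @param ... passed to [plot()].
#' @export
plot.manifold_traces <- function(x, ...) {
  odors <- sort(unique(x$odor))
  cols <- setNames(grDevices::hcl.colors(max(3, length(odors)), "Dark 3"),
                   c(odors, rep("", max(0, 3 - length(odors)))))[odors]
  xs <- x$coords[, , 1]; ys <- if (dim(x$coords)[3] > 1) x$coords[, , 2] else
    matrix(0, nrow(xs), ncol(xs))
  plot(range(xs), range(ys), type = "n", xlab = "LD 1", ylab = "LD 2", ...)
  for (i in seq_len(nrow(xs)))
    graphics::lines(xs[i, ], ys[i, ], col = grDevices::adjustcolor(
      cols[[x$odor[i]]], alpha.f = 0.25))
  for (od in odors) {
    idx <- x$odor == od
    graphics::lines(colMeans(xs[idx, , drop = FALSE]),
                    colMeans(ys[idx, , drop = FALSE]),
                    col = cols[[od]], lwd = 3)
  }
  graphics::legend("topright", legend = odors, col = cols, lwd = 3, bty = "n")
  invisible(x)
}

#' @export
print.manifold_traces <- function(x, ...) {
  d <- dim(x$coords)
  cat("Manifold traces:", d[1], "trials x", d[2], "frames x", d[3],
      "dims, t =", min(x$time_axis), "..", round(max(x$time_axis), 2), "s\n")
  invisible(x)
}

# Class-mean trajectory matrix of one fold: (odors*frames) x dims.
fold_class_means <- function(traces, fold) {
  sel <- traces$fold_ids == fold
  odors <- sort(unique(traces$odor))
  do.call(rbind, lapply(odors, function(od) {
    idx <- which(sel & traces$odor == od)
    apply(traces$coords[idx, , , drop = FALSE], c(2, 3), mean)
  }))
}

#' Align per-fold manifolds by orthogonal Procrustes
#'
#' Each fold's class-mean trajectory matrix is mapped onto fold 1's by the
#' best orthogonal transform (rotation/reflection, no scaling), and the
#' fold's trial coordinates are rotated accordingly. Residual Frobenius
#' misfits per fold are reported in the `residuals` attribute so gross
#' misalignment can be detected.
#'
#' @param traces a `manifold_traces` with at least 2 folds.
#' @return the aligned `manifold_traces`.
#' @export
align_folds <- function(traces) {
  folds <- sort(unique(traces$fold_ids))
  if (length(folds) < 2) return(traces)
  A <- fold_class_means(traces, folds[1])
  residuals <- setNames(numeric(length(folds)), folds)
  for (f in folds[-1]) {
    B <- fold_class_means(traces, f)
    if (!all(is.finite(B)) || sum(B^2) == 0 || sum(A^2) == 0) {
      warning("degenerate class means in fold ", f, "; identity alignment")
      next
    }
    sv <- svd(crossprod(B, A))
    R <- sv$u %*% t(sv$v)
    idx <- which(traces$fold_ids == f)
    for (i in idx)
      traces$coords[i, , ] <- traces$coords[i, , , drop = TRUE] %*% R
    residuals[as.character(f)] <- sqrt(sum((B %*% R - A)^2))
  }
  attr(traces, "residuals") <- residuals
  traces
}

# linear-interpolated first time (after index i0) the curve drops to level
first_crossing <- function(times, values, level, i0) {
  n <- length(values)
  if (i0 >= n) return(NA_real_)
  for (i in (i0 + 1):n) {
    if (values[i] <= level) {
      v0 <- values[i - 1]; v1 <- values[i]
      if (v0 == v1) return(times[i])
      return(times[i - 1] + (v0 - level) / (v0 - v1) * (times[i] - times[i - 1]))
    }
  }
  NA_real_
}

#' Geometry metrics of a manifold
#'
#' Computes, on the per-odor mean trajectories: the distance to the origin
#' over time (the origin is the mean location of the first time point,
#' nominally 2 s before odor onset, across all trials), the inter-class
#' distance per odor pair, and, across same-odor trials, the intra-class
#' distance. Summaries: maximum distances; the time after the post-onset
#' peak at which the distance falls to one fifth of its maximum (`t_fifth`);
#' the time it falls back to the random-state level, the 29-30 s average
#' (`t_random`); and the average intra-class distance within 0-12 s.
#' Crossings that never occur are `NA`.
#'
#' @param traces a `manifold_traces` covering roughly -2 s to +33 s.
#' @return An object of class `manifold_metrics` (a list of curves and
#'   scalar summaries; `dist_origin`, `inter_class`, `intra_class` are per
#'   time point).
#' @export
manifold_metrics <- function(traces) {
  co <- traces$coords
  tt <- traces$time_axis
  odors <- sort(unique(traces$odor))
  n_t <- length(tt)
  origin <- apply(co[, 1, , drop = FALSE], 3, mean)
  means <- lapply(odors, function(od)
    apply(co[traces$odor == od, , , drop = FALSE], c(2, 3), mean))
  names(means) <- odors
  dist_origin_by_odor <- vapply(means, function(m)
    sqrt(rowSums(sweep(m, 2, origin)^2)), numeric(n_t))
  dist_origin <- rowMeans(dist_origin_by_odor)
  pairs <- utils::combn(odors, 2, simplify = FALSE)
  inter_by_pair <- vapply(pairs, function(pr)
    sqrt(rowSums((means[[pr[1]]] - means[[pr[2]]])^2)), numeric(n_t))
  colnames(inter_by_pair) <- vapply(pairs, paste, collapse = "-", "")
  inter_class <- rowMeans(inter_by_pair)
  intra_by_odor <- vapply(odors, function(od) {
    idx <- which(traces$odor == od)
    sapply(seq_len(n_t), function(t) {
      pts <- co[idx, t, , drop = TRUE]
      if (is.null(dim(pts))) pts <- matrix(pts, ncol = dim(co)[3])
      mean(stats::dist(pts))
    })
  }, numeric(n_t))
  intra_class <- rowMeans(intra_by_odor)

  post <- which(tt >= 0)
  summarize_curve <- function(curve) {
    ipk <- post[which.max(curve[post])]
    mx <- curve[ipk]
    rand_win <- which(tt >= 29 & tt <= 30)
    rand_level <- if (length(rand_win)) mean(curve[rand_win]) else NA_real_
    t5 <- first_crossing(tt, curve, mx / 5, ipk)
    tr <- if (is.na(rand_level)) NA_real_ else
      first_crossing(tt, curve, rand_level, ipk)
    list(max = mx, t_peak = tt[ipk], t_fifth = t5, t_random = tr,
         random_level = rand_level)
  }
  win_intra <- which(tt >= 0 & tt <= 12)
  structure(list(time_axis = tt, origin = origin,
                 dist_origin = dist_origin,
                 dist_origin_by_odor = dist_origin_by_odor,
                 inter_class = inter_class, inter_by_pair = inter_by_pair,
                 intra_class = intra_class,
                 origin_summary = summarize_curve(dist_origin),
                 inter_summary = summarize_curve(inter_class),
                 avg_intra_0_12 = if (length(win_intra))
                   mean(intra_class[win_intra]) else NA_real_),
            class = "manifold_metrics")
}

#' @export
print.manifold_metrics <- function(x, ...) {
  s <- x$origin_summary
  cat("Manifold metrics: max dist-to-origin", round(s$max, 3),
      "at", round(s$t_peak, 2), "s; t_fifth", round(s$t_fifth, 2),
      "s; t_random", round(s$t_random, 2), "s\n")
  cat("  max inter-class", round(x$inter_summary$max, 3),
      "; mean intra-class (0-12 s)", round(x$avg_intra_0_12, 3), "\n")
  invisible(x)
}

#' Stage-wise manifold analysis across sessions
#'
#' Sessions are divided evenly into `n_stages` contiguous stages (default
#' 4, e.g. 60 sessions give stages of 15); manifold metrics are computed per
#' stage, and per-session return locations (mean location over 29-30 s) are
#' reported with their first two discriminant coordinates and distance to
#' the whole-recording origin.
#'
#' @param traces a `manifold_traces`.
#' @param n_stages number of stages.
#' @return list with `per_stage` (a `manifold_metrics` per stage),
#'   `stage_of_session`, `return_locations` (data.frame per session), and
#'   `stage_summary` (data.frame of per-stage means).
#' @export
stage_analysis <- function(traces, n_stages = 4) {
  sessions <- sort(unique(traces$session))
  if (length(sessions) %% n_stages != 0)
    stop("sessions (", length(sessions), ") not divisible into ",
         n_stages, " stages")
  per <- length(sessions) %/% n_stages
  stage_of <- setNames(rep(seq_len(n_stages), each = per), sessions)
  tt <- traces$time_axis
  global_origin <- apply(traces$coords[, 1, , drop = FALSE], 3, mean)
  per_stage <- lapply(seq_len(n_stages), function(s) {
    keep <- stage_of[as.character(traces$session)] == s
    sub <- traces
    sub$coords <- traces$coords[keep, , , drop = FALSE]
    sub$odor <- traces$odor[keep]
    sub$session <- traces$session[keep]
    sub$fold_ids <- traces$fold_ids[keep]
    manifold_metrics(sub)
  })
  rl_win <- which(tt >= 29 & tt <= 30)
  return_locations <- do.call(rbind, lapply(sessions, function(se) {
    idx <- which(traces$session == se)
    loc <- apply(traces$coords[idx, rl_win, , drop = FALSE], 3, mean)
    data.frame(session = se, stage = stage_of[as.character(se)],
               x = loc[1], y = if (length(loc) > 1) loc[2] else NA_real_,
               dist_to_origin = sqrt(sum((loc - global_origin)^2)))
  }))
  stage_summary <- data.frame(
    stage = seq_len(n_stages),
    max_dist_origin = vapply(per_stage, function(m) m$origin_summary$max, 0),
    max_inter_class = vapply(per_stage, function(m) m$inter_summary$max, 0),
    avg_intra_0_12 = vapply(per_stage, function(m) m$avg_intra_0_12, 0),
    return_dist = vapply(seq_len(n_stages), function(s)
      mean(return_locations$dist_to_origin[return_locations$stage == s]), 0),
    return_x = vapply(seq_len(n_stages), function(s)
      mean(return_locations$x[return_locations$stage == s]), 0))
  list(per_stage = per_stage, stage_of_session = stage_of,
       return_locations = return_locations, stage_summary = stage_summary)
}
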