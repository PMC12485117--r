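#' Motion energy of a behavior video
#'
#' Mean over pixels of the absolute difference between consecutive frames.
#'
#' @param video H x W x T array of frames.
#' @return An object of class `motion_trace`: list with `energy` (length
#'   T - 1, aligned with frames 2..T) and `frame_rate`.
#' @param frame_rate Hz of the video.
#' @export
motion_energy <- function(video, frame_rate = NA_real_) {
  stopifnot(length(dim(video)) == 3, dim(video)[3] >= 2)
  T <- dim(video)[3]
  e <- vapply(seq_len(T - 1), function(t)
    mean(abs(video[, , t + 1] - video[, , t])), numeric(1))
  structure(list(energy = e, frame_rate = frame_rate), class = "motion_trace")
}

#' Behavioral features: PCA of trial-windowed motion frames
#'
#' Per trial, the motion-energy frames of the stimulation window (optionally
#' spatially downsampled) are flattened; a PCA across trials yields the
#' behavioral feature matrix. PC signs follow a deterministic convention
#' (the largest-magnitude loading of each component is positive).
#'
#' @param video H x W x T behavior frame stack.
#' @param trials trial table with `onset_frame`.
#' @param frame_rate video frame rate, Hz.
#' @param window_s seconds from odor onset included (default the 5 s
#'   stimulation period).
#' @param n_pcs number of principal components retained (default 30).
#' @param spatial_factor integer spatial downsampling factor (block mean).
#' @return trials x PCs score matrix with the explained-variance ratio per
#'   PC in the `variance_ratio` attribute.
#' @export
behavior_features <- function(video, trials, frame_rate, window_s = 5,
                              n_pcs = 30, spatial_factor = 1) {
  T <- dim(video)[3]
  # per-pixel motion frames
  energy <- abs(video[, , -1, drop = FALSE] - video[, , -T, drop = FALSE])
  if (spatial_factor > 1) {
    h <- dim(energy)[1] %/% spatial_factor
    w <- dim(energy)[2] %/% spatial_factor
    ds <- array(0, dim = c(h, w, dim(energy)[3]))
    for (i in seq_len(h)) for (j in seq_len(w)) {
      ri <- (i - 1) * spatial_factor + seq_len(spatial_factor)
      rj <- (j - 1) * spatial_factor + seq_len(spatial_factor)
      ds[i, j, ] <- apply(energy[ri, rj, , drop = FALSE], 3, mean)
    }
    energy <- ds
  }
  win <- max(1L, round(window_s * frame_rate))
  feats <- t(vapply(trials$onset_frame, function(on) {
    idx <- on:min(on + win - 1, dim(energy)[3])
    as.vector(energy[, , idx])
  }, numeric(prod(dim(energy)[1:2]) * win)))
  p <- prcomp(feats, center = TRUE, scale. = FALSE)
  d <- min(n_pcs, ncol(p$rotation))
  rot <- p$rotation[, seq_len(d), drop = FALSE]
  scores <- p$x[, seq_len(d), drop = FALSE]
  for (k in seq_len(d)) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  attr(scores, "variance_ratio") <- (p$sdev^2 / sum(p$sdev^2))[seq_len(d)]
  scores
}

#' Decode stimulus structure or odor identity from features
#'
#' Linear SVM with stratified cross-validation; an optional seeded label
#' shuffle serves as the negative control.
#'
#' @param features samples x features matrix.
#' @param labels label per sample (e.g. odor identity, or period vs
#'   interval).
#' @param shuffle_control permute labels before decoding (negative control).
#' @param cv_folds folds.
#' @param seed seed for folds (and the shuffle, when requested).
#' @param cost linear SVM cost.
#' @return list with `accuracy` and `fold_accuracy`.
#' @export
behavior_decoding <- function(features, labels, shuffle_control = FALSE,
                              cv_folds = 5, seed = 1L, cost = 1) {
  labels <- as.character(labels)
  if (shuffle_control) labels <- with_seed(seed + 1L, sample(labels))
  folds <- stratified_folds(labels, cv_folds, seed)
  acc <- numeric(cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    svm <- svm_ovr_fit(features[tr, , drop = FALSE], labels[tr], cost = cost)
    acc[f] <- mean(svm_ovr_predict(svm, features[te, , drop = FALSE]) ==
                   labels[te])
  }
  list(accuracy = mean(acc), fold_accuracy = acc)
}

# standardized ridge solve: returns function(newX) -> fitted values
ridge_fit <- function(X, Y, lambda) {
  if (lambda <= 0) stop("ridge penalty must be positive")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  beta <- solve(crossprod(Xs) + lambda * diag(ncol(Xs)), crossprod(Xs, Yc))
  function(newX) {
    Ns <- sweep(sweep(newX, 2, mu), 2, sdv, "/")
    sweep(Ns %*% beta, 2, ym, "+")
  }
}

#' Ridge variance partitioning of neural dynamics
#'
#' Predicts the leading neural principal components from behavioral
#' features, the stimulus regressors (trial-averaged responses per odor
#' identity), or both, by ridge regression (fixed penalty on standardized
#' predictors). Reports cross-validated R-squared per predictor set, the
#' behavior-explained component (fitted values of the behavior-only model)
#' and the residual after removing it — residual plus explained reconstruct
#' the input exactly. Both parts can be fed to odor classification to test
#' whether motion carries the odor information.
#'
#' @param neural_pcs samples x PCs matrix of neural dynamics.
#' @param behavior samples x features behavioral matrix.
#' @param stimulus samples x regressors stimulus design (e.g. indicator or
#'   trial-averaged response per odor).
#' @param lambda ridge penalty (> 0 enforced; default 1 on standardized
#'   predictors).
#' @param cv_folds folds for the R-squared estimate.
#' @param seed fold seed.
#' @return list with `r2` (named: behavior, stimulus, both; mean over PCs),
#'   `r2_per_pc`, `explained` (behavior-explained component), `residual`.
#' @export
ridge_partition <- function(neural_pcs, behavior, stimulus, lambda = 1,
                            cv_folds = 5, seed = 1L) {
  Y <- as.matrix(neural_pcs)
  sets <- list(behavior = as.matrix(behavior),
               stimulus = as.matrix(stimulus),
               both = cbind(as.matrix(behavior), as.matrix(stimulus)))
  n <- nrow(Y)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  r2_per_pc <- sapply(sets, function(X) {
    press <- numeric(ncol(Y)); tot <- numeric(ncol(Y))
    for (f in seq_len(cv_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      fit <- ridge_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], lambda)
      pred <- fit(X[te, , drop = FALSE])
      press <- press + colSums((Y[te, , drop = FALSE] - pred)^2)
      tot <- tot + colSums(sweep(Y[te, , drop = FALSE], 2,
                                 colMeans(Y[tr, , drop = FALSE]))^2)
    }
    1 - press / tot
  })
  full_fit <- ridge_fit(sets$behavior, Y, lambda)
  explained <- full_fit(sets$behavior)
  list(r2 = colMeans(r2_per_pc), r2_per_pc = r2_per_pc,
       explained = explained, residual = Y - explained)
}

#' Lagged cross-correlation between neural signals and motion
#'
#' Pearson correlation between each node's trace and the motion trace
#' shifted over a grid of lags (default within 1 s at 0.1 s steps, with
#' linear interpolation for sub-frame shifts). Positive lags mean the
#' neural signal is delayed relative to motion.
#'
#' @param neural nodes x frames matrix (voxels or region averages).
#' @param motion a `motion_trace` or numeric vector; length `T` or `T - 1`
#'   (difference-energy traces are aligned to frames 2..T).
#' @param frame_rate Hz of `neural`.
#' @param max_lag maximum absolute lag, seconds.
#' @param step lag grid step, seconds.
#' @return list with `lags` (s), `profiles` (nodes x lags correlation
#'   matrix), `mean_by_lag`, `frac_above_mean` (fraction of node-lag
#'   correlations above the overall mean, per lag), `peak_lag` (per node).
#' @export
lagged_correlation <- function(neural, motion, frame_rate, max_lag = 1,
                               step = 0.1) {
  if (inherits(motion, "motion_trace")) motion <- motion$energy
  T <- ncol(neural)
  if (length(motion) == T - 1) motion <- c(motion[1], motion)
  stopifnot(length(motion) == T)
  times <- (seq_len(T) - 1) / frame_rate
  lags <- seq(-max_lag, max_lag, by = step)
  margin <- ceiling(max_lag * frame_rate) + 1
  core <- (margin + 1):(T - margin)
  profiles <- vapply(lags, function(L) {
    shifted <- stats::approx(times, motion, xout = times[core] - L)$y
    suppressWarnings(as.vector(cor(t(neural[, core, drop = FALSE]), shifted)))
  }, numeric(nrow(neural)))
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  colnames(profiles) <- sprintf("%+.1f", lags)
  overall <- mean(profiles, na.rm = TRUE)
  list(lags = lags, profiles = profiles,
       mean_by_lag = colMeans(profiles, na.rm = TRUE),
       frac_above_mean = colMeans(profiles > overall, na.rm = TRUE),
       peak_lag = lags[apply(profiles, 1, which.max)])
}
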