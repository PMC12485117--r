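#' Decoder hyperparameters
#'
#' Bundles the hyperparameters of the odor-identity decoding tiers. The
#' defaults follow the study conventions: block-wise PCA keeping 90%
#' variance, a second PCA to 25 dimensions at the multi-region tier,
#' per-region PCA keeping 80% variance (99.8% at the brain-region-average
#' tier), LDA fitted at window offset 2 (the third frame after odor onset,
#' where the response is near its highest), SVM and PCA on offsets 0-13,
#' 5-fold cross-validation, and a linear one-vs-rest SVM with cost 1.
#'
#' @param pca1_variance block-wise PCA variance kept (proportion).
#' @param pca2_dims dimensions kept by the second, global PCA.
#' @param pca_variance PCA variance kept at the single-region tier.
#' @param lda_frame_offset window offset (frames from onset) used to fit LDA.
#' @param feature_frames window offsets used as classification features.
#' @param cv_folds number of stratified cross-validation folds.
#' @param block_shape voxel block for the accuracy map.
#' @param multiregion_block voxel block for the multi-region block-wise PCA.
#' @param cost linear SVM regularization constant.
#' @param seed integer seed (fold assignment).
#' @return An object of class `decoder_spec`.
#' @export
decoder_spec <- function(pca1_variance = 0.90, pca2_dims = 25,
                         pca_variance = 0.80, lda_frame_offset = 2,
                         feature_frames = 0:13, cv_folds = 5,
                         block_shape = c(4, 4, 2),
                         multiregion_block = c(10, 10, 10),
                         cost = 1, seed = 1L) {
  stopifnot(cv_folds >= 2, pca1_variance > 0, pca1_variance <= 1,
            pca_variance > 0, pca_variance <= 1, pca2_dims >= 1)
  structure(list(pca1_variance = pca1_variance, pca2_dims = pca2_dims,
                 pca_variance = pca_variance,
                 lda_frame_offset = lda_frame_offset,
                 feature_frames = feature_frames, cv_folds = cv_folds,
                 block_shape = block_shape,
                 multiregion_block = multiregion_block,
                 cost = cost, seed = as.integer(seed)),
            class = "decoder_spec")
}

# ---- linear algebra building blocks -------------------------------------

fit_pca <- function(X, var_keep = NULL, ndims = NULL) {
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (!is.null(var_keep)) {
    cum <- cumsum(ev) / sum(ev)
    d <- which(cum >= var_keep - 1e-12)[1]
    if (is.na(d)) d <- length(ev)
  } else {
    d <- min(ndims, length(ev))
  }
  # never keep numerically null components (they are constant within any
  # subset and break downstream discriminant fits)
  n_pos <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-10)
  d <- max(1L, min(d, ncol(p$rotation), n_pos))
  list(center = p$center, rotation = p$rotation[, seq_len(d), drop = FALSE],
       d = d)
}

pca_transform <- function(pca, X) {
  sweep(X, 2, pca$center) %*% pca$rotation
}

fit_lda <- function(scores, labels) {
  suppressWarnings(MASS::lda(scores, grouping = factor(labels)))
}

lda_transform <- function(lda, scores) {
  predict(lda, scores)$x
}

# One-vs-rest linear SVM (decision-value argmax across per-class machines).
svm_ovr_fit <- function(X, y, cost = 1) {
  classes <- sort(unique(as.character(y)))
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "target", "other"),
                 levels = c("target", "other"))
    e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
  })
  list(classes = classes, models = models)
}

svm_ovr_predict <- function(fit, X) {
  dec <- vapply(fit$models, function(m) {
    dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
    # libsvm orients the decision value toward whichever class appeared
    # first in the training data; the column name records that orientation
    flip <- if (identical(colnames(dv)[1], "target/other")) 1 else -1
    flip * as.numeric(dv)
  }, numeric(nrow(X)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  fit$classes[max.col(dec, ties.method = "first")]
}

# trials x voxels x frames -> (n*F) x V row matrix; row (i + n*(f-1)) is
# trial i at the f-th selected frame.
flatten_rows <- function(X, trial_idx, frame_idx) {
  x <- X[trial_idx, , frame_idx, drop = FALSE]
  n <- dim(x)[1]; V <- dim(x)[2]; F <- dim(x)[3]
  m <- aperm(x, c(1, 3, 2))
  dim(m) <- c(n * F, V)
  m
}

# (n*F) x D row matrix back to n x (F*D) per-trial trajectory features.
rows_to_traj <- function(L, n, F) {
  D <- ncol(L)
  arr <- array(L, dim = c(n, F, D))
  matrix(arr, nrow = n, ncol = F * D)
}

# Concatenate the voxel axes of one or more trial tensors (channels).
combine_channels <- function(trials) {
  if (inherits(trials, "trial_tensor")) trials <- list(trials)
  base <- trials[[1]]
  if (length(trials) == 1) {
    vals <- base$values
    channel_of <- rep(1L, dim(vals)[2])
    voxel_of <- seq_len(dim(vals)[2])
  } else {
    for (tt in trials[-1]) {
      stopifnot(identical(tt$odor, base$odor),
                identical(tt$window_offsets, base$window_offsets))
    }
    vals <- do.call(abind3, lapply(trials, function(t) t$values))
    channel_of <- rep(seq_along(trials),
                      vapply(trials, function(t) dim(t$values)[2], integer(1)))
    voxel_of <- unlist(lapply(trials, function(t) seq_len(dim(t$values)[2])))
  }
  list(values = vals, odor = base$odor, session = base$session,
       window_offsets = base$window_offsets, channel_of = channel_of,
       voxel_of = voxel_of)
}

# bind 3-d arrays along the middle (voxel) dimension
abind3 <- function(...) {
  arrs <- list(...)
  d1 <- dim(arrs[[1]])[1]; d3 <- dim(arrs[[1]])[3]
  total <- sum(vapply(arrs, function(a) dim(a)[2], integer(1)))
  out <- array(NA_real_, dim = c(d1, total, d3))
  at <- 0
  for (a in arrs) {
    out[, at + seq_len(dim(a)[2]), ] <- a
    at <- at + dim(a)[2]
  }
  out
}

new_decode_result <- function(tier, accuracy, fold_accuracy, predictions,
                              folds, labels, transforms, spec) {
  structure(list(tier = tier, accuracy = accuracy,
                 fold_accuracy = fold_accuracy, predictions = predictions,
                 folds = folds, labels = labels, transforms = transforms,
                 spec = spec),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat("Odor decoding (", x$tier, "): accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy), " (",
      paste(sprintf("%.0f%%", 100 * x$fold_accuracy), collapse = ", "),
      " per fold)\n", sep = "")
  invisible(x)
}

#' Copy of a trial tensor with permuted odor labels
#'
#' Used for chance-level calibration controls.
#'
#' @param trials a `trial_tensor`.
#' @param seed permutation seed.
#' @return the tensor with its `odor` labels shuffled.
#' @export
permute_labels <- function(trials, seed = NULL) {
  trials$odor <- with_seed(seed, sample(trials$odor))
  trials
}

# ---- region tier ---------------------------------------------------------

#' Odor identity classification within one region (PCA + LDA + SVM)
#'
#' Per cross-validation fold: a PCA keeping `pca_variance` variance is fitted
#' on the training trials' feature frames (each frame of each trial is one
#' sample); an LDA is fitted on the training trials at the LDA frame offset
#' only; all feature frames of train and test trials are projected through
#' both maps and reshaped to trials x (frames x LDA dimensions) trajectory
#' features; a linear one-vs-rest SVM fitted on the training trajectories
#' scores the test trials. No test-trial information enters any fit.
#'
#' @param trials a `trial_tensor`, or a list of them (channels; voxel axes
#'   are concatenated).
#' @param spec a [decoder_spec()].
#' @param pca_variance PCA variance kept (defaults to `spec$pca_variance`).
#' @return a `decode_result`.
#' @export
region_classify <- function(trials, spec = decoder_spec(),
                            pca_variance = spec$pca_variance) {
  tt <- combine_channels(trials)
  X <- tt$values
  labels <- as.character(tt$odor)
  fidx <- match(spec$feature_frames, tt$window_offsets)
  lidx <- match(spec$lda_frame_offset, tt$window_offsets)
  if (anyNA(fidx) || is.na(lidx))
    stop("trial window does not cover the requested feature frames")
  folds <- stratified_folds(labels, spec$cv_folds, spec$seed)
  nF <- length(fidx)
  preds <- character(length(labels))
  fold_acc <- numeric(spec$cv_folds)
  transforms <- vector("list", spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    pca <- fit_pca(flatten_rows(X, tr, fidx), var_keep = pca_variance)
    lda <- fit_lda(pca_transform(pca, X[tr, , lidx, drop = TRUE]), labels[tr])
    traj <- function(idx) {
      S <- pca_transform(pca, flatten_rows(X, idx, fidx))
      rows_to_traj(lda_transform(lda, S), length(idx), nF)
    }
    svm <- svm_ovr_fit(traj(tr), labels[tr], cost = spec$cost)
    pr <- svm_ovr_predict(svm, traj(te))
    preds[te] <- pr
    fold_acc[f] <- mean(pr == labels[te])
    transforms[[f]] <- list(pca = pca, lda = lda, svm = svm)
  }
  new_decode_result("region", mean(fold_acc), fold_acc, preds, folds,
                    labels, transforms, spec)
}

#' Brain-region-level odor classification on region-averaged traces
#'
#' Identical to [region_classify()] but run on region-mean traces with a
#' high PCA variance threshold (default 0.998), the setting appropriate for
#' the low-dimensional region-average feature space.
#'
#' @param region_trials a `trial_tensor` whose "voxels" are region-averaged
#'   traces.
#' @param spec a [decoder_spec()].
#' @param pca_variance variance kept (default 0.998).
#' @return a `decode_result`.
#' @export
brainregion_classify <- function(region_trials, spec = decoder_spec(),
                                 pca_variance = 0.998) {
  res <- region_classify(region_trials, spec, pca_variance = pca_variance)
  res$tier <- "brainregion"
  res
}

# ---- block accuracy map --------------------------------------------------

# Assign each voxel to a spatial block id given block shape.
block_ids <- function(coords, block_shape) {
  bx <- ceiling(coords[, 1] / block_shape[1])
  by <- ceiling(coords[, 2] / block_shape[2])
  bz <- ceiling(coords[, 3] / block_shape[3])
  paste(bx, by, bz, sep = "_")
}

#' Block-wise odor decoding accuracy map
#'
#' The volume is divided into small voxel blocks (default 4 x 4 x 2). Within
#' each block the per-trial features are the flattened voxels x frames
#' (x channels) values; a PCA keeping `pca1_variance` variance is fitted per
#' training fold, and a linear SVM scores the held-out trials; the map holds
#' each block's cross-validated accuracy (assigned to all member voxels).
#'
#' @param trials a `trial_tensor` or list of them (channels concatenated as
#'   features within each block).
#' @param coords voxels x 3 integer coordinates.
#' @param spec a [decoder_spec()].
#' @param blocks optional subset of block ids to evaluate (all by default).
#' @return list with `map` (a `metric_map` over voxels), `block_accuracy`
#'   (named per block), `block_of` (block id per voxel).
#' @export
block_accuracy_map <- function(trials, coords, spec = decoder_spec(),
                               blocks = NULL) {
  tt <- combine_channels(trials)
  X <- tt$values
  labels <- as.character(tt$odor)
  fidx <- match(spec$feature_frames, tt$window_offsets)
  if (anyNA(fidx)) stop("trial window does not cover the feature frames")
  bid <- block_ids(coords, spec$block_shape)
  bid_per_col <- bid[tt$voxel_of]
  folds <- stratified_folds(labels, spec$cv_folds, spec$seed)
  all_blocks <- unique(bid)
  if (!is.null(blocks)) all_blocks <- intersect(all_blocks, blocks)
  acc <- setNames(rep(NA_real_, length(all_blocks)), all_blocks)
  n <- length(labels)
  for (b in all_blocks) {
    cols <- which(bid_per_col == b)
    # per-trial features: voxels x frames (x channels) flattened
    feat <- matrix(X[, cols, fidx, drop = FALSE], nrow = n)
    facc <- numeric(spec$cv_folds)
    for (f in seq_len(spec$cv_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      pca <- fit_pca(feat[tr, , drop = FALSE], var_keep = spec$pca1_variance)
      svm <- svm_ovr_fit(pca_transform(pca, feat[tr, , drop = FALSE]),
                         labels[tr], cost = spec$cost)
      pr <- svm_ovr_predict(svm, pca_transform(pca, feat[te, , drop = FALSE]))
      facc[f] <- mean(pr == labels[te])
    }
    acc[b] <- mean(facc)
  }
  vox_acc <- acc[bid]
  list(map = metric_map(unname(vox_acc), metric_name = "block_accuracy"),
       block_accuracy = acc, block_of = bid)
}

#' Accuracy-gain map between two block accuracy maps
#'
#' @param map_dual,map_single outputs of [block_accuracy_map()] (dual-channel
#'   and single-channel).
#' @return a `metric_map` of accuracy differences (dual minus single).
#' @export
accuracy_gain_map <- function(map_dual, map_single) {
  metric_map(map_dual$map$values - map_single$map$values,
             metric_name = "accuracy_gain")
}

# ---- multi-region tier ---------------------------------------------------

#' Voxel-level multi-region odor classification (two-step PCA + LDA + SVM)
#'
#' Voxels inside the mask (conventionally the community holding most
#' olfactory regions; for the second channel, the regions with accuracy
#' gain) are divided into blocks (default 10 x 10 x 10). Per fold: each
#' block gets a PCA keeping 90% variance (fitted on the training trials'
#' feature frames); the block PCs of all blocks and channels are
#' concatenated and reduced by a second PCA to `pca2_dims` dimensions; an
#' LDA fitted at the LDA frame offset maps into the discriminant space; a
#' linear one-vs-rest SVM classifies the trial trajectories. All fits use
#' training folds only.
#'
#' @param trials a `trial_tensor` or list of them (one per channel).
#' @param coords voxels x 3 coordinates (shared across channels).
#' @param masks voxel-index subset per channel (list, or single vector
#'   recycled); `NULL` keeps all voxels.
#' @param spec a [decoder_spec()].
#' @return a `decode_result`; `transforms` holds per-fold block PCAs, the
#'   global PCA, LDA and SVM, enabling manifold projection and weight maps.
#' @export
multiregion_classify <- function(trials, coords, masks = NULL,
                                 spec = decoder_spec()) {
  if (inherits(trials, "trial_tensor")) trials <- list(trials)
  n_ch <- length(trials)
  if (is.null(masks)) masks <- rep(list(seq_len(dim(trials[[1]]$values)[2])), n_ch)
  if (!is.list(masks)) masks <- rep(list(masks), n_ch)
  sub <- lapply(seq_len(n_ch), function(c) {
    tt <- trials[[c]]
    tt$values <- tt$values[, masks[[c]], , drop = FALSE]
    tt
  })
  tt <- combine_channels(sub)
  X <- tt$values
  labels <- as.character(tt$odor)
  fidx <- match(spec$feature_frames, tt$window_offsets)
  lidx <- match(spec$lda_frame_offset, tt$window_offsets)
  if (anyNA(fidx) || is.na(lidx))
    stop("trial window does not cover the requested feature frames")
  nF <- length(fidx)
  # column blocks: channel x spatial block
  col_coords <- do.call(rbind, lapply(seq_len(n_ch), function(c)
    coords[masks[[c]], , drop = FALSE]))
  bid <- paste(tt$channel_of, block_ids(col_coords, spec$multiregion_block),
               sep = ":")
  block_cols <- split(seq_along(bid), bid)
  folds <- stratified_folds(labels, spec$cv_folds, spec$seed)
  preds <- character(length(labels))
  fold_acc <- numeric(spec$cv_folds)
  transforms <- vector("list", spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    block_pcas <- lapply(block_cols, function(cols) {
      Xb <- X[, cols, , drop = FALSE]
      fit_pca(flatten_rows(Xb, tr, fidx), var_keep = spec$pca1_variance)
    })
    project_blocks <- function(idx, frames) {
      do.call(cbind, lapply(names(block_cols), function(b) {
        Xb <- X[, block_cols[[b]], , drop = FALSE]
        pca_transform(block_pcas[[b]], flatten_rows(Xb, idx, frames))
      }))
    }
    Ptr <- project_blocks(tr, fidx)
    d2 <- min(spec$pca2_dims, ncol(Ptr), nrow(Ptr))
    if (d2 < spec$pca2_dims)
      warning("pca2_dims reduced to ", d2, " (available dimensions)")
    gpca <- fit_pca(Ptr, ndims = d2)
    lda <- fit_lda(pca_transform(gpca, project_blocks(tr, lidx)), labels[tr])
    traj <- function(idx, frames = fidx) {
      S <- pca_transform(gpca, project_blocks(idx, frames))
      rows_to_traj(lda_transform(lda, S), length(idx), length(frames))
    }
    svm <- svm_ovr_fit(traj(tr), labels[tr], cost = spec$cost)
    pr <- svm_ovr_predict(svm, traj(te))
    preds[te] <- pr
    fold_acc[f] <- mean(pr == labels[te])
    transforms[[f]] <- list(block_pcas = block_pcas, block_cols = block_cols,
                            gpca = gpca, lda = lda, svm = svm)
  }
  res <- new_decode_result("multiregion", mean(fold_acc), fold_acc, preds,
                           folds, labels, transforms, spec)
  res$channel_of <- tt$channel_of
  res$voxel_of <- tt$voxel_of
  res$masks <- masks
  res$window_offsets <- tt$window_offsets
  res
}

#' Odor identification weight map
#'
#' Composes the fitted linear maps of the multi-region decoder — block PCA,
#' global PCA and LDA — back into voxel space. For each odor, the weight of
#' a voxel is the magnitude of the composed map applied to that odor's
#' discriminant direction (class mean minus grand mean in LDA space),
#' averaged over folds.
#'
#' @param result a `decode_result` from [multiregion_classify()].
#' @return matrix (masked voxels x odors) of non-negative weights, with
#'   `channel_of`/`voxel_of` attributes locating each row.
#' @export
identification_weight_map <- function(result) {
  stopifnot(inherits(result, "decode_result"),
            result$tier == "multiregion")
  classes <- sort(unique(result$labels))
  n_cols <- length(result$channel_of)
  acc <- matrix(0, n_cols, length(classes))
  for (tf in result$transforms) {
    W <- matrix(0, n_cols, ncol(tf$gpca$rotation))
    at <- 0
    for (b in names(tf$block_cols)) {
      cols <- tf$block_cols[[b]]
      rot <- tf$block_pcas[[b]]$rotation
      W[cols, ] <- W[cols, ] +
        rot %*% tf$gpca$rotation[at + seq_len(ncol(rot)), , drop = FALSE]
      at <- at + ncol(rot)
    }
    W <- W %*% tf$lda$scaling
    centers <- tf$lda$means %*% tf$lda$scaling
    grand <- colMeans(centers)
    for (k in seq_along(classes)) {
      u <- centers[classes[k], ] - grand
      nu <- sqrt(sum(u^2))
      if (nu > 0) u <- u / nu
      acc[, k] <- acc[, k] + abs(W %*% u)
    }
  }
  acc <- acc / length(result$transforms)
  colnames(acc) <- classes
  attr(acc, "channel_of") <- result$channel_of
  attr(acc, "voxel_of") <- result$voxel_of
  acc
}
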