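make_traces <- function(coords, odor, session = rep(1, length(odor)),
                        time_axis = NULL,
                        fold_ids = rep(1, length(odor))) {
  if (is.null(time_axis)) time_axis <- seq(-2, 33, length.out = dim(coords)[2])
  structure(list(coords = coords, time_axis = time_axis, odor = odor,
                 session = session, fold_ids = fold_ids),
            class = "manifold_traces")
}

random_rotation <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d)))
}

test_that("fold alignment recovers rotations and reflections", {
  set.seed(60)
  n <- 12; F <- 20; D <- 2
  base <- array(rnorm(n * F * D), c(n, F, D))
  odor <- rep(c("A", "B"), 6)
  # identical folds: alignment leaves coordinates unchanged, residual 0
  both <- array(0, c(2 * n, F, D))
  both[1:n, , ] <- base
  both[n + 1:n, , ] <- base
  tr_same <- make_traces(both, rep(odor, 2), fold_ids = rep(1:2, each = n))
  aligned <- align_folds(tr_same)
  expect_equal(aligned$coords[n + 1:n, , ], base, tolerance = 1e-10)
  expect_lt(max(attr(aligned, "residuals")), 1e-10)
  # rotated / reflected fold 2 is mapped back onto fold 1
  R <- random_rotation(D, 61)
  rot <- base
  for (i in 1:n) rot[i, , ] <- base[i, , ] %*% R
  tr_rot <- tr_same
  tr_rot$coords[n + 1:n, , ] <- rot
  aligned2 <- align_folds(tr_rot)
  expect_equal(aligned2$coords[n + 1:n, , ], base, tolerance = 1e-8)
  refl <- base; refl[, , 1] <- -refl[, , 1]
  tr_ref <- tr_same
  tr_ref$coords[n + 1:n, , ] <- refl
  aligned3 <- align_folds(tr_ref)
  expect_equal(aligned3$coords[n + 1:n, , ], base, tolerance = 1e-8)
})

test_that("static two-class geometry gives constant inter and zero intra", {
  F <- 36
  time_axis <- seq(-2, 33, length.out = F)
  p1 <- c(0, 0); p2 <- c(3, 4)
  coords <- array(0, c(8, F, 2))
  for (i in 1:4) coords[i, , ] <- matrix(p1, F, 2, byrow = TRUE)
  for (i in 5:8) coords[i, , ] <- matrix(p2, F, 2, byrow = TRUE)
  tr <- make_traces(coords, rep(c("A", "B"), each = 4), time_axis = time_axis)
  m <- manifold_metrics(tr)
  expect_true(all(abs(m$intra_class) < 1e-12))
  expect_true(all(abs(m$inter_class - 5) < 1e-12))
  # homogeneity: scaling coordinates scales every distance
  tr2 <- tr; tr2$coords <- tr$coords * 2.5
  m2 <- manifold_metrics(tr2)
  expect_equal(m2$inter_class, m$inter_class * 2.5, tolerance = 1e-12)
  expect_equal(m2$dist_origin, m$dist_origin * 2.5, tolerance = 1e-12)
})

test_that("metrics are invariant to global rotations of the LDA space", {
  set.seed(62)
  n <- 18; F <- 36; D <- 3
  coords <- array(rnorm(n * F * D), c(n, F, D))
  odor <- rep(c("A", "B", "C"), 6)
  tr <- make_traces(coords, odor)
  m <- manifold_metrics(tr)
  R <- random_rotation(D, 63)
  tr2 <- tr
  for (i in 1:n) tr2$coords[i, , ] <- coords[i, , ] %*% R
  m2 <- manifold_metrics(tr2)
  expect_equal(m2$dist_origin, m$dist_origin, tolerance = 1e-10)
  expect_equal(m2$inter_class, m$inter_class, tolerance = 1e-10)
  expect_equal(m2$intra_class, m$intra_class, tolerance = 1e-10)
})

test_that("return-to-fifth time matches a dense-grid crossing oracle", {
  rate <- 2.3
  tt_ax <- seq(-2, 33, by = 1 / rate)
  F <- length(tt_ax)
  shape <- response_kernel(pmax(tt_ax, 0), delay = 0.3, rise_tau = 0.4,
                           decay_tau = 3, amplitude = 2)
  shape[tt_ax < 0] <- 0
  coords <- array(0, c(6, F, 2))
  for (i in 1:3) coords[i, , 1] <- shape
  for (i in 4:6) coords[i, , 1] <- -shape
  tr <- make_traces(coords, rep(c("A", "B"), each = 3), time_axis = tt_ax)
  m <- manifold_metrics(tr)
  dense_t <- seq(0, 33, by = 1e-4)
  dense <- response_kernel(dense_t, 0.3, 0.4, 3, 2)
  pk <- which.max(dense)
  oracle <- dense_t[pk + min(which(dense[-(1:pk)] <= max(dense) / 5))]
  expect_lt(abs(m$origin_summary$t_fifth - oracle), 1 / rate + 1e-9)
  expect_equal(m$origin_summary$max, 2, tolerance = 0.05)
})

test_that("stage analysis recovers planted amplitude schedules", {
  rate <- 1.15
  tt_ax <- seq(-2, 33, by = 1 / rate)
  F <- length(tt_ax)
  shape <- response_kernel(pmax(tt_ax, 0), delay = 0.3, rise_tau = 0.5,
                           decay_tau = 2.5, amplitude = 1)
  shape[tt_ax < 0] <- 0
  n_sessions <- 8
  stage_amp <- c(1, 1, 0.8, 0.8, 0.6, 0.6, 0.4, 0.4)
  odors <- c("A", "B")
  coords <- array(0, c(n_sessions * 2, F, 2))
  odor <- rep(odors, n_sessions)
  session <- rep(1:n_sessions, each = 2)
  set.seed(64)
  for (i in seq_len(n_sessions * 2)) {
    dir <- if (odor[i] == "A") c(1, 0) else c(0, 1)
    coords[i, , ] <- outer(shape * stage_amp[session[i]], dir) +
      rnorm(F * 2, sd = 0.01)
  }
  tr <- make_traces(coords, odor, session = session)
  st <- stage_analysis(tr, n_stages = 4)
  mx <- st$stage_summary$max_dist_origin
  expect_true(all(diff(mx) < 0))
  expect_equal(mx[1] / mx[4], 1 / 0.4, tolerance = 0.15)
  # flat schedule: no monotone trend
  coords2 <- coords
  for (i in seq_len(n_sessions * 2)) {
    dir <- if (odor[i] == "A") c(1, 0) else c(0, 1)
    coords2[i, , ] <- outer(shape, dir) + rnorm(F * 2, sd = 0.01)
  }
  st2 <- stage_analysis(make_traces(coords2, odor, session = session), 4)
  mx2 <- st2$stage_summary$max_dist_origin
  expect_lt(max(mx2) - min(mx2), 0.05)
  expect_error(stage_analysis(tr, n_stages = 3), "divisible")
})

test_that("projected manifolds separate classes only when signal is planted", {
  cfg <- small_config(seed = 70, n_sessions = 6, grid = c(8, 4, 2),
                      noise_sd = 0.05, rest_duration = 90)
  ex <- generate_experiment(cfg)
  dff <- test_dff(ex, "calcium")
  sp <- decoder_spec(seed = 1, pca2_dims = 10)
  trials <- extract_trials(dff, ex$trials, 0, 20)
  res <- multiregion_classify(trials, ex$voxel_coords, spec = sp)
  rate <- ex$frame_rate
  full <- extract_trials(dff, ex$trials, ceiling(2 * rate), ceiling(33 * rate))
  tr <- align_folds(project_manifold(res, full))
  m <- manifold_metrics(tr)
  stim <- tr$time_axis >= 1 & tr$time_axis <= 5
  base <- tr$time_axis < 0
  expect_gt(mean(m$inter_class[stim]), 3 * mean(m$inter_class[base]))
  expect_equal(dim(tr$coords)[3], length(cfg$odors) - 1)
})
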