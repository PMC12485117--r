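# Planted trial tensor: disjoint odor-tuned voxel sets carrying a
# kernel-shaped response of amplitude `amp` on top of Gaussian noise.
planted_tensor <- function(n_per = 10, V = 12, F = 16, amp = 1, noise = 0.2,
                           seed = 1, odors = c("OCT", "MCH", "EA"),
                           tuned = split(1:9, rep(1:3, each = 3))) {
  set.seed(seed)
  n <- n_per * length(odors)
  odor <- rep(odors, n_per)
  session <- rep(seq_len(n_per), each = length(odors))
  shape <- response_kernel((0:(F - 1)) / 2.3, delay = 0.2, rise_tau = 0.2,
                           decay_tau = 1.5, amplitude = 1)
  arr <- array(rnorm(n * V * F, sd = noise), c(n, V, F))
  for (k in seq_along(tuned)) {
    idx <- which(odor == odors[k])
    for (v in tuned[[k]])
      arr[idx, v, ] <- arr[idx, v, ] +
        matrix(shape * amp, nrow = length(idx), ncol = F, byrow = TRUE)
  }
  structure(list(values = arr, window_offsets = 0:(F - 1), odor = odor,
                 session = session, frame_rate = 2.3),
            class = "trial_tensor")
}

chance_band <- function(n, p = 1 / 3, k = 3) k * sqrt(p * (1 - p) / n)

test_that("region classifier recovers planted ensembles and stays at chance on noise", {
  tt <- planted_tensor(amp = 1, noise = 0.2, seed = 41)
  res <- region_classify(tt, decoder_spec(seed = 5))
  expect_gte(res$accuracy, 0.9)
  expect_equal(res$accuracy, mean(res$fold_accuracy))
  null <- planted_tensor(amp = 0, noise = 0.2, seed = 42)
  res0 <- region_classify(null, decoder_spec(seed = 5))
  expect_lt(abs(res0$accuracy - 1 / 3), chance_band(30) + 0.05)
})

test_that("every trial is tested exactly once per cross-validation run", {
  tt <- planted_tensor(seed = 43)
  res <- region_classify(tt, decoder_spec(seed = 1))
  expect_equal(length(res$predictions), 30)
  expect_false(any(res$predictions == ""))
  expect_equal(sort(unique(res$folds)), 1:5)
  expect_true(all(table(res$folds, res$labels) >= 1))
})

test_that("no test-trial information enters the fitted transforms", {
  tt <- planted_tensor(seed = 44)
  res1 <- region_classify(tt, decoder_spec(seed = 9))
  # perturb only the test trials of fold 1 and refit
  perturbed <- tt
  te <- which(res1$folds == 1)
  perturbed$values[te, , ] <- perturbed$values[te, , ] + 5
  res2 <- region_classify(perturbed, decoder_spec(seed = 9))
  t1 <- res1$transforms[[1]]; t2 <- res2$transforms[[1]]
  expect_identical(t1$pca$rotation, t2$pca$rotation)
  expect_identical(t1$lda$scaling, t2$lda$scaling)
  expect_identical(t1$svm$models[[1]]$coefs, t2$svm$models[[1]]$coefs)
  # but the training set matters: perturbing training trials changes the PCA
  perturbed2 <- tt
  trn <- which(res1$folds == 2)
  perturbed2$values[trn, , ] <- perturbed2$values[trn, , ] + 5
  res3 <- region_classify(perturbed2, decoder_spec(seed = 9))
  expect_false(identical(res1$transforms[[1]]$pca$rotation,
                         res3$transforms[[1]]$pca$rotation))
})

test_that("accuracy is non-decreasing in planted amplitude", {
  accs <- vapply(c(0.1, 0.5, 2), function(a) {
    tt <- planted_tensor(amp = a, noise = 1, seed = 45)
    region_classify(tt, decoder_spec(seed = 2))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], accs[1])
})

test_that("multi-region decoding: duplicate channel adds nothing, complementary channel helps", {
  coords <- cbind(1:12, 1, 1)
  # duplicated channel: same information, accuracy equal within CV noise
  tt <- planted_tensor(amp = 0.6, noise = 0.5, seed = 46)
  single <- multiregion_classify(tt, coords, spec = decoder_spec(seed = 3, pca2_dims = 10))
  dual <- multiregion_classify(list(tt, tt), coords,
                               spec = decoder_spec(seed = 3, pca2_dims = 10))
  expect_lt(abs(dual$accuracy - single$accuracy), 0.15)
  # channel A cannot separate MCH from EA; channel B can
  ttA <- planted_tensor(amp = 1, noise = 0.2, seed = 47,
                        tuned = list(1:3, 4:6, 4:6))
  ttB <- planted_tensor(amp = 1, noise = 0.2, seed = 48,
                        tuned = list(integer(0), integer(0), 7:9))
  a_only <- multiregion_classify(ttA, coords, spec = decoder_spec(seed = 3, pca2_dims = 10))
  both <- multiregion_classify(list(ttA, ttB), coords,
                               spec = decoder_spec(seed = 3, pca2_dims = 10))
  expect_gt(both$accuracy, a_only$accuracy + 0.1)
  expect_gt(both$accuracy, 0.9)
  expect_lt(a_only$accuracy, 0.8)
})

test_that("label permutation drives the multi-region tier to chance", {
  coords <- cbind(1:12, 1, 1)
  tt <- planted_tensor(amp = 1, noise = 0.2, seed = 49)
  accs <- vapply(1:5, function(s) {
    multiregion_classify(permute_labels(tt, seed = s), coords,
                         spec = decoder_spec(seed = s, pca2_dims = 10))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), chance_band(30 * 5) + 0.05)
})

test_that("identification weights concentrate on informative voxels", {
  coords <- cbind(1:12, 1, 1)
  # voxel 1 carries all OCT information; voxel 2 duplicates voxel 1
  tt <- planted_tensor(amp = 1.5, noise = 0.1, seed = 50,
                       tuned = list(1, 5, 9))
  tt$values[, 2, ] <- tt$values[, 1, ]
  res <- multiregion_classify(tt, coords, spec = decoder_spec(seed = 4, pca2_dims = 10))
  w <- identification_weight_map(res)
  oct <- w[, "OCT"]
  expect_true(all(rank(-oct)[c(1, 2)] <= 4))
  # duplicates share weight (up to sign conventions inside the maps)
  expect_lt(abs(oct[1] - oct[2]) / max(oct), 0.35)
  expect_equal(colnames(w), c("EA", "MCH", "OCT"))
})

test_that("block accuracy maps localize signal and duplicated channels give zero gain", {
  V <- 12
  coords <- cbind(1:V, 1, 1)          # blocks of 4 voxels along x
  tt <- planted_tensor(V = V, amp = 1.2, noise = 0.2, seed = 51,
                       tuned = list(1:2, 3:4, integer(0)))
  out <- block_accuracy_map(tt, coords, decoder_spec(seed = 6))
  expect_equal(length(out$block_accuracy), 3)
  expect_gt(out$block_accuracy[["1_1_1"]], 0.85)
  expect_lt(out$block_accuracy[["3_1_1"]], 1 / 3 + chance_band(30) + 0.1)
  expect_equal(out$map$values[1], out$block_accuracy[["1_1_1"]])
  dual <- block_accuracy_map(list(tt, tt), coords, decoder_spec(seed = 6))
  gain <- accuracy_gain_map(dual, out)
  expect_lt(max(abs(gain$values)), 0.2)
})

test_that("brain-region-level decoding works on region-averaged traces", {
  tt <- planted_tensor(V = 9, amp = 1, noise = 0.15, seed = 52,
                       tuned = list(1:3, 4:6, 7:9))
  atlas <- rep(1:3, each = 3)
  reg <- vapply(1:3, function(r) apply(tt$values[, atlas == r, , drop = FALSE],
                                       c(1, 3), mean),
                array(0, c(30, 16)))
  reg_tt <- tt
  reg_tt$values <- aperm(reg, c(1, 3, 2))
  res <- brainregion_classify(reg_tt, decoder_spec(seed = 7))
  expect_gte(res$accuracy, 0.9)
  # ablation: dropping an uninformative constant region changes nothing
  with_junk <- reg_tt
  with_junk$values <- with_junk$values[, c(1, 2, 3, 3), ]
  with_junk$values[, 4, ] <- 0
  res2 <- brainregion_classify(with_junk, decoder_spec(seed = 7))
  expect_lt(abs(res2$accuracy - res$accuracy), 0.1)
  null <- planted_tensor(V = 4, amp = 0, noise = 0.3, seed = 53,
                         tuned = list(integer(0)))
  res0 <- brainregion_classify(null, decoder_spec(seed = 7))
  expect_lt(abs(res0$accuracy - 1 / 3), chance_band(30) + 0.05)
})
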