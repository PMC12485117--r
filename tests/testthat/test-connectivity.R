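test_that("functional connectivity matches a textbook Pearson loop oracle", {
  set.seed(20)
  tr <- matrix(rnorm(6 * 80), nrow = 6)
  tr[2, ] <- tr[1, ]                       # duplicated node
  fc <- build_fc(tr, edge_rule = "all")
  expect_equal(fc$corr[1, 2], 1)
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(fc$corr[i, j], pearson(tr[i, ], tr[j, ]), tolerance = 1e-12)
  expect_equal(fc$corr, t(fc$corr), tolerance = 1e-12)
  expect_true(all(diag(fc$corr) == 1))
})

test_that("top-fraction edge rule keeps the ceiling of q * pairs", {
  set.seed(21)
  tr <- matrix(rnorm(4 * 50), nrow = 4)
  fc <- build_fc(tr, edge_rule = "top_fraction", q = 0.30)
  expect_equal(nrow(fc$edges), ceiling(0.3 * 6))   # 2 of 6 pairs
  # the kept edges are the 2 largest correlations
  ut <- fc$corr[upper.tri(fc$corr)]
  expect_equal(sort(fc$edges$weight, decreasing = TRUE),
               sort(ut, decreasing = TRUE)[1:2])
  # zero-variance node excluded from ranking
  tr[1, ] <- 5
  fc2 <- build_fc(tr, edge_rule = "top_fraction", q = 0.5)
  expect_false(any(fc2$edges$from == 1 | fc2$edges$to == 1))
})

test_that("community detection separates disconnected cliques", {
  n <- 8
  tr <- matrix(0, n, n);
  A <- matrix(0, n, n)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
  fc <- list(edges = igraph::as_data_frame(g) |>
               (\(d) data.frame(from = as.integer(d$from),
                                to = as.integer(d$to),
                                weight = d$weight))(),
             corr = A)
  class(fc) <- "fc_matrix"
  out <- detect_communities(fc, "both", seed = 1)
  expect_equal(length(unique(out$louvain$assignment)), 2)
  expect_equal(length(unique(out$greedy$assignment)), 2)
  expect_equal(out$agreement, 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(out$agreement,
                 mclust::adjustedRandIndex(out$louvain$assignment,
                                           out$greedy$assignment))
  }
})

test_that("planted two-block correlation structure is recovered", {
  set.seed(22)
  n_per <- 10
  shared1 <- rnorm(300); shared2 <- rnorm(300)
  tr <- rbind(t(replicate(n_per, shared1 + rnorm(300, sd = 0.3))),
              t(replicate(n_per, shared2 + rnorm(300, sd = 0.3))))
  fc <- build_fc(tr, edge_rule = "top_fraction", q = 0.3)
  part <- detect_communities(fc, "louvain", seed = 2)
  truth <- rep(1:2, each = n_per)
  expect_equal(olfactr:::adjusted_rand_index(part$assignment, truth), 1)
})

test_that("community ratio follows the combinatorial oracle", {
  # complete uniform graph on n nodes, target community of k nodes
  n <- 8; k <- 3
  tr <- NULL
  M <- matrix(0.5, n, n); diag(M) <- 1
  ut <- which(upper.tri(M), arr.ind = TRUE)
  fc <- structure(list(corr = M,
                       edges = data.frame(from = ut[, 1], to = ut[, 2],
                                          weight = M[ut])),
                  class = "fc_matrix")
  assign_ <- c(rep(1, k), rep(2, n - k))
  olf <- c(rep(TRUE, k), rep(FALSE, n - k))
  expect_equal(community_ratio(fc, assign_, olf), choose(k, 2) / choose(n, 2))
  # all weight inside the target -> 1; none inside -> 0
  fc$edges <- data.frame(from = c(1, 2), to = c(2, 3), weight = c(1, 1))
  expect_equal(community_ratio(fc, assign_, olf), 1)
  fc$edges <- data.frame(from = 4, to = 5, weight = 1)
  expect_equal(community_ratio(fc, assign_, olf), 0)
  expect_error(community_ratio(fc, assign_, rep(FALSE, n)), "olfactory")
})

test_that("weighted degrees equal adjacency row sums", {
  M <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  fc <- structure(list(corr = M,
                       edges = data.frame(from = ut[, 1], to = ut[, 2],
                                          weight = M[ut])),
                  class = "fc_matrix")
  nd <- node_degrees(fc)
  oracle <- rowSums(M) - 1
  expect_equal(nd$degree, oracle)
  expect_equal(nd$average_degree, mean(oracle))
  # star with unit weights
  star <- structure(list(corr = diag(5),
                         edges = data.frame(from = 1, to = 2:5, weight = 1)),
                    class = "fc_matrix")
  expect_equal(node_degrees(star)$degree, c(4, 1, 1, 1, 1))
})

test_that("deflation ratio and difference matrix obey the formula oracle", {
  M <- matrix(c(1, .3, .5, .3, 1, .7, .5, .7, 1), 3)
  mbar <- mean(M[row(M) != col(M)])
  expect_equal(deflation_ratio(M), (M - mbar) / mbar, tolerance = 1e-15)
  # constant matrix -> all zeros; positive scaling leaves it unchanged
  K <- matrix(0.4, 3, 3)
  expect_true(all(deflation_ratio(K) == 0))
  expect_equal(deflation_ratio(2.7 * M), deflation_ratio(M), tolerance = 1e-12)
  expect_error(deflation_ratio(matrix(c(0, 1, -1, 0), 2)), "undefined")
  set.seed(23)
  A <- matrix(runif(16, .1, .9), 4); A <- (A + t(A)) / 2; diag(A) <- 1
  B <- matrix(runif(16, .1, .9), 4); B <- (B + t(B)) / 2; diag(B) <- 1
  d <- difference_matrix(A, B)
  ma <- mean(A[row(A) != col(A)]); mb <- mean(B[row(B) != col(B)])
  expect_equal(d$delta, (A - ma) / ma - (B - mb) / mb, tolerance = 1e-12)
  expect_true(all(difference_matrix(B, B)$delta == 0))
  expect_equal(max(abs(difference_matrix(3 * B, B)$delta)), 0,
               tolerance = 1e-12)
  expect_error(difference_matrix(A, matrix(1, 3, 3)), "alignment")
})

test_that("complementation metric equals a mask-and-mean loop oracle", {
  set.seed(24)
  n <- 8
  D <- matrix(rnorm(n * n), n); D <- (D + t(D)) / 2
  cl <- rep(1:2, each = 4)
  got <- complementation_metric(D, cl)
  w <- c(); b <- c()
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (cl[i] == cl[j]) w <- c(w, D[i, j]) else b <- c(b, D[i, j])
  }
  pm <- function(x) if (any(x > 0)) mean(x[x > 0]) else 0
  expect_equal(got, pm(w) - pm(b), tolerance = 1e-12)
  # positive only within clusters -> mean(within positives)
  D2 <- matrix(-1, n, n); D2[1:4, 1:4] <- 0.5; D2[5:8, 5:8] <- 0.25
  expect_equal(complementation_metric(D2, cl), (12 * 0.5 + 12 * 0.25) / 24)
  expect_error(complementation_metric(D, rep(1, n)), "single cluster")
})

test_that("clustering coefficient matches brute-force triangle counting", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  expect_equal(clustering_coefficient(tri)$global, 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(star)$global, 0)
  set.seed(25)
  n <- 12
  A <- matrix(rbinom(n * n, 1, 0.4), n); A[lower.tri(A)] <- 0; diag(A) <- 0
  A <- A + t(A)
  got <- clustering_coefficient(A)
  # brute force: enumerate neighbor pairs
  oracle <- sapply(1:n, function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2) return(0)
    e <- 0
    for (i in seq_along(nb)) for (j in seq_len(i - 1))
      e <- e + A[nb[i], nb[j]]
    2 * e / (length(nb) * (length(nb) - 1))
  })
  expect_equal(got$local, oracle, tolerance = 1e-12)
  g <- igraph::graph_from_adjacency_matrix(A, "undirected")
  ig <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  expect_equal(got$local, ig, tolerance = 1e-12)
})

test_that("Wasserstein distance matches closed forms and the OT oracle", {
  expect_equal(wasserstein_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_distance(rep(2, 5), rep(7.5, 5)), 5.5)
  set.seed(26)
  # exhaustive assignment oracle: min over permutations of mean |a - b_perm|
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (rep_i in 1:3) {
    a <- rnorm(6); b <- rnorm(6)
    oracle <- min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1)))
    expect_equal(wasserstein_distance(a, b), oracle, tolerance = 1e-9)
  }
  # symmetry and non-negativity
  a <- rnorm(10); b <- rnorm(15)
  expect_equal(wasserstein_distance(a, b), wasserstein_distance(b, a))
  expect_gte(wasserstein_distance(a, b), 0)
})

test_that("energy distance is a metric-like discrepancy", {
  a <- c(1, 2, 3, 4)
  expect_equal(energy_distance(a, a), 0)
  expect_equal(centrality_distance(a, a + 2, "energy"),
               energy_distance(a, a + 2))
  expect_equal(energy_distance(a, a + 2), energy_distance(a + 2, a))
  expect_gt(energy_distance(a, a + 2), 0)
  expect_equal(centrality_distance(c(1, 5), c(2, 4), "wasserstein"),
               wasserstein_distance(c(1, 5), c(2, 4)))
})

test_that("ensemble connectivity separates planted odor ensembles", {
  set.seed(27)
  n_trials <- 18; w <- 8
  odor <- rep(c("A", "B"), each = 9)
  arr <- array(rnorm(n_trials * 6 * w, sd = 0.2), c(n_trials, 6, w))
  sigA <- matrix(rnorm(9 * w), 9, w)
  sigB <- matrix(rnorm(9 * w), 9, w)
  for (v in 1:3) arr[odor == "A", v, ] <- arr[odor == "A", v, ] + sigA
  for (v in 4:6) arr[odor == "B", v, ] <- arr[odor == "B", v, ] + sigB
  tt <- structure(list(values = arr, window_offsets = 0:(w - 1), odor = odor,
                       session = rep(1:9, 2), frame_rate = 2.3),
                  class = "trial_tensor")
  coords <- cbind(1:6, 1, 1)
  out <- ensemble_fc(tt, list(A = 1:3, B = 4:6), coords)
  C <- out$fc$corr
  within <- c(C[1, 2], C[1, 3], C[2, 3], C[4, 5], C[4, 6], C[5, 6])
  between <- as.vector(C[1:3, 4:6])
  expect_gt(mean(within), mean(between) + 0.3)
  # two voxels at distance d with correlation c -> weighted coverage d * c
  tt2 <- tt; tt2$values <- arr[, 1:2, , drop = FALSE]
  coords2 <- rbind(c(0, 0, 0), c(3, 4, 0))
  out2 <- ensemble_fc(tt2, list(A = 1:2), coords2)
  expect_equal(out2$per_odor$A$weighted_coverage,
               5 * out2$fc$corr[1, 2], tolerance = 1e-12)
})
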