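# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic entry points route
# through this so that a seed argument fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stratified fold assignment: each class is spread as evenly as possible
# across k folds; returns an integer fold id per observation.
stratified_folds <- function(labels, k, seed = NULL) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  n <- length(labels)
  if (min(table(labels)) < k)
    stop("stratification error: some class has fewer than ", k, " trials")
  with_seed(seed, {
    folds <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

# Adjusted Rand index between two partitions (vectors of labels).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Pearson correlation of each row of `mat` with vector `y`, plus two-sided
# p-values from the t distribution. Zero-variance rows give NA.
row_cor_test <- function(mat, y) {
  n <- length(y)
  stopifnot(ncol(mat) == n)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- mat - rowMeans(mat)
  sx <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% yc) / (sx * sy)
  r[!is.finite(r)] <- NA_real_
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

# md5 fingerprint of an R object (serialized via a scratch file).
object_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

# Euclidean distance between rows of two equally-shaped matrices.
row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

`%||%` <- function(x, y) if (is.null(x)) y else x
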