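#' Uniform statistical test record
#'
#' @param statistic test statistic.
#' @param p_value p value in `[0, 1]`.
#' @param effect_size effect size where defined (`NA` otherwise).
#' @param df degrees of freedom (may be `NA`).
#' @param method test label.
#' @param sided `"two"` or `"one"`.
#' @return An object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, effect_size = NA_real_,
                        df = NA_real_, method = "test", sided = "two") {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 effect_size = unname(effect_size), df = unname(df),
                 method = method, sided = sided),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, " (", x$sided, "-sided): statistic = ",
      signif(x$statistic, 4), ", df = ", x$df, ", p = ",
      signif(x$p_value, 4),
      if (!is.na(x$effect_size)) paste0(", effect = ",
                                        signif(x$effect_size, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Scheirer-Ray-Hare nonparametric two-way ANOVA
#'
#' All observations are ranked jointly (midranks for ties); two-way ANOVA
#' sums of squares are computed on the ranks, and each effect's statistic is
#' `H = SS_effect / MS_total`, where `MS_total` is the total variance of the
#' ranks (which carries the tie correction automatically, since tied ranks
#' shrink the total rank variance by exactly the standard correction
#' factor). P-values come from the chi-squared distribution with the
#' effect's degrees of freedom. For unbalanced designs the main-effect sums
#' of squares use group sizes as weights and the interaction is the cell
#' sum of squares minus both main effects.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factor labels (at least 2 levels each; every
#'   cell must contain at least one observation).
#' @return named list of `test_result` objects for `A`, `B`, and
#'   `interaction`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", rownames(cells)[empty[1]], " x ",
         colnames(cells)[empty[2]])
  }
  r <- rank(values)
  n <- length(r)
  grand <- mean(r)
  ss <- function(groups) {
    m <- tapply(r, groups, mean)
    cnt <- tapply(r, groups, length)
    sum(cnt * (m - grand)^2)
  }
  ss_a <- ss(a)
  ss_b <- ss(b)
  ss_cells <- ss(interaction(a, b, drop = TRUE))
  ss_ab <- ss_cells - ss_a - ss_b
  ss_total <- sum((r - grand)^2)
  ms_total <- ss_total / (n - 1)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  mk <- function(ss_eff, df, label) {
    if (ms_total == 0) return(test_result(0, 1, df = df, method = label))
    h <- ss_eff / ms_total
    h <- max(h, 0)
    test_result(h, pchisq(h, df, lower.tail = FALSE), df = df,
                method = label, sided = "two")
  }
  list(A = mk(ss_a, df_a, "Scheirer-Ray-Hare (factor A)"),
       B = mk(ss_b, df_b, "Scheirer-Ray-Hare (factor B)"),
       interaction = mk(ss_ab, df_ab, "Scheirer-Ray-Hare (interaction)"))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values plus rejection flags at level `alpha`.
#'
#' @param p_values raw p-values.
#' @param alpha FDR level.
#' @return list with `adjusted` and `reject`.
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj < alpha)
}

#' Nonparametric test battery with uniform records
#'
#' Thin wrappers around the standard nonparametric tests, returning
#' [test_result()] records with rank-based effect sizes: rank-biserial
#' correlation for Mann-Whitney (`1 - 2U/(n1 n2)`) and for the Wilcoxon
#' signed-rank test (`(W+ - W-) / (W+ + W-)`), epsilon-squared for
#' Kruskal-Wallis, and the D statistic itself for Kolmogorov-Smirnov.
#'
#' @param x first sample (or the sole sample for `"wilcoxon"` differences
#'   when `y` is given as the paired second sample).
#' @param y second sample (or `NULL`).
#' @param test one of `"mannwhitney"`, `"wilcoxon"`, `"ks"`, `"kruskal"`.
#' @param groups group labels for `"kruskal"` (with `x` the pooled values).
#' @param alternative `"two.sided"`, `"less"`, `"greater"`; one-sided
#'   directions must be stated explicitly, there is no auto-detection.
#' @return a `test_result`.
#' @export
test_battery <- function(x, y = NULL,
                         test = c("mannwhitney", "wilcoxon", "ks", "kruskal"),
                         groups = NULL, alternative = "two.sided") {
  test <- match.arg(test)
  sided <- if (alternative == "two.sided") "two" else "one"
  switch(test,
    mannwhitney = {
      ht <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                         exact = FALSE))
      u <- unname(ht$statistic)
      eff <- 1 - 2 * u / (length(x) * length(y))
      test_result(u, ht$p.value, effect_size = eff,
                  method = "Mann-Whitney U", sided = sided)
    },
    wilcoxon = {
      ht <- suppressWarnings(wilcox.test(x, y, paired = !is.null(y),
                                         alternative = alternative,
                                         exact = FALSE))
      d <- if (is.null(y)) x else x - y
      d <- d[d != 0]
      rk <- rank(abs(d))
      wp <- sum(rk[d > 0]); wm <- sum(rk[d < 0])
      eff <- if (wp + wm > 0) (wp - wm) / (wp + wm) else 0
      test_result(unname(ht$statistic), ht$p.value, effect_size = eff,
                  method = "Wilcoxon signed-rank", sided = sided)
    },
    ks = {
      ht <- suppressWarnings(ks.test(x, y, alternative = alternative))
      test_result(unname(ht$statistic), ht$p.value,
                  effect_size = unname(ht$statistic),
                  method = "Kolmogorov-Smirnov", sided = sided)
    },
    kruskal = {
      if (is.null(groups)) stop("groups required for Kruskal-Wallis")
      ht <- kruskal.test(x, factor(groups))
      n <- length(x)
      eff <- unname(ht$statistic) / (n - 1)       # epsilon-squared
      test_result(unname(ht$statistic), ht$p.value, effect_size = eff,
                  df = unname(ht$parameter), method = "Kruskal-Wallis",
                  sided = "two")
    })
}
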