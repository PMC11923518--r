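#' Group summary (mean, SEM, n)
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Number of animals/observations (>= 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n) {
  stopifnot(is.finite(mean), is.finite(sem), sem >= 0, n >= 2)
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' Summarize a sample as mean +/- SEM
#'
#' @param x Numeric sample, n >= 2.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite observations")
  group_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

fp_test_result <- function(statistic, df, p, method, df_pooled = NA_real_,
                           n1 = NA_integer_, n2 = NA_integer_) {
  structure(list(statistic = statistic, df = df, df_pooled = df_pooled,
                 p = p, method = method, n1 = n1, n2 = n2),
            class = "fp_test_result")
}

#' @export
print.fp_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g%s, p = %.4g\n",
              x$method, x$statistic, x$df,
              if (is.finite(x$df_pooled))
                sprintf(" (pooled df = %g)", x$df_pooled) else "",
              x$p))
  invisible(x)
}

#' Welch's t-test from group summaries
#'
#' Computes Welch's two-sample t statistic from printed summary values
#' (mean, SEM, n):
#' `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)`.  Two degrees-of-freedom
#' variants are reported: the Welch-Satterthwaite approximation
#' (which drives the returned p value) and the pooled `n1 + n2 - 2`
#' (`df_pooled`), a convention some reports use under a Welch label.
#' Two-sided p throughout.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return An object of class `fp_test_result`.
#' @export
welch_t_from_summaries <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  v1 <- g1$sem^2; v2 <- g2$sem^2       # sem^2 = s^2 / n
  if (v1 + v2 == 0) stop("both groups have zero SEM")
  t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  fp_test_result(t, df, p, "welch_t", df_pooled = g1$n + g2$n - 2,
                 n1 = g1$n, n2 = g2$n)
}

#' Welch's t-test from raw samples
#'
#' Exactly equivalent to [welch_t_from_summaries()] applied to the
#' groups' computed summaries.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @return An `fp_test_result`.
#' @export
welch_t_from_samples <- function(x, y) {
  res <- welch_t_from_summaries(summarize_group(x), summarize_group(y))
  res$method <- "welch_t"
  res
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = x - y`, `df = n - 1`, two-sided p.
#'
#' @param x,y Paired numeric samples of equal length n >= 2.
#' @return An `fp_test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance of the paired differences")
  t <- mean(d) / (sd_d / sqrt(n))
  fp_test_result(t, n - 1, 2 * stats::pt(-abs(t), n - 1), "paired_t",
                 n1 = n, n2 = n)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors, n >= 3, non-constant.
#' @return The sample correlation r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' Linear regression through the origin
#'
#' Least-squares slope with the intercept restricted to (0, 0):
#' `slope = sum(x * y) / sum(x^2)`.  Used for method-comparison plots of
#' ratio- versus difference-method peak magnitudes and times.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The slope.
#' @export
regression_through_origin <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L || sum(x^2) == 0) stop("sum of x^2 must be positive")
  sum(x * y) / sum(x^2)
}

#' Shapiro-Wilk normality test
#'
#' Gate applied before parametric tests; wraps the standard W statistic.
#'
#' @param x Numeric sample, 3 <= n <= 50 for the intended use.
#' @return An `fp_test_result` with the W statistic (df is `NA`).
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant sample")
  sw <- stats::shapiro.test(x)
  fp_test_result(unname(sw$statistic), NA_real_, sw$p.value, "shapiro",
                 n1 = length(x))
}

#' Express one mean as a percentage of another
#'
#' Convenience for statements of the form "the early-stage reduction was
#' as much as X% of the terminal reduction".
#'
#' @param a,b Numeric values (same units).
#' @return `100 * a / b`.
#' @export
percent_of <- function(a, b) {
  if (b == 0) stop("reference value must be nonzero")
  100 * a / b
}
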