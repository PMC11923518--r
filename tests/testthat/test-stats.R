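test_that("Welch t from summaries: symmetry and zero at equal means", {
  g <- group_summary(5, 1, 4)
  expect_equal(welch_t_from_summaries(g, g)$statistic, 0)
  a <- group_summary(2, 0.5, 5); b <- group_summary(4, 0.7, 6)
  expect_equal(welch_t_from_summaries(a, b)$statistic,
               -welch_t_from_summaries(b, a)$statistic)
  expect_equal(welch_t_from_summaries(a, b)$df_pooled, 9)
  expect_error(welch_t_from_summaries(group_summary(1, 0, 3),
                                      group_summary(2, 0, 3)), "zero SEM")
})

test_that("welch_t_from_samples agrees exactly with the summary formula", {
  set.seed(11)
  for (i in 1:100) {
    x <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, -2, 2))
    y <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 3))
    a <- welch_t_from_samples(x, y)
    b <- welch_t_from_summaries(summarize_group(x), summarize_group(y))
    expect_identical(a$statistic, b$statistic)
    expect_identical(a$df, b$df)
    expect_identical(a$p, b$p)
    expect_true(a$p >= 0 && a$p <= 1)
  }
  expect_equal(welch_t_from_samples(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

test_that("two-sided p matches numerical integration of the t density", {
  dens <- function(u, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + u^2 / df)^(-(df + 1) / 2)
  set.seed(21)
  for (i in 1:10) {
    x <- stats::rnorm(6); y <- stats::rnorm(8, 1)
    r <- welch_t_from_samples(x, y)
    p_quad <- 2 * stats::integrate(dens, abs(r$statistic), Inf,
                                   df = r$df, rel.tol = 1e-10)$value
    expect_equal(r$p, p_quad, tolerance = 1e-6)
  }
})

test_that("paired t: hand-computed case, antisymmetry, degenerate input", {
  # differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.464, df = 2
  x <- c(11, 22, 33); y <- c(10, 20, 30)
  r <- paired_t(x, y)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(paired_t(y, x)$statistic, -r$statistic)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, y[1:2]), "equal length")
})

test_that("pearson_r and regression_through_origin match their closed forms", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -2 * (1:10) + 5), -1)
  set.seed(31)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(pearson_r(x, y),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")

  expect_equal(regression_through_origin(1:5, 2 * (1:5)), 2)
  expect_equal(regression_through_origin(x, y), sum(x * y) / sum(x^2),
               tolerance = 1e-12)
  expect_error(regression_through_origin(numeric(0), numeric(0)), "positive")
})

test_that("Shapiro-Wilk gate separates normal from exponential samples", {
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  set.seed(41)
  keep_norm <- mean(replicate(100, shapiro_wilk(stats::rnorm(20))$p > 0.05))
  expect_gte(keep_norm, 0.9)
  reject_exp <- mean(replicate(100, shapiro_wilk(stats::rexp(50))$p < 0.05))
  expect_gte(reject_exp, 0.9)
})
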