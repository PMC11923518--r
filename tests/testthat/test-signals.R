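test_that("normalize_to_baseline arithmetic and idempotence", {
  t_s <- seq(-120, 60)
  x <- rep(2, length(t_s))
  expect_equal(as.numeric(normalize_to_baseline(x, t_s)), rep(0, length(x)))
  # F0 = 2.0, excursion to 1.5 -> -25%
  x[t_s == 30] <- 1.5
  n1 <- normalize_to_baseline(x, t_s)
  expect_equal(n1[t_s == 30], -25)
  expect_equal(attr(n1, "F0"), 2)
  # re-normalizing the %-trace shifted around a 100 offset changes nothing
  n2 <- normalize_to_baseline(as.numeric(n1) + 100, t_s)
  expect_equal(as.numeric(n2), as.numeric(n1), tolerance = 1e-12)
  expect_error(normalize_to_baseline(x - 10, t_s), "positive")
  expect_error(normalize_to_baseline(x, t_s, c(500, 600)), "baseline window")
})

test_that("ratio_signal orientation and small-signal algebra", {
  t_s <- seq(-120, 10)
  n <- length(t_s)
  ch <- channel_traces(data.frame(time_s = t_s, fCFP = rep(1, n),
                                  fYFP = rep(1, n)))
  expect_equal(ratio_signal(ch, "ATeam")$value, rep(1, n))
  # fYFP = (1+e)c, fCFP = (1-e)c -> ratio ~ 1 + 2e for small e
  e <- 0.01
  ch2 <- channel_traces(data.frame(time_s = t_s, fCFP = (1 - e) * 2,
                                   fYFP = rep((1 + e) * 2, n)))
  expect_equal(ratio_signal(ch2, "ATeam")$value,
               rep((1 + e) / (1 - e), n), tolerance = 1e-12)
  expect_equal(ratio_signal(ch2, "ATeam")$value[1], 1 + 2 * e,
               tolerance = 1e-3)
  # PYRS flips numerator and denominator
  expect_equal(ratio_signal(ch2, "PYRS")$value,
               rep((1 - e) / (1 + e), n), tolerance = 1e-12)
  ch3 <- ch
  ch3$fCFP[5] <- 0
  expect_error(ratio_signal(ch3, "ATeam"), "denominator")
})

test_that("calibrated ratio proxy reproduces the injected fluorescence change exactly", {
  # ligand staircase through the forward model, no confounds or noise
  sp <- ateam_params()
  g <- seq(-120, 120)
  lig <- simulate_atp_transient(-20, grid = g)
  em <- fret_emissions(as.numeric(lig), sp, time_s = g)
  rat <- ratio_signal(em, "ATeam", as_percent = TRUE, sensor_params = sp,
                      baseline_ligand = 2.3)
  expect_equal(rat$value, attr(lig, "fluo_pct"), tolerance = 1e-6)
})

test_that("difference_signal arithmetic and orientation for both sensors", {
  t_s <- 0:4
  z <- rep(0, 5)
  expect_equal(difference_signal(z + 3, z + 3, t_s, "ATeam")$value, z)
  expect_equal(difference_signal(z - 10, z + 5, t_s, "ATeam")$value[1], -15)
  expect_equal(difference_signal(z - 10, z + 5, t_s, "PYRS")$value[1], 15)
  expect_error(difference_signal(z, z[-1], t_s, "ATeam"), "match")
})

test_that("a ligand increase raises both proxies for both sensors", {
  for (cfgs in list(list(sp = ateam_params(), base = 2.3, sn = "ATeam"),
                    list(sp = pyrs_params(), base = 15, sn = "PYRS"))) {
    g <- seq(-120, 60)
    lig <- rep(cfgs$base, length(g))
    lig[g >= 0] <- cfgs$base * 1.5
    em <- fret_emissions(lig, cfgs$sp, time_s = g)
    nm <- normalize_channels(em)
    dif <- difference_signal(nm$fYFP, nm$dYFP, nm$time_s, cfgs$sn)
    rat <- ratio_signal(em, cfgs$sn)
    expect_gt(mean(dif$value[g > 0]), 0)
    expect_gt(mean(rat$value[g > 0]), mean(rat$value[g < 0]))
  }
})

test_that("detrend_texasred recovers a rectangular dip on a sloping baseline", {
  t_s <- seq(-120, 400)
  line <- 5 - 0.01 * t_s
  dip <- ifelse(t_s >= 10 & t_s <= 40, -0.5, 0)
  out <- detrend_texasred(line + dip, t_s)
  expect_lt(max(abs(out - dip)), 1e-9)
  # exactly linear input -> residual identically zero
  expect_lt(max(abs(detrend_texasred(line, t_s))), 1e-9)
  expect_error(detrend_texasred(line[1:5], t_s[1:5],
                                fit_windows = list(c(-120, -118))),
               "fewer than")
})

test_that("invert is an involution and perfectly anti-correlates", {
  x <- stats::rnorm(50)
  expect_identical(invert(invert(x)), x)
  expect_identical(invert(0), 0)
  expect_equal(stats::cor(x, invert(x)), -1)
  tr <- fp_trace(1:5, c(1, -2, 3, -4, 5))
  expect_equal(invert(tr)$value, -tr$value)
})
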