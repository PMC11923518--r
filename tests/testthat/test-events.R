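test_that("bandpass_eeg frequency response: drift blocked, pass-band unity, DC removed", {
  fs <- 2000
  t_s <- seq(0, 40 - 1 / fs, by = 1 / fs)
  gain <- function(f0) {
    x <- sin(2 * pi * f0 * t_s)
    y <- bandpass_eeg(x, fs)
    keep <- t_s > 2 & t_s < 38   # ignore wrap-around edges
    sqrt(mean(y[keep]^2) / mean(x[keep]^2))
  }
  expect_lt(gain(0.1), 0.10)            # >= 90% attenuation of slow drift
  expect_equal(gain(10), 1, tolerance = 0.05)
  expect_equal(gain(50), 1, tolerance = 0.05)
  expect_lt(gain(150), 0.1)             # >= 20 dB above the band
  dc <- bandpass_eeg(rep(3, fs * 10), fs)
  expect_lt(max(abs(dc)), 1e-9)
  expect_error(bandpass_eeg(rnorm(100), fs = 150, low = 1, high = 100),
               "sampling rate")
  expect_error(bandpass_eeg(rnorm(100), low = 10, high = 5), "band edges")
})

test_that("detect_ad_duration: noise gives 0, a synthetic AD is recovered within 1 s", {
  tt <- seq(-60, 60, by = 5e-4)
  noise <- simulate_eeg(0, noise_rms = 0.05, grid_2khz = tt, seed = 4)
  d0 <- detect_ad_duration(bandpass_eeg(noise), tt)
  expect_equal(as.numeric(d0), 0)

  for (dur in c(5, 15)) {
    eeg <- simulate_eeg(dur, noise_rms = 0.05, grid_2khz = tt, seed = 4)
    d <- detect_ad_duration(bandpass_eeg(eeg), tt)
    expect_lt(abs(as.numeric(d) - dur), 1)
  }
  expect_error(detect_ad_duration(noise, tt, stim_start = -55), "baseline")
})

test_that("find_extremum equals a brute-force scan and has documented edge semantics", {
  set.seed(77)
  for (i in 1:25) {
    x <- stats::rnorm(50)
    t_s <- 0:49
    w <- sort(sample(0:49, 2))
    if (diff(w) < 2) w <- c(0, 49)
    idx <- which(t_s >= w[1] & t_s <= w[2])
    mn <- find_extremum(x, t_s, w, "min")
    mx <- find_extremum(x, t_s, w, "max")
    expect_equal(mn$magnitude, min(x[idx]))
    expect_equal(mn$time, t_s[idx][which(x[idx] == min(x[idx]))[1]])
    expect_equal(mx$magnitude, max(x[idx]))
  }
  # monotone decreasing trace: minimum sits on the window end
  x <- 100 - (0:49)
  expect_equal(find_extremum(x, 0:49, c(10, 30), "min")$time, 30)
  # ties break to the earliest sample
  expect_equal(find_extremum(rep(1, 50), 0:49, c(5, 20), "min")$time, 5)
  expect_error(find_extremum(x, 0:49, c(10, 11), "min"), "3 samples")
})

test_that("onset_by_inflection lands at the analytic sigmoid inflection", {
  # f(t) = -A / (1 + exp(-(t - t0)/tau)): negative peak of f'' at t0 - 1.317 tau
  t_s <- 0:199
  t0 <- 100; tau <- 8
  f <- -20 / (1 + exp(-(t_s - t0) / tau))
  on <- onset_by_inflection(f, t_s, c(0, 199), smooth_s = 1)
  expect_lt(abs(on - (t0 - 1.317 * tau)), 1)
  # light smoothing must not move it by more than a sample or two
  on5 <- onset_by_inflection(f, t_s, c(0, 199), smooth_s = 5)
  expect_lt(abs(on5 - (t0 - 1.317 * tau)), 2)
  # linear ramp: second derivative never negative -> onset undefined
  expect_error(onset_by_inflection(-0.5 * t_s, t_s, c(0, 199), smooth_s = 1),
               class = "fretfp_onset_undefined")
})

test_that("onset_by_baseline_crossing finds a clean step and errors on flat traces", {
  t_s <- seq(-120, 60)
  x <- numeric(length(t_s))
  x[t_s >= -120 & t_s <= -10] <- stats::rnorm(111, 0, 0.1)
  x[t_s >= 12] <- 5
  set.seed(3)
  expect_equal(onset_by_baseline_crossing(x, t_s), 12)
  expect_error(onset_by_baseline_crossing(numeric(length(t_s)) , t_s),
               class = "fretfp_onset_undefined")
})

test_that("segment_pyruvate_phases recovers generator breakpoints within 2 s", {
  g <- seq(-120, 900)
  spp <- pyrs_params()
  for (mode in c("rise", "decay")) {
    lig <- simulate_pyruvate_transient(p2_mode = mode, grid = g)
    em <- fret_emissions(as.numeric(lig), spp, time_s = g)
    nm <- normalize_channels(em)
    dif <- difference_signal(nm$fYFP, nm$dYFP, nm$time_s, "PYRS")
    # tiny baseline jitter so the baseline SD is defined
    set.seed(8)
    v <- dif$value + stats::rnorm(length(g), 0, 0.02)
    seg <- segment_pyruvate_phases(v, g)
    bp <- attr(lig, "breakpoints")
    expect_equal(seg$p2_mode, mode)
    expect_lt(abs(seg$t_onset - bp$t_onset), 2)
    expect_lt(abs(seg$t1 - bp$t1), 2)
    expect_lt(abs(seg$t2 - bp$t2), 2)
    expect_true(seg$has_dip)
    # plateau persists for tens of minutes
    expect_gt(seg$t3 - seg$t2, 600)
  }
  set.seed(9)
  expect_error(segment_pyruvate_phases(stats::rnorm(length(g), 0, 0.02), g),
               class = "fretfp_onset_undefined")
  expect_error(segment_pyruvate_phases(numeric(200), seq(-100, 99)),
               "post-stimulus")
})

test_that("cumulative_signal arithmetic and additivity over adjacent intervals", {
  t_s <- 0:59
  x <- numeric(60)
  expect_equal(cumulative_signal(x, t_s, 0, 30), 0)
  x[t_s >= 10 & t_s <= 19] <- -1
  expect_equal(cumulative_signal(x, t_s, 10, 19), -10)
  y <- stats::rnorm(60)
  expect_equal(cumulative_signal(y, t_s, 0, 20) +
                 cumulative_signal(y, t_s, 21, 59),
               cumulative_signal(y, t_s, 0, 59), tolerance = 1e-12)
  expect_error(cumulative_signal(y, t_s, -5, 10), "outside")
  expect_error(cumulative_signal(y, t_s, 10, 10), "t0 < t1")
})
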