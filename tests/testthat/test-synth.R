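grid1 <- seq(-120, 480)

test_that("ATP transient: zero amplitude is the identity, round trip hits the requested drop", {
  sp <- ateam_params()
  flat <- simulate_atp_transient(0, grid = grid1)
  expect_true(all(abs(as.numeric(flat) - 2.3) < 1e-12))

  # requested fluorescence drop recovered through the forward model
  for (amp in c(-10, -20.88, -38.04)) {
    lig <- simulate_atp_transient(amp, grid = grid1)
    em <- fret_emissions(as.numeric(lig), sp, time_s = grid1)
    fy <- normalize_to_baseline(em$fYFP, grid1)
    expect_lt(abs(min(fy) - amp), abs(amp) * 0.001 + 1e-9)
    expect_equal(grid1[which.min(fy)], attr(lig, "t_min"), tolerance = 1)
  }
  # non-recovering terminal collapse stays at the floor
  sud <- simulate_atp_transient(-38.04, recovery_tau_s = Inf, grid = grid1)
  g <- attr(sud, "fluo_pct")
  expect_lt(g[length(g)], -37.9)
  # amplitude outside the sensor's dynamic range errors
  expect_error(simulate_atp_transient(-99, grid = grid1), "non-physical")
  expect_error(simulate_atp_transient(5, grid = grid1), "amplitude")
})

test_that("pyruvate transient: flat when silent, rise mode peaks ~1 min post-stim", {
  g <- seq(-120, 900)
  flat <- simulate_pyruvate_transient(0, 0, plateau_amp_pct = 0, grid = g)
  expect_true(all(abs(as.numeric(flat) - 15) < 1e-9))

  lig <- simulate_pyruvate_transient(p2_mode = "rise", grid = g)
  pct <- attr(lig, "fluo_pct")
  expect_equal(g[which.max(pct)], 60, tolerance = 1)
  # plateau persists above baseline for tens of minutes
  expect_true(all(pct[g >= 180 & g <= 600] > 0))
  # decay mode: global max is the first-phase peak instead
  ligd <- simulate_pyruvate_transient(p2_mode = "decay", grid = g)
  expect_equal(g[which.max(attr(ligd, "fluo_pct"))], 21, tolerance = 1)
  expect_error(simulate_pyruvate_transient(grid = seq(-120, 100)), "plateau")
})

test_that("apply_confounds: identity at zero, exact arithmetic under a uniform shadow", {
  sp <- ateam_params()
  g <- seq(-60, 60)
  em <- fret_emissions(rep(2.3, length(g)), sp, time_s = g)
  out <- apply_confounds(em)
  expect_equal(as.data.frame(out), as.data.frame(em))

  # uniform -10% shadow: raw fYFP drops 10%, ratio and %-difference invariant
  bbv <- rep(0.1, length(g))   # dilation, shadow factor 0.9
  sh <- apply_confounds(em, bbv = bbv)
  expect_equal(sh$fYFP, 0.9 * em$fYFP, tolerance = 1e-12)
  expect_equal(sh$fYFP / sh$fCFP, em$fYFP / em$fCFP, tolerance = 1e-12)
  # normalized difference unchanged (identically zero here): use a ligand step
  lig <- c(rep(2.3, 80), rep(1.5, 41))
  em2 <- fret_emissions(lig, sp, time_s = g)
  sh2 <- apply_confounds(em2, bbv = bbv)
  n_a <- normalize_channels(em2, c(-60, -10), min_samples = 10)
  n_b <- normalize_channels(sh2, c(-60, -10), min_samples = 10)
  expect_equal(n_a$fYFP - n_a$dYFP, n_b$fYFP - n_b$dYFP, tolerance = 1e-9)

  expect_error(apply_confounds(em, bbv = rep(2, length(g))), "positive")
})

test_that("Texas Red co-varies with blood volume; constriction pairs a TR dip with a dYFP rise", {
  sp <- ateam_params()
  g <- seq(-120, 240)
  em <- fret_emissions(rep(2.3, length(g)), sp, time_s = g)
  bbv <- confound_bump(-0.05, 15, 8, g)   # constriction
  out <- apply_confounds(em, bbv = bbv,
                         texasred = list(base = 2, tau_s = 2700, offset = 0))
  # direct-arithmetic oracle: TR = base * exp(-(t - t0)/tau) * (1 + bbv)
  expect_equal(out$TexasRed, 2 * exp(-(g - g[1]) / 2700) * (1 + bbv),
               tolerance = 1e-12)
  act <- bbv != 0
  expect_gt(stats::cor(out$TexasRed[act] / (2 * exp(-(g[act] - g[1]) / 2700)),
                       bbv[act]), 0.999)
  tr_det <- detrend_texasred(out$TexasRed, g,
                             fit_windows = list(c(-120, -1), c(60, 240)))
  t_tr <- g[which.min(tr_det)]
  t_dy <- g[which.max(out$dYFP)]
  expect_lt(abs(t_tr - t_dy), 10)
})

test_that("simulate_eeg: seeded reproducibility, AD only when requested", {
  tt <- seq(-60, 60, by = 5e-4)
  a <- simulate_eeg(15, noise_rms = 0.05, grid_2khz = tt, seed = 9)
  b <- simulate_eeg(15, noise_rms = 0.05, grid_2khz = tt, seed = 9)
  expect_identical(a, b)
  expect_true(all(is.finite(a)))
  no_ad <- simulate_eeg(0, noise_rms = 0.05, grid_2khz = tt, seed = 9)
  post <- tt > 10.5
  # post-stimulus segment is indistinguishable from noise (no supra-noise burst)
  expect_lt(sqrt(mean(no_ad[post]^2)), 3 * 0.05)
  # with an AD the post-stimulus RMS is far above noise
  ad_seg <- tt > 10 & tt < 25
  expect_gt(sqrt(mean(a[ad_seg]^2)), 5 * 0.05)
})

test_that("seeded episode generation is bit-reproducible and finite", {
  e1 <- simulate_episode(seed = 31L)
  e2 <- simulate_episode(seed = 31L)
  expect_identical(e1$channels, e2$channels)
  expect_identical(e1$truth, e2$truth)
  expect_true(all(vapply(trace_channels(e1$channels),
                         function(ch) all(is.finite(e1$channels[[ch]])),
                         logical(1))))
})
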