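make_channels <- function(n = 20, f = function(i) cbind(fCFP = i, fYFP = 2 * i,
                                                        dYFP = rep(3, length(i)))) {
  i <- seq_len(n)
  channel_traces(data.frame(time_s = i - 0.5, f(i)))
}

test_that("demux recovers a constant recording and subtracts dark", {
  sched <- schedule_preset("dual")
  n <- 12 * 2000
  raw <- raw_recording(rep(2.1, n), rep(2.1, n), schedule = sched, dark = 0.1)
  out <- demux(raw)
  expect_equal(nrow(out), 12)
  for (ch in c("fCFP", "fYFP", "dYFP"))
    expect_equal(out[[ch]], rep(2.0, 12), tolerance = 1e-12)
})

test_that("demux is the exact inverse of synthesize_raw_recording at zero noise", {
  ch <- make_channels(25)
  raw <- synthesize_raw_recording(ch, noise_rms = 0, dark = 0.1)
  out <- demux(raw)
  expect_equal(out$time_s, ch$time_s)
  for (c_ in c("fCFP", "fYFP", "dYFP"))
    expect_equal(out[[c_]], ch[[c_]], tolerance = 1e-12)
  # triple configuration round trip too
  cht <- channel_traces(data.frame(time_s = (1:10) - 0.5, fYFP = 1:10,
                                   dYFP = 10:1, TexasRed = rep(2, 10)))
  rawt <- synthesize_raw_recording(cht, schedule_preset("triple"),
                                   dark = c(fYFP = 0.1, dYFP = 0.2,
                                            TexasRed = 0.05))
  outt <- demux(rawt)
  expect_equal(outt$TexasRed, cht$TexasRed, tolerance = 1e-12)
  expect_false("fCFP" %in% names(outt))
})

test_that("a 600 s recording under the dual schedule yields 600 samples per channel", {
  ch <- make_channels(600)
  out <- demux(synthesize_raw_recording(ch, dark = 0))
  expect_equal(nrow(out), 600)
  expect_equal(diff(out$time_s), rep(1, 599))
})

test_that("demux ignores samples outside pulse windows and is linear", {
  ch <- make_channels(10)
  raw <- synthesize_raw_recording(ch, noise_rms = 0, dark = 0)
  # corrupt inter-pulse samples (after 60 ms within each cycle)
  spoiled <- raw
  for (cyc in 0:9) {
    idx <- cyc * 2000 + 200:1900
    spoiled$pmt1[idx] <- 99
    spoiled$pmt2[idx] <- -42
  }
  expect_equal(as.data.frame(demux(spoiled)), as.data.frame(demux(raw)))

  # linearity at equal dark
  ch2 <- make_channels(10, f = function(i) cbind(fCFP = sin(i), fYFP = cos(i),
                                                 dYFP = sqrt(i)))
  r1 <- synthesize_raw_recording(ch, noise_rms = 0, dark = 0)
  r2 <- synthesize_raw_recording(ch2, noise_rms = 0, dark = 0)
  mix <- r1
  mix$pmt1 <- 2 * r1$pmt1 + 3 * r2$pmt1
  mix$pmt2 <- 2 * r1$pmt2 + 3 * r2$pmt2
  d1 <- demux(r1); d2 <- demux(r2); dm <- demux(mix)
  for (c_ in c("fCFP", "fYFP", "dYFP"))
    expect_equal(dm[[c_]], 2 * d1[[c_]] + 3 * d2[[c_]], tolerance = 1e-10)
})

test_that("measure_dark estimates the offset within 3 sigma / sqrt(n)", {
  sched <- schedule_preset("dual")
  ch <- channel_traces(data.frame(time_s = (1:60) - 0.5,
                                  fCFP = rep(0, 60), fYFP = rep(0, 60),
                                  dYFP = rep(0, 60)))
  raw <- synthesize_raw_recording(ch, noise_rms = 0.01, dark = 0.07, seed = 5)
  dk <- measure_dark(raw)
  n_pulse <- 40 * 60   # 20 ms pulse = 40 samples, 60 cycles
  expect_true(all(abs(dk - 0.07) < 3 * 0.01 / sqrt(n_pulse)))
  # constant 0.07 V segment: dark exactly 0.07 on every channel
  raw0 <- raw_recording(rep(0.07, 10 * 2000), rep(0.07, 10 * 2000),
                        schedule = sched)
  expect_true(all(measure_dark(raw0) == 0.07))
  expect_error(measure_dark(raw0, segment = c(0, 3)), "at least 5")
  # subtracting the measured dark recovers an injected constant signal
  chs <- channel_traces(data.frame(time_s = (1:30) - 0.5, fCFP = rep(1.5, 30),
                                   fYFP = rep(1.5, 30), dYFP = rep(1.5, 30)))
  raws <- synthesize_raw_recording(chs, noise_rms = 0, dark = 0.07)
  out <- demux(raws, dark = measure_dark(raw0))
  expect_equal(mean(out$fYFP), 1.5, tolerance = 1e-9)
})

test_that("schedule invariants: overlaps and bad mappings are rejected", {
  bad <- data.frame(label = c("Blue", "Teal"), start_ms = c(0, 15),
                    duration_ms = c(20, 20),
                    detector = c("pmt1", "pmt1"),
                    channel = c("fCFP", "dYFP"))
  expect_error(excitation_schedule(bad), "overlap")
  dup <- data.frame(label = "Blue", start_ms = 0, duration_ms = c(20, 20),
                    detector = "pmt1", channel = c("fCFP", "fYFP"))
  expect_error(excitation_schedule(dup), "only one channel")
  # preset layout: dual = Blue 20 ms, 10 ms gap, Teal 20 ms
  s <- schedule_preset("dual")
  teal <- s$pulses[s$pulses$label == "Teal", ]
  expect_equal(unique(teal$start_ms), 30)
  expect_equal(s$cycle_period_s, 1)
})

test_that("raw CSV round trip preserves the recording", {
  ch <- make_channels(8)
  raw <- synthesize_raw_recording(ch, noise_rms = 0.005, dark = 0.1, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_raw_csv(raw, f)
  back <- read_raw_csv(f, schedule = raw$schedule, dark = raw$dark)
  expect_equal(back$pmt1, raw$pmt1, tolerance = 1e-6)
  expect_equal(back$fs, raw$fs)
  unlink(f)
})
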