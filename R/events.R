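# Condition signalled when an onset/feature is genuinely undefined for a
# trace (e.g. linear ramp has no second-derivative minimum, or a proxy
# never crosses its baseline).  The pipeline converts these to NA.
onset_undefined <- function(msg) {
  stop(structure(class = c("fretfp_onset_undefined", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Centered moving average; width is forced odd, edges keep the original
# samples (shrinking window would bias slopes at the boundary; the
# analysis windows never reach the edges in practice).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  sm <- stats::filter(x, rep(1 / width, width), sides = 2)
  sm <- as.numeric(sm)
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

#' Zero-phase band-pass filter for EEG traces
#'
#' Frequency-domain filter with unit gain inside `[low, high]` Hz,
#' raised-cosine transition bands (`[low/2, low]` and
#' `[high, 1.2 * high]`) and zero gain outside, applied symmetrically in
#' the FFT domain so the filter is exactly zero-phase.  DC is removed
#' entirely.  The default 1-100 Hz band isolates epileptic slow
#' oscillations from drift, EMG contamination and motion artifacts.
#'
#' @param x EEG trace.
#' @param fs Sampling rate (Hz); must be >= `2 * high`.
#' @param low,high Pass-band edges (Hz), `0 < low < high`.
#' @return Filtered trace, same length.
#' @export
bandpass_eeg <- function(x, fs = 2000, low = 1, high = 100) {
  if (!(low > 0 && high > low)) stop("invalid band edges")
  if (fs < 2 * high) stop("sampling rate must be at least 2 * high")
  n0 <- length(x)
  # R's mixed-radix FFT degrades to O(n^2) for lengths with large prime
  # factors; pad to a highly composite length with a reflected tail and
  # truncate afterwards
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) {
    pad <- pmin(n - n0, n0)
    x <- c(x, rev(x)[seq_len(pad)], rep(x[1], n - n0 - pad))
  }
  f <- (seq_len(n) - 1L) * fs / n
  fa <- pmin(f, fs - f)                      # absolute frequency
  lo0 <- low / 2; hi1 <- 1.2 * high
  h <- numeric(n)
  h[fa >= low & fa <= high] <- 1
  tl <- fa > lo0 & fa < low
  h[tl] <- 0.5 * (1 - cos(pi * (fa[tl] - lo0) / (low - lo0)))
  th <- fa > high & fa < hi1
  h[th] <- 0.5 * (1 + cos(pi * (fa[th] - high) / (hi1 - high)))
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  y[seq_len(n0)]
}

#' Detect after-discharge duration from a filtered EEG trace
#'
#' A reproducible surrogate for the manual determination of AD cessation:
#' the amplitude envelope (RMS in `bin_s` bins, smoothed over `smooth_s`)
#' is compared with `k` times the pre-stimulus baseline RMS, and the AD
#' is taken to end at the last post-stimulus bin that belongs to a
#' sustained (`sustain_s`) supra-threshold run.  Returns 0 when the
#' envelope never exceeds threshold after stimulation -- the "no AD"
#' case.
#'
#' @param eeg Band-pass-filtered EEG trace (see [bandpass_eeg()]).
#' @param time_s Time stamps (s).
#' @param stim_start,stim_end Stimulation interval (s).
#' @param k Threshold in multiples of the baseline RMS (default 3).
#' @param bin_s Envelope bin width (s, default 0.5).
#' @param smooth_s Envelope smoothing span (s, default 1; a trailing
#'   mean over `smooth_s / bin_s` bins).
#' @param sustain_s Minimum supra-threshold run length (s, default 1).
#' @param min_baseline_s Minimum pre-stimulus baseline required (s).
#' @return AD duration (s), with attribute `ad_end` (s).
#' @export
detect_ad_duration <- function(eeg, time_s, stim_start = 0, stim_end = 10,
                               k = 3, bin_s = 0.5, smooth_s = 1,
                               sustain_s = 1, min_baseline_s = 30) {
  stopifnot(length(eeg) == length(time_s))
  base_idx <- which(time_s < stim_start - 1)
  if (length(base_idx) == 0 ||
      diff(range(time_s[base_idx])) < min_baseline_s)
    stop("need at least ", min_baseline_s, " s of pre-stimulus EEG baseline")
  base_rms <- sqrt(mean(eeg[base_idx]^2))
  # RMS envelope in non-overlapping bins
  bin <- floor((time_s - time_s[1]) / bin_s)
  rms <- sqrt(tapply(eeg^2, bin, mean))
  bin_end <- time_s[1] + (as.numeric(names(rms)) + 1) * bin_s
  nb <- max(1L, round(smooth_s / bin_s))
  env <- vapply(seq_along(rms), function(i)
    mean(rms[max(1L, i - nb + 1L):i]), numeric(1))
  post <- bin_end > stim_end
  hot <- post & env > k * base_rms
  run <- rle(hot)
  need <- max(1L, round(sustain_s / bin_s))
  ends <- cumsum(run$lengths)
  ok <- which(run$values & run$lengths >= need)
  if (length(ok) == 0L) {
    out <- 0
    attr(out, "ad_end") <- stim_end
    return(out)
  }
  ad_end <- bin_end[ends[max(ok)]]
  out <- ad_end - stim_end
  attr(out, "ad_end") <- ad_end
  out
}

#' Locate the extremum of a proxy trace within an analysis window
#'
#' Exhaustive scan for the minimum (`polarity = "min"`, e.g. the negative
#' peak of the ATP proxy) or maximum (`"max"`, e.g. the positive peak of
#' dYFP or pyruvate) over the window.  Ties are broken to the earliest
#' sample.  On a monotone trace the extremum lands on the window edge;
#' this edge semantics is intentional and documented.
#'
#' @param x Numeric trace.
#' @param time_s Time stamps (s).
#' @param window `[t0, t1]` analysis window (s); must contain >= 3
#'   samples.
#' @param polarity `"min"` or `"max"`.
#' @return List with `time` (s) and `magnitude`.
#' @export
find_extremum <- function(x, time_s, window, polarity = c("min", "max")) {
  polarity <- match.arg(polarity)
  stopifnot(length(x) == length(time_s))
  idx <- window_idx(time_s, window)
  if (length(idx) < 3L) stop("analysis window must contain at least 3 samples")
  j <- if (polarity == "min") which.min(x[idx]) else which.max(x[idx])
  list(time = time_s[idx[j]], magnitude = x[idx[j]])
}

#' Onset of a signal decline via the second-derivative inflection
#'
#' The onset of the ATP signal reduction is defined as the negative peak
#' of the (discrete) second derivative of the smoothed proxy -- the
#' inflection point where the decline accelerates fastest -- searched
#' within the analysis window and before the proxy's negative peak.
#'
#' @param x Proxy trace (% units).
#' @param time_s Time stamps (s), uniformly sampled.
#' @param window `[t0, t1]` search window (s), >= 10 samples.
#' @param smooth_s Centered moving-average span applied before
#'   differencing (s, default 5; raw second differences at 1 Hz are
#'   noise-dominated).
#' @return Onset time (s).  Signals a `fretfp_onset_undefined` condition
#'   when the second derivative has no negative values in the searched
#'   range (e.g. a linear trace).
#' @export
onset_by_inflection <- function(x, time_s, window, smooth_s = 5) {
  stopifnot(length(x) == length(time_s))
  dt <- stats::median(diff(time_s))
  idx <- window_idx(time_s, window)
  if (length(idx) < 10L) stop("window must contain at least 10 samples")
  sm <- moving_average(x, round(smooth_s / dt))
  d2 <- c(NA, diff(sm, differences = 2) / dt^2, NA)
  peak_i <- idx[which.min(sm[idx])]
  cand <- idx[idx < peak_i & is.finite(d2[idx])]
  if (length(cand) == 0L || all(d2[cand] >= 0))
    onset_undefined("onset undefined: no negative second derivative before the peak")
  time_s[cand[which.min(d2[cand])]]
}

#' Onset of a signal rise via baseline crossing
#'
#' The onset of the first pyruvate phase is the first time after
#' stimulation onset at which the proxy exceeds its baseline mean by
#' `m` baseline standard deviations for at least `consecutive` samples.
#'
#' @param x Proxy trace.
#' @param time_s Time stamps (s).
#' @param baseline_window `[t0, t1]` window for the baseline statistics.
#' @param stim_start Search start (s, default 0).
#' @param m Threshold in baseline SDs (default 2).
#' @param consecutive Required consecutive supra-threshold samples
#'   (default 2).
#' @return Onset time (s); signals `fretfp_onset_undefined` when the
#'   proxy never crosses.
#' @export
onset_by_baseline_crossing <- function(x, time_s,
                                       baseline_window = c(-120, -10),
                                       stim_start = 0, m = 2,
                                       consecutive = 2L) {
  stopifnot(length(x) == length(time_s))
  bidx <- window_idx(time_s, baseline_window)
  if (length(bidx) < 3L) stop("baseline window outside trace")
  thr <- mean(x[bidx]) + m * stats::sd(x[bidx])
  if (!is.finite(thr)) stop("baseline statistics not computable")
  cand <- which(time_s > stim_start)
  above <- x[cand] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= consecutive)
  if (length(ok) == 0L)
    onset_undefined("onset undefined: proxy never exceeds baseline threshold")
  time_s[cand[starts[ok[1L]]]]
}

#' Segment a pyruvate proxy into its triphasic structure
#'
#' Piecewise-slope analysis of the smoothed proxy: the first-phase end
#' `t1` is where the slope first falls below `slope_frac` of its maximum
#' after the rapid rise; the plateau start `t2` is the beginning of the
#' first sustained (`plateau_run_s`) run of near-zero slope
#' (`|slope| < plateau_slope` %/s) after `t1`; `t3` is the last time the
#' proxy remains above the baseline threshold (the plateau end, or the
#' trace end if still elevated).  The second phase between `t1` and `t2`
#' is classified as `"rise"` when the proxy gains more than 5% of the
#' first-phase amplitude after `t1`, else `"decay"`.
#'
#' @param x Pyruvate proxy trace (% units, oriented upward with ligand).
#' @param time_s Time stamps (s); must cover at least `min_post_s`
#'   seconds after `stim_start`.
#' @param baseline_window,stim_start,m,consecutive Passed to
#'   [onset_by_baseline_crossing()] for the onset.
#' @param smooth_s Smoothing span (s, default 3).
#' @param slope_frac Fraction of the maximum phase-1 slope defining the
#'   end of the rapid rise (default 0.25).
#' @param plateau_slope Absolute slope threshold for the plateau (%/s,
#'   default 0.02).
#' @param plateau_run_s Minimum run of near-zero slope (s, default 30).
#' @param min_post_s Required post-stimulus coverage (s, default 600).
#' @return List with `has_dip`, `t_onset`, `t1`, `t2`, `t3`, `p2_mode`.
#' @export
segment_pyruvate_phases <- function(x, time_s,
                                    baseline_window = c(-120, -10),
                                    stim_start = 0, m = 2, consecutive = 2L,
                                    smooth_s = 3, slope_frac = 0.25,
                                    plateau_slope = 0.02,
                                    plateau_run_s = 30, min_post_s = 600) {
  stopifnot(length(x) == length(time_s))
  if (max(time_s) < stim_start + min_post_s)
    stop("proxy must cover at least ", min_post_s, " s post-stimulus")
  dt <- stats::median(diff(time_s))
  t_onset <- tryCatch(
    onset_by_baseline_crossing(x, time_s, baseline_window, stim_start,
                               m = m, consecutive = consecutive),
    fretfp_onset_undefined = function(e)
      onset_undefined("no phase-1 rise detected"))
  sm <- moving_average(x, round(smooth_s / dt))
  slope <- c(NA, diff(sm, lag = 2) / (2 * dt), NA)
  bidx <- window_idx(time_s, baseline_window)
  thr <- mean(x[bidx]) + m * stats::sd(x[bidx])
  # phase-1 end: slope collapse after the steepest rise
  rise_idx <- which(time_s >= t_onset & time_s <= t_onset + 60)
  ms_i <- rise_idx[which.max(slope[rise_idx])]
  max_slope <- slope[ms_i]
  if (!is.finite(max_slope) || max_slope <= 0)
    onset_undefined("no phase-1 rise detected")
  after <- which(seq_along(x) > ms_i & is.finite(slope))
  drop_i <- after[slope[after] < slope_frac * max_slope]
  if (length(drop_i) == 0L) onset_undefined("phase-1 rise never ends")
  t1 <- time_s[drop_i[1L]]
  # plateau start: first sustained near-zero-slope run after t1
  # coarse plateau start: long-lag slope suppresses sample noise
  lag <- max(1L, round(5 / dt))
  coarse <- rep(NA_real_, length(sm))
  ci <- (lag + 1L):(length(sm) - lag)
  coarse[ci] <- (sm[ci + lag] - sm[ci - lag]) / (2 * lag * dt)
  cand <- which(time_s > t1 + 2 * dt & is.finite(coarse))
  flat <- abs(coarse[cand]) < plateau_slope
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- max(1L, round(plateau_run_s / dt))
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0L) onset_undefined("no plateau detected")
  t2c <- time_s[cand[starts[ok[1L]]]]
  # refine by a two-segment least-squares fit around the coarse estimate
  t2 <- refine_breakpoint(sm, time_s, t2c, lo = max(t1 + 2 * dt, t2c - 15),
                          hi = t2c + 5, arm_s = 40)
  # phase-2 mode
  seg <- which(time_s > t1 & time_s < t2)
  p1_amp <- sm[which.min(abs(time_s - t1))] - mean(x[bidx])
  p2_mode <- if (length(seg) &&
                 max(sm[seg]) - (p1_amp + mean(x[bidx])) > 0.05 * abs(p1_amp))
    "rise" else "decay"
  # plateau end
  elevated <- which(time_s >= t2 & sm > thr)
  t3 <- if (length(elevated)) time_s[max(elevated)] else t2
  # initial dip before onset?
  dip_idx <- which(time_s >= stim_start & time_s <= t_onset)
  has_dip <- length(dip_idx) > 0 &&
    min(x[dip_idx]) < mean(x[bidx]) - m * stats::sd(x[bidx])
  list(has_dip = has_dip, t_onset = t_onset, t1 = t1, t2 = t2, t3 = t3,
       p2_mode = p2_mode)
}

# Refine a slope change-point: over candidate times in [lo, hi], fit
# independent least-squares lines on the arm_s-long windows before and
# after the candidate and pick the candidate minimizing the total SSE.
refine_breakpoint <- function(x, time_s, t_coarse, lo, hi, arm_s = 40) {
  cand <- which(time_s >= lo & time_s <= hi)
  if (length(cand) < 2L) return(t_coarse)
  sse_line <- function(idx) {
    if (length(idx) < 3L) return(0)
    tt <- time_s[idx]; yy <- x[idx]
    fit <- stats::lm.fit(cbind(1, tt), yy)
    sum(fit$residuals^2)
  }
  sse <- vapply(cand, function(i) {
    left <- which(time_s >= time_s[i] - arm_s & time_s <= time_s[i])
    right <- which(time_s >= time_s[i] & time_s <= time_s[i] + arm_s)
    sse_line(left) + sse_line(right)
  }, numeric(1))
  time_s[cand[which.min(sse)]]
}

#' Cumulative signal over a time interval
#'
#' Discrete integral (sample sum times the sampling interval) of a
#' baseline-relative trace over `[t0, t1]`; used for the cumulative
#' (detrended) Texas Red signal from stimulation onset to the ATP
#' negative peak or to the after-discharge end.  Additive over adjacent
#' sample-disjoint intervals.
#'
#' @param x Baseline-relative trace (e.g. detrended Texas Red, a.u.).
#' @param time_s Time stamps (s), uniform sampling.
#' @param t0,t1 Integration bounds (s), `t0 < t1`, within the trace.
#' @return Cumulative signal (a.u. * s).
#' @export
cumulative_signal <- function(x, time_s, t0, t1) {
  stopifnot(length(x) == length(time_s))
  if (!(t0 < t1)) stop("require t0 < t1")
  if (t0 < min(time_s) || t1 > max(time_s))
    stop("integration bounds outside the trace")
  dt <- stats::median(diff(time_s))
  idx <- window_idx(time_s, c(t0, t1))
  sum(x[idx]) * dt
}
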