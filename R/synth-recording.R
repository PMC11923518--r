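# Run code with a local, restored RNG state.  All simulator randomness
# goes through this helper so no global seed is ever touched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Apply simulated optical confounds to ideal sensor emissions
#'
#' Models the two artifact pathways of fiber photometry in vascularized
#' tissue:
#' * **Blood-volume shadow**: vessels absorb both excitation and
#'   emission, so every fluorescence channel is multiplied by
#'   `1 - shadow_gain * bbv(t)` where `bbv` is the fractional
#'   blood-volume change (negative = constriction = brighter tissue).
#' * **pH quenching**: cytosolic pH modulates YFP emission; the
#'   YFP-family channels (fYFP, dYFP) are multiplied by
#'   `1 + ph_quench(t)`.  With `ph_mode = "equal"` the CFP channel is
#'   modulated by the same factor (the assumption under which both the
#'   ratio and the difference method cancel the artifact exactly);
#'   the default `"yfp_only"` leaves CFP untouched, creating the
#'   residual dYFP/Texas Red mismatch seen in real recordings.
#'
#' An intravascular Texas Red channel can be added:
#' `TexasRed(t) = base * exp(-(t - t[1])/tau_s) * (1 + bbv(t)) + offset`,
#' i.e. it decays with the post-injection dye dilution and co-varies
#' *positively* with blood volume.
#'
#' @param emissions A [channel_traces()] data frame (ideal emissions,
#'   e.g. from [fret_emissions()]).
#' @param bbv Fractional blood-volume change trace on the same grid
#'   (0 = baseline), or `NULL` for none.
#' @param ph_quench Fractional YFP emission modulation trace, or `NULL`.
#' @param shadow_gain Dimensionless gain `k` of the BBV shadow (the
#'   paper-scale value is unknown; default 1).
#' @param ph_mode `"yfp_only"` (default) or `"equal"`.
#' @param texasred `NULL`, or a list with elements `base`, `tau_s`,
#'   `offset` describing the dye decay.
#' @return A `channel_traces` data frame with confounded channels (and a
#'   `TexasRed` column when requested).
#' @export
apply_confounds <- function(emissions, bbv = NULL, ph_quench = NULL,
                            shadow_gain = 1,
                            ph_mode = c("yfp_only", "equal"),
                            texasred = NULL) {
  stopifnot(inherits(emissions, "channel_traces"))
  ph_mode <- match.arg(ph_mode)
  n <- nrow(emissions)
  if (is.null(bbv)) bbv <- numeric(n)
  if (is.null(ph_quench)) ph_quench <- numeric(n)
  stopifnot(length(bbv) == n, length(ph_quench) == n)
  shadow <- 1 - shadow_gain * bbv
  if (any(shadow <= 0))
    stop("shadow factor must stay positive; reduce 'shadow_gain' or the BBV excursion")
  out <- as.data.frame(emissions)
  for (ch in trace_channels(emissions)) {
    v <- out[[ch]] * shadow
    if (ch %in% c("fYFP", "dYFP") ||
        (ch == "fCFP" && ph_mode == "equal"))
      v <- v * (1 + ph_quench)
    out[[ch]] <- v
  }
  if (!is.null(texasred)) {
    stopifnot(all(c("base", "tau_s") %in% names(texasred)))
    offset <- if (is.null(texasred$offset)) 0 else texasred$offset
    t_rel <- out$time_s - out$time_s[1]
    out$TexasRed <- texasred$base * exp(-t_rel / texasred$tau_s) *
      (1 + bbv) + offset
  }
  channel_traces(out)
}

#' Simulate a cortical EEG trace with a stimulation artifact and an
#' after-discharge
#'
#' Builds a 2 kHz EEG containing Gaussian background noise, a 50 Hz
#' train-stimulation artifact (1 ms pulses) during `stim_interval`, and a
#' self-sustained oscillatory after-discharge (mixed 2-20 Hz sinusoids
#' with random phases, RMS amplitude `ad_amplitude` times the background
#' noise) lasting exactly `ad_duration_s` after stimulation offset.
#'
#' @param ad_duration_s After-discharge duration (s, >= 0; 0 = the
#'   "no AD" case).
#' @param stim_interval `[start, end]` of the stimulation train (s).
#' @param noise_rms Background noise RMS (a.u.).
#' @param grid_2khz Time grid (s) at `fs` Hz.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param fs Sampling rate (Hz), default 2000.
#' @param ad_amplitude After-discharge RMS in multiples of `noise_rms`
#'   (default 10).
#' @param stim_amplitude Stimulation artifact pulse amplitude (a.u.).
#' @return Numeric EEG trace on `grid_2khz`.
#' @export
simulate_eeg <- function(ad_duration_s, stim_interval = c(0, 10),
                         noise_rms = 0.05, grid_2khz = seq(-120, 120, by = 5e-4),
                         seed = NULL, fs = 2000, ad_amplitude = 10,
                         stim_amplitude = 2) {
  stopifnot(ad_duration_s >= 0, length(stim_interval) == 2L,
            stim_interval[1] < stim_interval[2])
  with_seed(seed, {
    n <- length(grid_2khz)
    eeg <- stats::rnorm(n, 0, noise_rms)
    # 50 Hz train: 1 ms biphasic pulses
    stim <- grid_2khz >= stim_interval[1] & grid_2khz < stim_interval[2]
    ph <- (grid_2khz[stim] - stim_interval[1]) %% 0.02  # 50 Hz period
    eeg[stim] <- eeg[stim] + stim_amplitude * (ph < 0.0005) -
      stim_amplitude * (ph >= 0.0005 & ph < 0.001)
    if (ad_duration_s > 0) {
      ad <- grid_2khz >= stim_interval[2] &
        grid_2khz < stim_interval[2] + ad_duration_s
      t_ad <- grid_2khz[ad] - stim_interval[2]
      freqs <- c(2.5, 4.5, 7, 12, 18)
      phases <- stats::runif(length(freqs), 0, 2 * pi)
      osc <- rowSums(vapply(seq_along(freqs), function(i)
        sin(2 * pi * freqs[i] * t_ad + phases[i]), numeric(length(t_ad))))
      osc <- osc / sqrt(length(freqs) / 2)          # unit RMS
      eeg[ad] <- eeg[ad] + ad_amplitude * noise_rms * osc
    }
    eeg
  })
}

#' Synthesize a raw multiplexed recording from 1 Hz channel traces
#'
#' The inverse of [demux()]: for each 1 Hz cycle and each scheduled
#' pulse, the corresponding PMT trace is set to
#' `channel value + dark + noise` inside the pulse window, and to
#' `dark + noise` between pulses.  At zero noise,
#' `demux(synthesize_raw_recording(x))` recovers `x` exactly.
#'
#' @param channels A [channel_traces()] data frame on a 1 Hz grid whose
#'   channels cover the schedule's channel set.
#' @param schedule An [excitation_schedule()] with a 1 s cycle.
#' @param noise_rms Additive Gaussian noise RMS on the PMT voltages (V).
#' @param dark Dark level (V): scalar or named per-channel vector.
#' @param eeg Optional EEG trace at `fs` Hz covering the same span.
#' @param seed Integer seed for the noise.
#' @param fs PMT sampling rate (Hz), default 2000.
#' @return A [raw_recording()].
#' @export
synthesize_raw_recording <- function(channels, schedule = schedule_preset("dual"),
                                     noise_rms = 0, dark = 0.1, eeg = NULL,
                                     seed = NULL, fs = 2000) {
  stopifnot(inherits(channels, "channel_traces"),
            inherits(schedule, "excitation_schedule"))
  missing <- setdiff(unique(schedule$pulses$channel), trace_channels(channels))
  if (length(missing))
    stop("channels missing for schedule: ", paste(missing, collapse = ", "))
  dt <- diff(channels$time_s)
  if (any(abs(dt - schedule$cycle_period_s) > 1e-9))
    stop("channel traces must be sampled at the schedule's cycle period")
  n_cycles <- nrow(channels)
  cyc_n <- round(schedule$cycle_period_s * fs)
  n <- n_cycles * cyc_n
  dk <- dark_vector(dark, schedule)
  dark_floor <- mean(dk)   # detector output between pulses
  with_seed(seed, {
    pmt <- list(pmt1 = dark_floor + stats::rnorm(n, 0, noise_rms),
                pmt2 = dark_floor + stats::rnorm(n, 0, noise_rms))
    offs <- (seq_len(n_cycles) - 1L) * cyc_n
    for (i in seq_len(nrow(schedule$pulses))) {
      row <- schedule$pulses[i, ]
      idx <- pulse_samples(row, fs, 0)
      pos <- rep(offs, each = length(idx)) + idx
      pmt[[row$detector]][pos] <- rep(channels[[row$channel]],
                                      each = length(idx)) +
        dk[[row$channel]] + stats::rnorm(length(pos), 0, noise_rms)
    }
    if (!is.null(eeg)) stopifnot(length(eeg) >= n)
    raw_recording(pmt$pmt1, pmt$pmt2, fs = fs, schedule = schedule,
                  dark = dk, eeg = if (is.null(eeg)) NULL else eeg[seq_len(n)],
                  t0 = channels$time_s[1] - schedule$cycle_period_s / 2,
                  seed = seed)
  })
}
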