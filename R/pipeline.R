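#' Analysis configuration for a recording session
#'
#' Fully specified defaults so that an empty call runs: baseline window
#' `[-120, -10]` s before stimulation onset; AD detection with threshold
#' `k = 3` baseline RMS, 0.5 s bins, 1 s smoothing and a 1 s sustained
#' run; baseline-crossing onsets at `m = 2` SD for `consecutive = 2`
#' samples; 5 s smoothing before second differencing; extremum search
#' windows `[0, 120]` s (ATP/dYFP/Texas Red) and `[0, 300]` s
#' (pyruvate); stage grouping "first three" (early) / "last three"
#' (fully kindled) episodes.
#'
#' @param ... Overrides of any default listed above (see the source for
#'   the full field list).
#' @return A list of class `session_config`.
#' @export
session_config <- function(...) {
  cfg <- list(
    sensor = "ATeam", schedule = "dual",
    baseline_window = c(-120, -10),
    ad_k = 3, ad_bin_s = 0.5, ad_smooth_s = 1, ad_sustain_s = 1,
    onset_m = 2, onset_consecutive = 2L,
    inflection_smooth_s = 5,
    peak_smooth_s = 5,
    atp_window = c(0, 120), pyr_window = c(0, 300),
    texasred_fit_windows = list(c(-120, -1), c(300, Inf)),
    stage_group_n = 3L,
    # model-based calibration of the ratio proxy into fYFP-equivalent %
    sensor_params = NULL, baseline_ligand = NULL,
    seed = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (!cfg$sensor %in% c("ATeam", "PYRS")) stop("sensor must be ATeam or PYRS")
  if (!cfg$schedule %in% c("dual", "triple")) stop("schedule must be dual or triple")
  structure(cfg, class = "session_config")
}

#' Built-in simulation scenario presets
#'
#' Named parameter sets for [simulate_episode()] reflecting the stated
#' conditions of each recording situation:
#' * `early_kindling`: -20.88% fluorescence ATP drop, short
#'   after-discharges (5-20 s), vessel constriction plus a pH
#'   (alkalinization) transient.
#' * `fully_kindled`: -14.72% drop, long ADs (25-40 s), vessel dilation.
#' * `no_ad`: stimulation without an after-discharge; no ATP response,
#'   no confounds.
#' * `sudep_like`: terminal -38.04% collapse with no recovery.
#' * `pyrs_triphasic`: astrocytic pyruvate sensor, triphasic response.
#' * `texasred_session`: triple-excitation configuration with an
#'   intravascular Texas Red channel on a decaying baseline.
#'
#' @param name Scenario name.
#' @return A named list of [simulate_episode()] arguments.
#' @export
scenario_preset <- function(name = c("early_kindling", "fully_kindled",
                                     "no_ad", "sudep_like",
                                     "pyrs_triphasic", "texasred_session")) {
  name <- match.arg(name)
  switch(name,
    early_kindling = list(
      sensor = "ATeam", schedule = "dual", amplitude_pct = -20.88,
      ad_range = c(5, 20), bbv_peak = -0.05, bbv_time_s = 12,
      bbv_width_s = 8, ph_peak = 0.04, ph_time_s = 20, ph_width_s = 15),
    fully_kindled = list(
      sensor = "ATeam", schedule = "dual", amplitude_pct = -14.72,
      ad_range = c(25, 40), bbv_peak = 0.06, bbv_time_s = 18,
      bbv_width_s = 20, ph_peak = 0.02, ph_time_s = 25, ph_width_s = 20),
    no_ad = list(
      sensor = "ATeam", schedule = "dual", amplitude_pct = 0,
      ad_range = c(0, 0), bbv_peak = 0, ph_peak = 0),
    sudep_like = list(
      sensor = "ATeam", schedule = "dual", amplitude_pct = -38.04,
      recovery_tau_s = Inf, ad_range = c(30, 60), bbv_peak = -0.08,
      bbv_time_s = 15, bbv_width_s = 12, ph_peak = 0.04, ph_time_s = 20,
      ph_width_s = 15),
    pyrs_triphasic = list(
      sensor = "PYRS", schedule = "dual", ad_range = c(5, 20),
      bbv_peak = -0.05, bbv_time_s = 12, bbv_width_s = 8,
      ph_peak = 0.04, ph_time_s = 20, ph_width_s = 15,
      grid = seq(-120, 900)),
    texasred_session = list(
      sensor = "ATeam", schedule = "triple", amplitude_pct = -20.88,
      ad_range = c(5, 20), bbv_peak = -0.05, bbv_time_s = 12,
      bbv_width_s = 8, ph_peak = 0.04, ph_time_s = 20, ph_width_s = 15))
}

#' Forward-simulate one stimulation episode
#'
#' Produces 1 Hz channel traces (with confounds and measurement noise),
#' optional 2 kHz EEG, an annotation row, and the ground truth used by
#' every round-trip test.  ATP episodes use [simulate_atp_transient()];
#' pyruvate episodes use [simulate_pyruvate_transient()].
#'
#' @param sensor `"ATeam"` or `"PYRS"`.
#' @param schedule `"dual"` (fCFP/fYFP/dYFP) or `"triple"`
#'   (fYFP/dYFP/TexasRed; no fCFP).
#' @param amplitude_pct ATP fluorescence drop (% of baseline fYFP, <= 0).
#' @param onset_delay_s,decay_tau_s,recovery_tau_s ATP transient shape
#'   (defaults follow the early-stage timing: onset 13.5 s after
#'   stimulation onset, trough near 32 s).
#' @param pyr List of overrides for [simulate_pyruvate_transient()].
#' @param ad_duration_s After-discharge duration (s); `NULL` draws
#'   uniformly from `ad_range`.
#' @param ad_range Range for the AD duration draw (s).
#' @param bbv_peak,bbv_time_s,bbv_width_s Blood-volume bump (fractional;
#'   negative = constriction).
#' @param ph_peak,ph_time_s,ph_width_s pH-quench bump (fractional).
#' @param ph_mode `"yfp_only"` or `"equal"` (see [apply_confounds()]).
#' @param shadow_gain BBV shadow gain.
#' @param noise_pct Additive Gaussian channel noise, % of each channel's
#'   baseline (1 Hz samples).
#' @param grid 1 Hz time grid (s), 0 = stimulation onset.
#' @param stim Stimulation interval (s).
#' @param with_eeg Also synthesize a 2 kHz EEG trace.
#' @param eeg_noise EEG background RMS.
#' @param texasred Texas Red decay parameters (list with `base`,
#'   `tau_s`, `offset`); defaults applied for the triple schedule.
#' @param baseline_ligand Resting ligand level (mM ATP / uM pyruvate).
#' @param stage Stage label stored in the annotation.
#' @param episode Episode index.
#' @param seed Integer seed; the episode is bit-reproducible.
#' @return A list of class `fp_episode` with elements `channels`,
#'   `eeg`, `eeg_time`, `annotation`, `truth`, `config_used`.
#' @export
simulate_episode <- function(sensor = c("ATeam", "PYRS"),
                             schedule = c("dual", "triple"),
                             amplitude_pct = -20.88,
                             onset_delay_s = 13.5, decay_tau_s = 2.3,
                             recovery_tau_s = 60,
                             pyr = list(),
                             ad_duration_s = NULL, ad_range = c(5, 20),
                             bbv_peak = -0.05, bbv_time_s = 12,
                             bbv_width_s = 8,
                             ph_peak = 0.04, ph_time_s = 20, ph_width_s = 15,
                             ph_mode = "yfp_only", shadow_gain = 1,
                             noise_pct = 0.3,
                             grid = seq(-120, 480), stim = c(0, 10),
                             with_eeg = FALSE, eeg_noise = 0.05,
                             texasred = NULL,
                             baseline_ligand = NULL,
                             stage = "unknown", episode = 1L,
                             seed = NULL) {
  sensor <- match.arg(sensor)
  schedule <- match.arg(schedule)
  with_seed(seed, {
    if (is.null(ad_duration_s))
      ad_duration_s <- if (diff(ad_range) == 0) ad_range[1] else
        stats::runif(1, ad_range[1], ad_range[2])
    sp <- if (sensor == "ATeam") ateam_params() else pyrs_params()
    if (is.null(baseline_ligand))
      baseline_ligand <- if (sensor == "ATeam") 2.3 else 15
    respond <- ad_duration_s > 0
    if (sensor == "ATeam") {
      ligand <- simulate_atp_transient(
        if (respond) amplitude_pct else 0,
        onset_delay_s, decay_tau_s, recovery_tau_s, grid,
        sensor = sp, baseline_ligand = baseline_ligand)
    } else {
      args <- utils::modifyList(
        list(grid = grid, sensor = sp, baseline_ligand = baseline_ligand),
        pyr)
      if (!respond) args[c("dip_amp_pct", "p1_amp_pct",
                           "plateau_amp_pct")] <- list(0, 0, 0)
      ligand <- do.call(simulate_pyruvate_transient, args)
    }
    em <- fret_emissions(as.numeric(ligand), sp, time_s = grid)
    bbv <- if (respond && bbv_peak != 0)
      confound_bump(bbv_peak, bbv_time_s, bbv_width_s, grid) else
        numeric(length(grid))
    ph <- if (respond && ph_peak != 0)
      confound_bump(ph_peak, ph_time_s, ph_width_s, grid) else
        numeric(length(grid))
    if (schedule == "triple") {
      if (is.null(texasred))
        texasred <- list(base = 2, tau_s = 2700, offset = 0.2)
      em$fCFP <- NULL   # CFP emission is not detected with triple excitation
      em <- channel_traces(em)
    }
    obs <- apply_confounds(em, bbv = bbv, ph_quench = ph,
                           shadow_gain = shadow_gain, ph_mode = ph_mode,
                           texasred = texasred)
    # additive measurement noise, scaled to each channel's baseline level
    if (noise_pct > 0) {
      for (ch in trace_channels(obs)) {
        f0 <- mean(obs[[ch]][grid < stim[1]])
        obs[[ch]] <- obs[[ch]] +
          stats::rnorm(length(grid), 0, noise_pct / 100 * f0)
      }
    }
    eeg <- NULL; eeg_time <- NULL
    if (with_eeg) {
      eeg_time <- seq(grid[1], max(grid), by = 1 / 2000)
      eeg <- simulate_eeg(ad_duration_s, stim_interval = stim,
                          noise_rms = eeg_noise, grid_2khz = eeg_time,
                          seed = NULL)   # inherits the episode RNG stream
    }
    truth <- list(sensor = sensor, amplitude_pct = amplitude_pct,
                  ad_duration_s = ad_duration_s,
                  atp_onset_s = onset_delay_s,
                  atp_trough_s = if (sensor == "ATeam")
                    attr(ligand, "t_min") else NA_real_,
                  pyr_breakpoints = attr(ligand, "breakpoints"),
                  bbv_peak = bbv_peak, bbv_time_s = bbv_time_s,
                  ph_peak = ph_peak, fluo_pct = attr(ligand, "fluo_pct"),
                  baseline_ligand = baseline_ligand, seed = seed)
    structure(list(channels = obs, eeg = eeg, eeg_time = eeg_time,
                   annotation = annotate_episode(
                     stim[1], stim[2], stim[2] + ad_duration_s,
                     stage = stage, episode = episode),
                   truth = truth,
                   config_used = list(schedule = schedule, sensor = sensor,
                                      ph_mode = ph_mode,
                                      shadow_gain = shadow_gain,
                                      noise_pct = noise_pct)),
              class = "fp_episode")
  })
}

na_if_undefined <- function(expr) {
  tryCatch(expr, fretfp_onset_undefined = function(e) NA_real_)
}

#' Extract all per-episode event features
#'
#' Runs the full analysis chain for one stimulation episode: optional
#' demultiplexing, baseline normalization, ligand-proxy construction,
#' after-discharge measurement, and feature extraction (peaks, onsets,
#' phase boundaries, cumulative Texas Red).  Episodes without an
#' after-discharge get `ad_duration = 0` and all response features
#' undefined (`NA`), since without an AD the sensors show minimal
#' change.
#'
#' @param x A [raw_recording()], a [simulate_episode()] result, or a
#'   [channel_traces()] data frame.
#' @param annotation One-row annotation (see [annotate_episode()]).  If
#'   `ad_end_s` is `NA`, the AD is detected from the EEG.
#' @param config A [session_config()].
#' @param eeg,eeg_time Optional EEG trace and time stamps when `x` is a
#'   plain channel table.
#' @return A one-row data frame of event features.
#' @export
analyze_episode <- function(x, annotation = NULL, config = session_config(),
                            eeg = NULL, eeg_time = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (inherits(x, "fp_episode")) {
    if (is.null(annotation)) annotation <- x$annotation
    eeg <- x$eeg; eeg_time <- x$eeg_time
    x <- x$channels
  }
  if (inherits(x, "raw_recording")) {
    if (!is.null(x$eeg)) {
      eeg <- x$eeg
      eeg_time <- x$t0 + (seq_along(eeg) - 1L) / x$fs
    }
    x <- demux(x)
  }
  stopifnot(inherits(x, "channel_traces"))
  if (is.null(annotation)) stop("an episode annotation is required")
  validate_annotation(annotation)
  stim_start <- annotation$stim_start_s
  stim_end <- annotation$stim_end_s

  # after-discharge duration: manual override wins, else detect from EEG
  if (!is.na(annotation$ad_end_s)) {
    ad_end <- annotation$ad_end_s
    ad_duration <- ad_end - stim_end
  } else if (!is.null(eeg)) {
    filt <- bandpass_eeg(eeg, fs = round(1 / stats::median(diff(eeg_time))))
    ad_duration <- detect_ad_duration(filt, eeg_time, stim_start, stim_end,
                                      k = config$ad_k, bin_s = config$ad_bin_s,
                                      smooth_s = config$ad_smooth_s,
                                      sustain_s = config$ad_sustain_s)
    ad_end <- attr(ad_duration, "ad_end")
    ad_duration <- as.numeric(ad_duration)
  } else stop("no ad_end annotation and no EEG to detect it from")

  norm <- normalize_channels(x, config$baseline_window)
  feat <- data.frame(episode = annotation$episode, stage = annotation$stage,
                     ad_duration = ad_duration, ad_end = ad_end,
                     atp_neg_peak_time = NA_real_, atp_neg_peak_mag = NA_real_,
                     atp_onset_time = NA_real_,
                     ratio_neg_peak_time = NA_real_,
                     ratio_neg_peak_mag = NA_real_,
                     dyfp_pos_peak_time = NA_real_,
                     dyfp_pos_peak_mag = NA_real_,
                     texasred_neg_peak_time = NA_real_,
                     cum_texasred_to_atp_peak = NA_real_,
                     cum_texasred_to_ad_end = NA_real_,
                     pyr_onset_time = NA_real_, pyr_pos_peak_time = NA_real_,
                     pyr_pos_peak_mag = NA_real_,
                     pyr_t1 = NA_real_, pyr_t2 = NA_real_, pyr_t3 = NA_real_,
                     pyr_p2_mode = NA_character_,
                     stringsAsFactors = FALSE)
  has_ad <- ad_duration > 0
  chans <- trace_channels(x)
  win <- stim_start + config$atp_window
  # argmin/argmax of a noisy 1 Hz trace is deep-biased and jittery; peaks
  # are located on a lightly smoothed copy (magnitude taken from the same
  # smoothed trace for consistency)
  dt <- stats::median(diff(x$time_s))
  smooth_peaks <- function(v) moving_average(v, round(config$peak_smooth_s / dt))

  if ("dYFP" %in% chans && has_ad) {
    pk <- find_extremum(smooth_peaks(norm$dYFP), norm$time_s, win, "max")
    feat$dyfp_pos_peak_time <- pk$time
    feat$dyfp_pos_peak_mag <- pk$magnitude
  }

  if (config$sensor == "ATeam") {
    if (all(c("fYFP", "dYFP") %in% chans) && has_ad) {
      dif <- difference_signal(norm$fYFP, norm$dYFP, norm$time_s, "ATeam")
      pk <- find_extremum(smooth_peaks(dif$value), dif$time_s, win, "min")
      feat$atp_neg_peak_time <- pk$time
      feat$atp_neg_peak_mag <- pk$magnitude
      feat$atp_onset_time <- na_if_undefined(
        onset_by_inflection(dif$value, dif$time_s, win,
                            smooth_s = config$inflection_smooth_s))
    }
    if (all(c("fYFP", "fCFP") %in% chans) && has_ad) {
      rat <- if (!is.null(config$sensor_params))
        ratio_signal(x, "ATeam", as_percent = TRUE,
                     sensor_params = config$sensor_params,
                     baseline_ligand = config$baseline_ligand,
                     baseline_window = config$baseline_window)
      else ratio_signal(x, "ATeam")
      pk <- find_extremum(smooth_peaks(rat$value), rat$time_s, win, "min")
      feat$ratio_neg_peak_time <- pk$time
      feat$ratio_neg_peak_mag <- if (!is.null(config$sensor_params))
        pk$magnitude else pk$magnitude - mean(
          rat$value[window_idx(rat$time_s, config$baseline_window)])
    }
  } else {  # PYRS
    if (all(c("fYFP", "dYFP") %in% chans) && has_ad) {
      dif <- difference_signal(norm$fYFP, norm$dYFP, norm$time_s, "PYRS")
      pwin <- stim_start + config$pyr_window
      pk <- find_extremum(smooth_peaks(dif$value), dif$time_s, pwin, "max")
      feat$pyr_pos_peak_time <- pk$time
      feat$pyr_pos_peak_mag <- pk$magnitude
      feat$pyr_onset_time <- na_if_undefined(
        onset_by_baseline_crossing(dif$value, dif$time_s,
                                   config$baseline_window, stim_start,
                                   m = config$onset_m,
                                   consecutive = config$onset_consecutive))
      if (max(dif$time_s) >= stim_start + 600) {
        ph <- tryCatch(
          segment_pyruvate_phases(dif$value, dif$time_s,
                                  config$baseline_window, stim_start,
                                  m = config$onset_m,
                                  consecutive = config$onset_consecutive),
          fretfp_onset_undefined = function(e) NULL)
        if (!is.null(ph)) {
          feat$pyr_t1 <- ph$t1; feat$pyr_t2 <- ph$t2; feat$pyr_t3 <- ph$t3
          feat$pyr_p2_mode <- ph$p2_mode
        }
      }
    }
  }

  if ("TexasRed" %in% chans) {
    tr <- detrend_texasred(x$TexasRed, x$time_s,
                           fit_windows = config$texasred_fit_windows)
    if (has_ad) {
      pk <- find_extremum(smooth_peaks(tr), x$time_s, win, "min")
      feat$texasred_neg_peak_time <- pk$time
      if (is.finite(feat$atp_neg_peak_time))
        feat$cum_texasred_to_atp_peak <- cumulative_signal(
          tr, x$time_s, stim_start, feat$atp_neg_peak_time)
      feat$cum_texasred_to_ad_end <- cumulative_signal(
        tr, x$time_s, stim_start, ad_end)
    }
  }
  feat
}

#' Analyze a session of stimulation episodes
#'
#' Runs [analyze_episode()] on every episode, groups the first
#' `stage_group_n` episodes as "early" and the last `stage_group_n` as
#' "fully_kindled", and summarizes AD duration and ATP-drop magnitude
#' per stage (mean +/- SEM) with a Welch comparison between the two
#' groups of episodes.
#'
#' @param episodes A list of episodes: [simulate_episode()] results,
#'   `raw_recording`s, or `channel_traces` (the latter require matching
#'   `annotations`).
#' @param config A [session_config()].
#' @param annotations Optional data frame of annotations, one row per
#'   episode, when the episodes do not carry their own.
#' @return A list of class `fp_session` with `features` (one row per
#'   episode), `stage_summary`, and `comparisons`.
#' @export
analyze_session <- function(episodes, config = session_config(),
                            annotations = NULL) {
  n <- length(episodes)
  g <- config$stage_group_n
  if (n < 2 * g)
    stop("need at least ", 2 * g, " episodes for early/fully-kindled grouping")
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    ann <- if (!is.null(annotations)) annotations[i, , drop = FALSE] else NULL
    analyze_episode(episodes[[i]], annotation = ann, config = config)
  }))
  early_i <- seq_len(g)
  late_i <- seq.int(n - g + 1L, n)
  summarize_stage <- function(idx, label) {
    out <- lapply(c("ad_duration", "atp_neg_peak_mag", "pyr_pos_peak_mag"),
                  function(col) {
      v <- feats[[col]][idx]
      v <- v[is.finite(v)]
      if (length(v) < 2L) return(NULL)
      data.frame(stage = label, metric = col, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  summary <- rbind(summarize_stage(early_i, "early"),
                   summarize_stage(late_i, "fully_kindled"))
  comparisons <- list()
  for (col in c("ad_duration", "atp_neg_peak_mag")) {
    e <- feats[[col]][early_i]; l <- feats[[col]][late_i]
    if (sum(is.finite(e)) >= 2 && sum(is.finite(l)) >= 2)
      comparisons[[col]] <- tryCatch(
        welch_t_from_samples(e[is.finite(e)], l[is.finite(l)]),
        error = function(err) err)
  }
  structure(list(features = feats, stage_summary = summary,
                 comparisons = comparisons),
            class = "fp_session")
}

#' Write a reproducible synthetic dataset to disk
#'
#' Materializes a named scenario as plain-text files: per-episode
#' channel tables (`episode_XX_channels.tsv`), a session annotation
#' table (`annotations.tsv`), and a ground-truth table (`truth.tsv`)
#' with the generator parameters per episode.  Outputs are
#' bit-reproducible for a given seed.
#'
#' @param scenario A [scenario_preset()] name.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param n_episodes Number of episodes (default 3).
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(scenario, seed = 1L, out_dir = tempfile("fixtures"),
                          n_episodes = 3L) {
  preset <- scenario_preset(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  anns <- NULL
  truths <- NULL
  for (i in seq_len(n_episodes)) {
    ep <- do.call(simulate_episode,
                  c(preset, list(seed = seed + i - 1L, episode = i)))
    f <- file.path(out_dir, sprintf("episode_%02d_channels.tsv", i))
    write_channel_traces(ep$channels, f,
                         comment = c(paste("scenario:", scenario),
                                     paste("seed:", seed + i - 1L),
                                     paste("schedule:", ep$config_used$schedule),
                                     paste("sensor:", ep$config_used$sensor)))
    files <- c(files, f)
    anns <- rbind(anns, ep$annotation)
    truths <- rbind(truths, data.frame(
      episode = i, amplitude_pct = ep$truth$amplitude_pct,
      ad_duration_s = ep$truth$ad_duration_s,
      atp_onset_s = ep$truth$atp_onset_s,
      atp_trough_s = ep$truth$atp_trough_s,
      bbv_peak = ep$truth$bbv_peak, seed = seed + i - 1L))
  }
  fa <- file.path(out_dir, "annotations.tsv")
  write_annotations(anns, fa)
  ft <- file.path(out_dir, "truth.tsv")
  utils::write.table(truths, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, fa, ft))
}
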