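#' Simulated recovery and method-comparison study
#'
#' Simulates `n` independent stimulation episodes with blood-volume and
#' pH confounds and ATP fluorescence drops drawn uniformly from
#' `amp_range`, analyzes each with the difference method, the
#' (model-calibrated) ratio method, and the uncorrected fYFP channel,
#' and returns the per-episode truth and estimates.  This is the package's
#' standing check that the difference method recovers the injected drop
#' while raw fYFP inherits the confound, and that the ratio and
#' difference methods agree (origin-constrained slope near 1) in both
#' peak magnitude and peak time.
#'
#' @param n Number of episodes.
#' @param seed Integer seed; episode `i` uses `seed + i`.
#' @param amp_range Range for the injected fluorescence drop (%).
#' @param ph_mode pH action mode (see [apply_confounds()]); the default
#'   `"equal"` matches the assumption under which both correction
#'   methods are unbiased.
#' @param noise_pct Channel noise level (% of baseline).
#' @return Data frame with one row per episode: `truth_amp`,
#'   `diff_mag`, `diff_time`, `ratio_mag`, `ratio_time`, `fyfp_mag`,
#'   `atp_onset`, `dyfp_peak_time`.
#' @export
recovery_study <- function(n = 50, seed = 1L, amp_range = c(-30, -10),
                           ph_mode = "equal", noise_pct = 0.3) {
  cfg <- session_config(sensor = "ATeam",
                        sensor_params = ateam_params(),
                        baseline_ligand = 2.3)
  out <- lapply(seq_len(n), function(i) {
    amp <- with_seed(seed + i, stats::runif(1, amp_range[1], amp_range[2]))
    ep <- simulate_episode(sensor = "ATeam", amplitude_pct = amp,
                           ph_mode = ph_mode, noise_pct = noise_pct,
                           seed = seed + i)
    ft <- analyze_episode(ep, config = cfg)
    norm <- normalize_channels(ep$channels, cfg$baseline_window)
    fy <- find_extremum(norm$fYFP, norm$time_s, cfg$atp_window, "min")
    data.frame(truth_amp = amp,
               diff_mag = ft$atp_neg_peak_mag, diff_time = ft$atp_neg_peak_time,
               ratio_mag = ft$ratio_neg_peak_mag,
               ratio_time = ft$ratio_neg_peak_time,
               fyfp_mag = fy$magnitude,
               atp_onset = ft$atp_onset_time,
               dyfp_peak_time = ft$dyfp_pos_peak_time)
  })
  do.call(rbind, out)
}

#' Joint ATP/pyruvate timing study
#'
#' Simulates paired neuronal-ATP and astrocytic-pyruvate episodes under
#' the early-kindling preset and measures the onset and peak orderings
#' reported across sensors: the pyruvate rise precedes the ATP
#' reduction, and the ATP negative peak trails the dYFP positive peak.
#'
#' @param n Number of episode pairs.
#' @param seed Integer seed.
#' @return Data frame with `atp_onset`, `atp_peak_time`,
#'   `dyfp_peak_time`, `pyr_onset`, `pyr_peak_time` per episode.
#' @export
timing_study <- function(n = 50, seed = 1L) {
  cfg_a <- session_config(sensor = "ATeam")
  cfg_p <- session_config(sensor = "PYRS")
  out <- lapply(seq_len(n), function(i) {
    ea <- simulate_episode(sensor = "ATeam", seed = seed + i)
    fa <- analyze_episode(ea, config = cfg_a)
    epy <- simulate_episode(sensor = "PYRS", grid = seq(-120, 480),
                            seed = seed + 10000L + i)
    fp <- analyze_episode(epy, config = cfg_p)
    data.frame(atp_onset = fa$atp_onset_time,
               atp_peak_time = fa$atp_neg_peak_time,
               dyfp_peak_time = fa$dyfp_pos_peak_time,
               pyr_onset = fp$pyr_onset_time,
               pyr_peak_time = fp$pyr_pos_peak_time)
  })
  do.call(rbind, out)
}

#' Simulated kindling-session study
#'
#' Simulates `n_sessions` twelve-episode kindling sessions (first three
#' episodes from the early preset, last three from the fully kindled
#' preset, intermediate episodes interpolated) and reports, per session,
#' the early/fully-kindled stage means of AD duration and ATP-drop
#' magnitude.
#'
#' @param n_sessions Number of sessions (animals).
#' @param seed Integer seed.
#' @param n_episodes Episodes per session (default 6: the two stage
#'   groups back to back; the intervening episodes carry no information
#'   for the stage contrast).
#' @return Data frame with one row per session: `ad_early`, `ad_late`,
#'   `drop_early`, `drop_late`.
#' @export
kindling_study <- function(n_sessions = 50, seed = 1L, n_episodes = 6L) {
  cfg <- session_config(sensor = "ATeam")
  early <- scenario_preset("early_kindling")
  late <- scenario_preset("fully_kindled")
  out <- lapply(seq_len(n_sessions), function(s) {
    eps <- lapply(seq_len(n_episodes), function(i) {
      preset <- if (i <= n_episodes / 2) early else late
      args <- c(preset[setdiff(names(preset), c("sensor", "schedule"))],
                list(seed = seed + s * 100L + i, episode = i,
                     stage = if (i <= n_episodes / 2) "A" else "C"))
      do.call(simulate_episode, args)
    })
    ses <- analyze_session(eps, config = cfg)
    ss <- ses$stage_summary
    pick <- function(stage, metric)
      ss$mean[ss$stage == stage & ss$metric == metric]
    data.frame(ad_early = pick("early", "ad_duration"),
               ad_late = pick("fully_kindled", "ad_duration"),
               drop_early = pick("early", "atp_neg_peak_mag"),
               drop_late = pick("fully_kindled", "atp_neg_peak_mag"))
  })
  do.call(rbind, out)
}
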