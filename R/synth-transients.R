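#' Simulate a neuronal ATP concentration transient
#'
#' Generates a ligand (ATP) concentration trace whose *fluorescence*
#' excursion is controlled directly: the transient is parameterized as a
#' percentage change of the baseline fYFP emission and mapped into
#' concentration units through the inverse sensor model (efficiency ->
#' occupancy -> Hill inversion).  This keeps the simulator's inputs in the
#' same units in which results are reported (% of basal fluorescence).
#'
#' The fluorescence-% excursion is flat at 0 before
#' `onset_delay_s`, then declines as a saturating exponential
#' `amplitude_pct * (1 - exp(-(t - t0)/decay_tau_s))` until
#' `t0 + 8 * decay_tau_s` (where it is within 0.04% of `amplitude_pct`),
#' and then recovers exponentially with time constant `recovery_tau_s`.
#' `recovery_tau_s = Inf` gives a terminal, non-recovering collapse
#' (the SUDEP-like case).
#'
#' @param amplitude_pct Requested fluorescence change at the trough, in %
#'   of baseline fYFP; must be <= 0 (a drop).
#' @param onset_delay_s Delay from stimulation onset (t = 0) to the start
#'   of the decline (s, >= 0).
#' @param decay_tau_s Time constant of the decline (s, > 0).
#' @param recovery_tau_s Time constant of the recovery (s, > 0, may be
#'   `Inf`).
#' @param grid Time grid (s, typically 1 Hz) with 0 at stimulation onset.
#' @param sensor A [sensor_params()] object; default [ateam_params()].
#' @param baseline_ligand Resting ligand concentration (sensor units);
#'   default 2.3 mM ATP.
#' @return Numeric ligand trace on `grid`, with attributes `fluo_pct`
#'   (the generating fluorescence-% trace), `t_min` (time of the trough)
#'   and `baseline_ligand`.
#' @export
simulate_atp_transient <- function(amplitude_pct, onset_delay_s = 13.5,
                                   decay_tau_s = 2.3, recovery_tau_s = 60,
                                   grid = seq(-120, 480),
                                   sensor = ateam_params(),
                                   baseline_ligand = 2.3) {
  stopifnot(is.finite(amplitude_pct), is.finite(onset_delay_s),
            is.finite(decay_tau_s))
  if (amplitude_pct > 0) stop("'amplitude_pct' must be <= 0 (a drop)")
  if (onset_delay_s < 0 || decay_tau_s <= 0 || recovery_tau_s <= 0)
    stop("delays and time constants must be positive")
  t0 <- onset_delay_s
  t_min <- t0 + 8 * decay_tau_s
  g <- numeric(length(grid))
  act <- grid > t0
  g[act] <- amplitude_pct * (1 - exp(-(grid[act] - t0) / decay_tau_s))
  if (is.finite(recovery_tau_s)) {
    rec <- grid > t_min
    g[rec] <- g[rec] * exp(-(grid[rec] - t_min) / recovery_tau_s)
  }
  ligand <- ligand_from_fluo_pct(g, sensor, baseline_ligand)
  attr(ligand, "fluo_pct") <- g
  attr(ligand, "t_min") <- t_min
  attr(ligand, "baseline_ligand") <- baseline_ligand
  ligand
}

# Map a fYFP-% excursion to ligand concentration through the inverse
# sensor model.  fYFP is proportional to E, so a g% fluorescence change
# corresponds to E = E0 * (1 + g/100) regardless of brightness scaling
# (crosstalk assumed 0 in the parameterization).
ligand_from_fluo_pct <- function(g_pct, sensor, baseline_ligand) {
  e0 <- baseline_efficiency(sensor, baseline_ligand)
  e <- e0 * (1 + g_pct / 100)
  if (any(e <= sensor$e_min) || any(e >= sensor$e_max))
    stop("fluorescence excursion drives FRET efficiency outside ",
         "[e_min, e_max]: amplitude implies a non-physical concentration")
  ligand_from_occupancy(occupancy_from_efficiency(e, sensor), sensor)
}

#' Simulate an astrocytic pyruvate concentration transient
#'
#' Generates the characteristic triphasic pyruvate response: an optional
#' brief negative dip during stimulation, a rapid first-phase rise to an
#' initial peak, a second phase that either rises slowly to a global
#' maximum about one minute after stimulation onset or decays slowly to a
#' plateau, and a sustained third-phase plateau above the pre-stimulation
#' baseline that decays on a tens-of-minutes time scale.
#'
#' Like [simulate_atp_transient()], the transient is parameterized in
#' proxy-% units (positive = pyruvate increase = fYFP decrease for this
#' inverted-polarity sensor) and mapped through the inverse sensor model.
#' Segments are piecewise linear so that the internal breakpoints are
#' crisp and recoverable by [segment_pyruvate_phases()].
#'
#' @param dip_amp_pct Amplitude of the initial negative dip (<= 0; 0
#'   disables it).
#' @param p1_amp_pct First-phase peak amplitude (%, > 0 for a response).
#' @param p2_mode `"rise"` (slow further increase peaking ~1 min after
#'   stimulation onset) or `"decay"` (slow decay to the plateau).
#' @param plateau_amp_pct Plateau amplitude (%, >= 0).
#' @param plateau_decay_min Plateau decay time constant (minutes).
#' @param grid Time grid (s), 0 = stimulation onset; must extend past
#'   `phase3_start_s` when a plateau is requested.
#' @param onset_s Response onset time (s after stimulation onset).
#' @param p1_peak_s Time of the first-phase peak (s).
#' @param p2_peak_s Time of the second-phase (global) peak in `"rise"`
#'   mode (s).
#' @param phase3_start_s Plateau start time (s).
#' @param sensor A [sensor_params()] object; default [pyrs_params()].
#' @param baseline_ligand Resting pyruvate concentration (uM).
#' @return Numeric ligand trace on `grid` with attributes `fluo_pct`
#'   (the proxy-% generating trace) and `breakpoints` (list with
#'   `has_dip`, `t_onset`, `t1`, `t2`, `p2_mode`).
#' @export
simulate_pyruvate_transient <- function(dip_amp_pct = -2, p1_amp_pct = 15,
                                        p2_mode = c("rise", "decay"),
                                        plateau_amp_pct = 8,
                                        plateau_decay_min = 15,
                                        grid = seq(-120, 900),
                                        onset_s = 2.7, p1_peak_s = 20.75,
                                        p2_peak_s = 60, phase3_start_s = 180,
                                        sensor = pyrs_params(),
                                        baseline_ligand = 15) {
  p2_mode <- match.arg(p2_mode)
  if (dip_amp_pct > 0) stop("'dip_amp_pct' must be <= 0")
  if (plateau_amp_pct < 0) stop("'plateau_amp_pct' must be >= 0")
  stopifnot(onset_s > 0, p1_peak_s > onset_s, p2_peak_s > p1_peak_s,
            phase3_start_s > p2_peak_s)
  if (plateau_amp_pct > 0 && max(grid) < phase3_start_s)
    stop("grid shorter than the requested plateau window")
  g <- numeric(length(grid))
  # initial dip: half-sine over [0, onset_s]
  d <- grid > 0 & grid < onset_s
  g[d] <- dip_amp_pct * sin(pi * grid[d] / onset_s)
  # phase 1: linear rise onset -> first peak
  ramp <- function(t, ta, tb, ya, yb) ya + (yb - ya) * (t - ta) / (tb - ta)
  p1 <- grid >= onset_s & grid < p1_peak_s
  g[p1] <- ramp(grid[p1], onset_s, p1_peak_s, 0, p1_amp_pct)
  if (p2_mode == "rise") {
    p2_amp <- 1.25 * p1_amp_pct
    a <- grid >= p1_peak_s & grid < p2_peak_s
    g[a] <- ramp(grid[a], p1_peak_s, p2_peak_s, p1_amp_pct, p2_amp)
    b <- grid >= p2_peak_s & grid < phase3_start_s
    g[b] <- ramp(grid[b], p2_peak_s, phase3_start_s, p2_amp, plateau_amp_pct)
  } else {
    a <- grid >= p1_peak_s & grid < phase3_start_s
    g[a] <- ramp(grid[a], p1_peak_s, phase3_start_s, p1_amp_pct,
                 plateau_amp_pct)
  }
  p3 <- grid >= phase3_start_s
  g[p3] <- plateau_amp_pct * exp(-(grid[p3] - phase3_start_s) /
                                   (plateau_decay_min * 60))
  # positive proxy-% = pyruvate up = fYFP down (inverted polarity sensor)
  ligand <- ligand_from_fluo_pct(-g, sensor, baseline_ligand)
  attr(ligand, "fluo_pct") <- g
  attr(ligand, "breakpoints") <- list(has_dip = dip_amp_pct < 0,
                                      t_onset = onset_s, t1 = p1_peak_s,
                                      t2 = phase3_start_s, p2_mode = p2_mode)
  attr(ligand, "baseline_ligand") <- baseline_ligand
  ligand
}

#' Smooth bump traces for simulated confounds
#'
#' Gaussian-shaped fractional perturbations used as blood-volume (BBV)
#' and pH-quench traces.  A negative `peak` models vessel constriction
#' (BBV drop -> brighter tissue through the reduced vascular shadow); a
#' positive pH bump models cytosolic alkalinization (YFP emission
#' enhancement).  The bump is truncated to zero beyond
#' `4 * width_s` from the peak so the perturbation has finite support.
#'
#' @param peak Peak fractional change (dimensionless, e.g. -0.05).
#' @param peak_time_s Time of the peak (s).
#' @param width_s Gaussian sigma (s).
#' @param grid Time grid (s).
#' @return Numeric trace on `grid`.
#' @export
confound_bump <- function(peak, peak_time_s, width_s, grid) {
  stopifnot(is.finite(peak), width_s > 0)
  z <- (grid - peak_time_s) / width_s
  out <- peak * exp(-z^2 / 2)
  out[abs(z) > 4] <- 0
  out
}
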