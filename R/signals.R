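#' Normalize a trace to its pre-stimulus baseline
#'
#' Expresses a fluorescence trace as a percentage change from its
#' baseline mean: `100 * (F(t) - F0) / F0` with `F0` the mean over
#' `baseline_window`.  All reported response magnitudes are in these
#' "% of basal fluorescence" units.
#'
#' @param x Numeric trace.
#' @param time_s Time stamps (s), same length.
#' @param baseline_window `[t0, t1]` (s) defining the baseline samples;
#'   default `c(-120, -10)` relative to stimulation onset.
#' @param min_samples Minimum number of baseline samples required
#'   (default 30).
#' @return Numeric trace in %, with attribute `F0`.
#' @export
normalize_to_baseline <- function(x, time_s, baseline_window = c(-120, -10),
                                  min_samples = 30L) {
  stopifnot(length(x) == length(time_s))
  idx <- window_idx(time_s, baseline_window)
  if (length(idx) < min_samples)
    stop("baseline window contains fewer than ", min_samples, " samples")
  f0 <- mean(x[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean F0 must be positive")
  out <- 100 * (x - f0) / f0
  attr(out, "F0") <- f0
  out
}

#' Normalize every channel of a trace table to baseline
#'
#' @param channels A [channel_traces()] data frame.
#' @inheritParams normalize_to_baseline
#' @return A `channel_traces` data frame of %-traces with attribute
#'   `F0` (named vector) and `baseline_window`.
#' @export
normalize_channels <- function(channels, baseline_window = c(-120, -10),
                               min_samples = 30L) {
  stopifnot(inherits(channels, "channel_traces"))
  out <- as.data.frame(channels)
  f0 <- numeric(0)
  for (ch in trace_channels(channels)) {
    v <- normalize_to_baseline(channels[[ch]], channels$time_s,
                               baseline_window, min_samples)
    f0[[ch]] <- attr(v, "F0")
    out[[ch]] <- as.numeric(v)
  }
  out <- channel_traces(out)
  attr(out, "F0") <- f0
  attr(out, "baseline_window") <- baseline_window
  out
}

#' Ratio-method ligand proxy
#'
#' Elementwise quotient of the two FRET channels, oriented per sensor so
#' that the proxy rises with ligand concentration: `fYFP/fCFP` for the
#' ATP sensor (FRET rises with ATP) and `fCFP/fYFP` for the
#' inverted-polarity pyruvate sensor.
#'
#' With `as_percent = TRUE` the ratio trace is converted to *fYFP
#' equivalent* percent units through the sensor model, so that ratio- and
#' difference-method magnitudes are directly comparable: from
#' `r(t)/r0 = [E(1-E0)] / [E0(1-E)]` (ATP orientation) the efficiency
#' `E(t)` is recovered exactly given the baseline efficiency `E0`, and
#' the proxy is reported as `100 * polarity * (E - E0)/E0`.
#'
#' @param channels A [channel_traces()] data frame containing `fCFP` and
#'   `fYFP` (raw, not normalized).
#' @param sensor `"ATeam"` or `"PYRS"` (chooses numerator/denominator
#'   and orientation).
#' @param as_percent Convert to calibrated % units (default `FALSE`:
#'   return the dimensionless ratio).
#' @param sensor_params A [sensor_params()] object (required for
#'   `as_percent`).
#' @param baseline_ligand Resting ligand level used to fix `E0`
#'   (required for `as_percent`).
#' @param baseline_window Window for the ratio baseline `r0`.
#' @return An [fp_trace()] with attributes `method = "ratio"`, `sensor`,
#'   and `units`.
#' @export
ratio_signal <- function(channels, sensor = c("ATeam", "PYRS"),
                         as_percent = FALSE, sensor_params = NULL,
                         baseline_ligand = NULL,
                         baseline_window = c(-120, -10)) {
  sensor <- match.arg(sensor)
  stopifnot(inherits(channels, "channel_traces"),
            all(c("fCFP", "fYFP") %in% names(channels)))
  num <- if (sensor == "ATeam") channels$fYFP else channels$fCFP
  den <- if (sensor == "ATeam") channels$fCFP else channels$fYFP
  if (any(den <= 0)) stop("denominator channel must be > 0 everywhere")
  r <- num / den
  if (!as_percent)
    return(fp_trace(channels$time_s, r, method = "ratio", sensor = sensor,
                    units = "ratio"))
  if (is.null(sensor_params) || is.null(baseline_ligand))
    stop("'sensor_params' and 'baseline_ligand' are required for as_percent")
  e0 <- baseline_efficiency(sensor_params, baseline_ligand)
  idx <- window_idx(channels$time_s, baseline_window)
  if (length(idx) < 3L) stop("baseline window outside trace")
  r0 <- mean(r[idx])
  rel <- r / r0
  # invert r/r0 -> E; for the PYRS orientation the quotient is flipped
  if (sensor == "PYRS") rel <- 1 / rel
  q <- rel * e0 / (1 - e0)
  e <- q / (1 + q)
  pct <- 100 * (e - e0) / e0
  if (sensor == "PYRS") pct <- -pct   # orient upward with ligand
  fp_trace(channels$time_s, pct, method = "ratio", sensor = sensor,
           units = "percent")
}

#' Difference-method ligand proxy
#'
#' The difference of the %-normalized FRET-excited and directly excited
#' YFP channels.  Artifacts that act equally (multiplicatively) on fYFP
#' and dYFP -- blood-volume shadowing and, under the equal-action
#' assumption, pH -- cancel to first order, leaving the ligand-driven
#' FRET change.  Orientation follows the sensor polarity so the proxy
#' rises with ligand: `fYFP% - dYFP%` for the ATP sensor, `dYFP% - fYFP%`
#' for the pyruvate sensor.
#'
#' @param fyfp_pct,dyfp_pct %-normalized fYFP and dYFP traces on a
#'   common grid (see [normalize_to_baseline()]).
#' @param time_s Shared time stamps (s).
#' @param sensor `"ATeam"` or `"PYRS"`.
#' @return An [fp_trace()] in % units with attributes `method`, `sensor`.
#' @export
difference_signal <- function(fyfp_pct, dyfp_pct, time_s,
                              sensor = c("ATeam", "PYRS")) {
  sensor <- match.arg(sensor)
  if (length(fyfp_pct) != length(dyfp_pct) ||
      length(fyfp_pct) != length(time_s))
    stop("fYFP, dYFP and time grids must match")
  v <- if (sensor == "ATeam") fyfp_pct - dyfp_pct else dyfp_pct - fyfp_pct
  fp_trace(time_s, v, method = "difference", sensor = sensor,
           units = "percent")
}

#' Detrend the Texas Red channel against its post-injection decay
#'
#' Intravascular Texas Red fades over one to two hours after injection,
#' so the recorded trace sits on a sloping baseline.  A least-squares
#' line is fitted over `fit_windows` -- which must exclude the
#' stimulus/after-discharge response epoch -- and subtracted from the
#' whole trace.
#'
#' @param x Texas Red trace.
#' @param time_s Time stamps (s).
#' @param fit_windows A list of `[t0, t1]` windows used for the fit;
#'   default: the 120 s pre-stimulus segment plus everything from 300 s
#'   post-stimulus onward.
#' @param min_samples Minimum total fit samples (default 30).
#' @return Detrended trace (baseline-relative), with attribute `fit`
#'   (`c(intercept, slope)`).
#' @export
detrend_texasred <- function(x, time_s,
                             fit_windows = list(c(-120, -1), c(300, Inf)),
                             min_samples = 30L) {
  stopifnot(length(x) == length(time_s))
  idx <- sort(unique(unlist(lapply(fit_windows, function(w)
    which(time_s >= w[1] & time_s <= w[2])))))
  if (length(idx) < min_samples)
    stop("fit windows contain fewer than ", min_samples, " samples")
  if (stats::var(time_s[idx]) == 0)
    stop("degenerate fit: all fit-window timestamps identical")
  fit <- stats::lm.fit(cbind(1, time_s[idx]), x[idx])
  out <- x - (fit$coefficients[1] + fit$coefficients[2] * time_s)
  attr(out, "fit") <- unname(fit$coefficients)
  out
}

#' Invert a trace
#'
#' Elementwise negation; used to overlay the (inverted) Texas Red
#' blood-volume trace on the dYFP shadow trace.
#'
#' @param x Numeric trace or [fp_trace()].
#' @return Same shape as `x`, negated.
#' @export
invert <- function(x) {
  if (inherits(x, "fp_trace")) {
    x$value <- -x$value
    x
  } else -x
}
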