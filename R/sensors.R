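#' Sensor parameter set for a FRET-based metabolite biosensor
#'
#' Bundles the binding and emission constants that define the forward model
#' of a genetically encoded FRET sensor.  Ligand occupancy follows a Hill
#' binding curve, FRET efficiency interpolates linearly between `e_min` and
#' `e_max` with occupancy, and the three measured channels are mixed from
#' the donor/acceptor emissions:
#' \deqn{\theta = L^h / (K_d^h + L^h)}
#' \deqn{E = e_{min} + (e_{max}-e_{min})\,\theta \quad (\mathrm{polarity}\; +1)}
#' \deqn{E = e_{max} - (e_{max}-e_{min})\,\theta \quad (\mathrm{polarity}\; -1)}
#'
#' @param kd Apparent dissociation constant, in the sensor's ligand units
#'   (mM for the ATP sensor, uM for the pyruvate sensor).
#' @param hill Hill coefficient (dimensionless, > 0).
#' @param polarity `+1` if FRET efficiency rises with ligand (ATeam-type
#'   ATP sensors), `-1` if it falls (PYRS-type pyruvate sensors).
#' @param e_min,e_max FRET efficiency bounds, `0 <= e_min < e_max <= 1`.
#' @param cfp_brightness,yfp_brightness Emission yield of the donor (CFP)
#'   and FRET-excited acceptor (YFP) channels per unit excitation
#'   (arbitrary units).
#' @param direct_yfp_yield Emission yield of the directly excited acceptor
#'   channel (dYFP); independent of FRET state.
#' @param crosstalk Fraction of direct acceptor excitation bleeding into
#'   the donor-excitation pulse (adds `crosstalk * direct_yfp_yield` to
#'   fYFP).  Default 0.
#' @return An object of class `sensor_params`.
#' @seealso [ateam_params()], [pyrs_params()], [fret_emissions()]
#' @export
sensor_params <- function(kd, hill = 1, polarity = 1L,
                          e_min = 0.15, e_max = 0.60,
                          cfp_brightness = 1, yfp_brightness = 1,
                          direct_yfp_yield = 1, crosstalk = 0) {
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd),
            is.numeric(hill), length(hill) == 1L, is.finite(hill))
  if (kd <= 0) stop("'kd' must be > 0")
  if (hill <= 0) stop("'hill' must be > 0")
  if (!polarity %in% c(-1L, 1L, -1, 1)) stop("'polarity' must be +1 or -1")
  if (!(e_min >= 0 && e_min < e_max && e_max <= 1))
    stop("require 0 <= e_min < e_max <= 1")
  if (cfp_brightness <= 0 || yfp_brightness <= 0 || direct_yfp_yield < 0)
    stop("brightness parameters must be positive")
  structure(list(kd = kd, hill = hill, polarity = as.integer(polarity),
                 e_min = e_min, e_max = e_max,
                 cfp_brightness = cfp_brightness,
                 yfp_brightness = yfp_brightness,
                 direct_yfp_yield = direct_yfp_yield,
                 crosstalk = crosstalk),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf("<sensor_params> Kd = %g, Hill = %g, polarity = %+d, E in [%g, %g]\n",
              x$kd, x$hill, x$polarity, x$e_min, x$e_max))
  invisible(x)
}

#' Preset: neuronal cytosolic ATP sensor (ATeam family)
#'
#' Apparent Kd 1.2 mM, Hill coefficient 1, FRET efficiency rises with ATP.
#' Ligand units are mM.
#'
#' @param ... Overrides passed to [sensor_params()].
#' @return A `sensor_params` object.
#' @export
ateam_params <- function(...) {
  args <- utils::modifyList(
    list(kd = 1.2, hill = 1, polarity = 1L),
    list(...))
  do.call(sensor_params, args)
}

#' Preset: astrocytic cytosolic pyruvate sensor (PYRS family)
#'
#' Apparent Kd 26 uM, Hill coefficient 1.2, inverted polarity: pyruvate
#' binding lowers FRET efficiency, so fCFP rises and fYFP falls with
#' ligand.  Ligand units are uM.
#'
#' @param ... Overrides passed to [sensor_params()].
#' @return A `sensor_params` object.
#' @export
pyrs_params <- function(...) {
  args <- utils::modifyList(
    list(kd = 26, hill = 1.2, polarity = -1L),
    list(...))
  do.call(sensor_params, args)
}

#' Hill binding occupancy
#'
#' Fraction of sensor molecules with ligand bound.
#'
#' @param ligand Numeric vector of ligand concentrations (>= 0), in the
#'   sensor's units.
#' @param sensor A [sensor_params()] object.
#' @return Occupancy in `[0, 1)`, same length as `ligand`.
#' @export
hill_occupancy <- function(ligand, sensor) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (any(!is.finite(ligand)) || any(ligand < 0))
    stop("'ligand' must be finite and >= 0")
  lh <- ligand^sensor$hill
  lh / (sensor$kd^sensor$hill + lh)
}

#' Invert the Hill binding curve
#'
#' @param theta Occupancy in `[0, 1)`.
#' @param sensor A [sensor_params()] object.
#' @return Ligand concentration in the sensor's units.
#' @export
ligand_from_occupancy <- function(theta, sensor) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (any(theta < 0 | theta >= 1))
    stop("occupancy must lie in [0, 1)")
  sensor$kd * (theta / (1 - theta))^(1 / sensor$hill)
}

#' FRET efficiency at a given occupancy
#'
#' @inheritParams ligand_from_occupancy
#' @return FRET efficiency in `[e_min, e_max]`.
#' @export
fret_efficiency <- function(theta, sensor) {
  stopifnot(inherits(sensor, "sensor_params"))
  span <- sensor$e_max - sensor$e_min
  if (sensor$polarity > 0) sensor$e_min + span * theta
  else sensor$e_max - span * theta
}

#' Occupancy implied by a FRET efficiency
#'
#' @param e FRET efficiency, within `[e_min, e_max]`.
#' @param sensor A [sensor_params()] object.
#' @return Occupancy in `[0, 1]`.
#' @export
occupancy_from_efficiency <- function(e, sensor) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (any(e < sensor$e_min - 1e-12 | e > sensor$e_max + 1e-12))
    stop("efficiency outside the sensor's [e_min, e_max] range")
  span <- sensor$e_max - sensor$e_min
  th <- if (sensor$polarity > 0) (e - sensor$e_min) / span
        else (sensor$e_max - e) / span
  pmin(pmax(th, 0), 1)
}

#' Ideal (confound-free) sensor emissions for a ligand trace
#'
#' Maps a ligand concentration trace through the sensor forward model to
#' the three measured fluorescence channels:
#' `fCFP = (1 - E) * cfp_brightness`, `fYFP = E * yfp_brightness +
#' crosstalk * direct_yfp_yield`, and `dYFP = direct_yfp_yield`, which is
#' independent of the FRET state and therefore of ligand concentration.
#'
#' @param ligand Ligand concentration trace (>= 0).
#' @param sensor A [sensor_params()] object.
#' @param time_s Optional time stamps (s); defaults to `seq_along(ligand) - 1`.
#' @return A `channel_traces` data frame with columns `time_s`, `fCFP`,
#'   `fYFP`, `dYFP`.
#' @export
fret_emissions <- function(ligand, sensor, time_s = NULL) {
  theta <- hill_occupancy(ligand, sensor)
  e <- fret_efficiency(theta, sensor)
  if (is.null(time_s)) time_s <- seq_along(ligand) - 1
  stopifnot(length(time_s) == length(ligand))
  channel_traces(data.frame(
    time_s = time_s,
    fCFP = (1 - e) * sensor$cfp_brightness,
    fYFP = e * sensor$yfp_brightness + sensor$crosstalk * sensor$direct_yfp_yield,
    dYFP = rep(sensor$direct_yfp_yield, length(ligand))))
}

# Baseline FRET efficiency at a resting ligand level; used by the
# %-fluorescence parameterization of the transient generators and by the
# model-based calibration of the ratio proxy.
baseline_efficiency <- function(sensor, baseline_ligand) {
  fret_efficiency(hill_occupancy(baseline_ligand, sensor), sensor)
}
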