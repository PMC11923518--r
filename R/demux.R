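#' Excitation pulse schedule for time-division ("gallop") photometry
#'
#' Describes how PMT samples within each excitation cycle map to
#' fluorescence channels.  Each row is one (excitation pulse, detector)
#' assignment: during the pulse window `[start_ms, start_ms + duration_ms)`
#' the named detector reads the named channel.  A single excitation pulse
#' may feed both detectors (e.g. Blue excitation yields fCFP on the CFP
#' PMT and fYFP on the YFP PMT simultaneously).
#'
#' @param pulses Data frame with columns `label` (`Blue`, `Teal`,
#'   `Yellow`), `start_ms`, `duration_ms`, `detector` (`pmt1`, `pmt2`)
#'   and `channel` (`fCFP`, `fYFP`, `dYFP`, `TexasRed`).
#' @param cycle_period_s Length of one excitation cycle (s); default 1.
#' @return An object of class `excitation_schedule`.
#' @export
excitation_schedule <- function(pulses, cycle_period_s = 1.0) {
  need <- c("label", "start_ms", "duration_ms", "detector", "channel")
  stopifnot(is.data.frame(pulses), all(need %in% names(pulses)))
  if (!all(pulses$detector %in% c("pmt1", "pmt2")))
    stop("detector must be 'pmt1' or 'pmt2'")
  if (!all(pulses$channel %in% .fp_channels))
    stop("unknown channel name in schedule")
  if (any(pulses$duration_ms <= 0)) stop("pulse durations must be > 0")
  if (any(pulses$start_ms < 0) ||
      any(pulses$start_ms + pulses$duration_ms > cycle_period_s * 1000))
    stop("pulse windows must lie within one cycle")
  if (anyDuplicated(pulses[c("label", "detector")]))
    stop("each (label, detector) pair may map to only one channel")
  # distinct excitation pulses (distinct labels) must not overlap in time
  win <- unique(pulses[c("label", "start_ms", "duration_ms")])
  if (anyDuplicated(win$label))
    stop("inconsistent pulse windows for a single excitation label")
  win <- win[order(win$start_ms), ]
  if (nrow(win) > 1L) {
    ends <- win$start_ms + win$duration_ms
    if (any(win$start_ms[-1L] < ends[-nrow(win)]))
      stop("excitation pulse windows overlap within the cycle")
  }
  structure(list(pulses = pulses, cycle_period_s = cycle_period_s),
            class = "excitation_schedule")
}

#' @export
print.excitation_schedule <- function(x, ...) {
  cat(sprintf("<excitation_schedule> cycle %.3g s\n", x$cycle_period_s))
  print(x$pulses, row.names = FALSE)
  invisible(x)
}

#' Standard excitation schedule presets
#'
#' * `"dual"`: Blue (~440 nm) for 20 ms, a 10 ms gap, then Teal
#'   (~510 nm) for 20 ms, then a 950 ms gap until the next cycle.  The
#'   Blue pulse is read as fCFP on pmt1 and fYFP on pmt2; the Teal pulse
#'   as dYFP on pmt2.
#' * `"triple"`: Blue 10 ms, 10 ms gap, Teal 10 ms, 10 ms gap, Yellow
#'   (~575 nm) 30 ms, then a 930 ms gap.  Read as fYFP (pmt1), dYFP
#'   (pmt1) and TexasRed (pmt2); CFP emission is not detected in this
#'   configuration.
#'
#' @param preset `"dual"` or `"triple"`.
#' @return An [excitation_schedule()].
#' @export
schedule_preset <- function(preset = c("dual", "triple")) {
  preset <- match.arg(preset)
  pulses <- switch(preset,
    dual = data.frame(
      label = c("Blue", "Blue", "Teal"),
      start_ms = c(0, 0, 30),
      duration_ms = c(20, 20, 20),
      detector = c("pmt1", "pmt2", "pmt2"),
      channel = c("fCFP", "fYFP", "dYFP"),
      stringsAsFactors = FALSE),
    triple = data.frame(
      label = c("Blue", "Teal", "Yellow"),
      start_ms = c(0, 20, 40),
      duration_ms = c(10, 10, 30),
      detector = c("pmt1", "pmt1", "pmt2"),
      channel = c("fYFP", "dYFP", "TexasRed"),
      stringsAsFactors = FALSE))
  excitation_schedule(pulses)
}

#' Raw multiplexed photometry recording
#'
#' Container for the two PMT voltage traces (and optionally the EEG)
#' sampled at 2 kHz, together with the excitation schedule and the
#' per-channel dark (background) levels needed to demultiplex them.
#'
#' @param pmt1,pmt2 Numeric voltage traces, equal length.
#' @param fs Sampling rate (Hz); fixed at 2000 in the acquisition system.
#' @param schedule An [excitation_schedule()].
#' @param dark Dark PMT output: a single value, or a named vector with
#'   one entry per channel.  Must be >= 0.
#' @param eeg Optional EEG trace, same length as the PMT traces.
#' @param t0 Time stamp (s) of the first sample; the first excitation
#'   cycle starts here.
#' @param seed Optional integer recorded for provenance.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(pmt1, pmt2, fs = 2000, schedule = schedule_preset("dual"),
                          dark = 0, eeg = NULL, t0 = 0, seed = NULL) {
  stopifnot(length(pmt1) == length(pmt2))
  if (!is.null(eeg)) stopifnot(length(eeg) == length(pmt1))
  stopifnot(inherits(schedule, "excitation_schedule"))
  if (any(dark < 0)) stop("'dark' must be >= 0")
  structure(list(pmt1 = pmt1, pmt2 = pmt2, eeg = eeg, fs = fs,
                 schedule = schedule, dark = dark, t0 = t0, seed = seed),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %g Hz (%.1f s), eeg: %s\n",
              length(x$pmt1), x$fs, length(x$pmt1) / x$fs,
              if (is.null(x$eeg)) "absent" else "present"))
  invisible(x)
}

# Expand a scalar/partial dark specification to a full named per-channel
# vector for the channels in the schedule.
dark_vector <- function(dark, schedule) {
  chans <- unique(schedule$pulses$channel)
  if (is.null(names(dark))) {
    if (length(dark) != 1L) stop("unnamed 'dark' must be a single value")
    return(stats::setNames(rep(dark, length(chans)), chans))
  }
  missing <- setdiff(chans, names(dark))
  if (length(missing))
    stop("missing dark level for channel(s): ", paste(missing, collapse = ", "))
  dark[chans]
}

# In-pulse sample indices (1-based, within one cycle) for a schedule row,
# optionally trimmed by an edge guard at each end.
pulse_samples <- function(row, fs, edge_guard_ms = 0) {
  first <- floor(row$start_ms / 1000 * fs) + 1L
  last  <- floor((row$start_ms + row$duration_ms) / 1000 * fs)
  g <- round(edge_guard_ms / 1000 * fs)
  first <- first + g
  last <- last - g
  if (last < first)
    stop("pulse window has no samples left after edge trimming")
  seq.int(first, last)
}

#' Demultiplex a raw recording into 1 Hz channel traces
#'
#' For every complete excitation cycle and every scheduled pulse, the PMT
#' output within the pulse window (after trimming `edge_guard_ms` at each
#' pulse edge to avoid LED rise/fall transients) is averaged and the
#' channel's dark level subtracted, yielding one sample per channel per
#' cycle -- an effective 1 Hz sampling rate for the default 1 s cycle.
#' Samples outside pulse windows are ignored; a partial trailing cycle is
#' dropped.  Time stamps are assigned at the cycle midpoint.
#'
#' Dark subtraction may yield small negative values; these are preserved
#' (they carry noise information), not clipped.
#'
#' @param raw A [raw_recording()].
#' @param schedule Excitation schedule; defaults to the one stored in `raw`.
#' @param dark Dark levels; default from `raw`.  See [raw_recording()].
#' @param edge_guard_ms Duration trimmed from each pulse edge before
#'   averaging (default 1 ms = 2 samples at 2 kHz).  Set to 0 to average
#'   the whole pulse.
#' @return A [channel_traces()] data frame with one column per scheduled
#'   channel.
#' @export
demux <- function(raw, schedule = raw$schedule, dark = raw$dark,
                  edge_guard_ms = 1) {
  stopifnot(inherits(raw, "raw_recording"),
            inherits(schedule, "excitation_schedule"))
  fs <- raw$fs
  cyc_n <- round(schedule$cycle_period_s * fs)
  if (abs(cyc_n - schedule$cycle_period_s * fs) > 1e-9)
    stop("cycle period is not an integer number of samples at this rate")
  n_cycles <- length(raw$pmt1) %/% cyc_n
  if (n_cycles < 1L) stop("recording shorter than one excitation cycle")
  dk <- dark_vector(dark, schedule)
  offs <- (seq_len(n_cycles) - 1L) * cyc_n
  out <- data.frame(time_s = raw$t0 + (seq_len(n_cycles) - 1L) *
                      schedule$cycle_period_s + schedule$cycle_period_s / 2)
  for (i in seq_len(nrow(schedule$pulses))) {
    row <- schedule$pulses[i, ]
    idx <- pulse_samples(row, fs, edge_guard_ms)
    tr <- raw[[row$detector]]
    m <- matrix(tr[rep(offs, each = length(idx)) + idx],
                nrow = length(idx))
    out[[row$channel]] <- colMeans(m) - dk[[row$channel]]
  }
  channel_traces(out)
}

#' Estimate per-channel dark (background) levels from a blocked segment
#'
#' During acquisition the fiber tip is covered so that only excitation
#' bleed-through and amplifier offset reach the PMTs; averaging the
#' in-pulse output over that segment gives the background level to
#' subtract during demultiplexing.
#'
#' @param raw A [raw_recording()] of the fiber-blocked segment (or a
#'   longer recording, see `segment`).
#' @param segment Optional `[t_start, t_end]` (s, in recording time)
#'   restricting which cycles are used; default: all complete cycles.
#' @param min_cycles Minimum number of complete cycles required
#'   (default 5).
#' @return Named numeric vector of dark levels, one per scheduled channel.
#' @export
measure_dark <- function(raw, segment = NULL, min_cycles = 5L) {
  stopifnot(inherits(raw, "raw_recording"))
  sched <- raw$schedule
  fs <- raw$fs
  cyc_n <- round(sched$cycle_period_s * fs)
  n_cycles <- length(raw$pmt1) %/% cyc_n
  cyc_start_t <- raw$t0 + (seq_len(n_cycles) - 1L) * sched$cycle_period_s
  keep <- if (is.null(segment)) seq_len(n_cycles) else
    which(cyc_start_t >= segment[1] &
            cyc_start_t + sched$cycle_period_s <= segment[2])
  if (length(keep) < min_cycles)
    stop("blocked segment must contain at least ", min_cycles,
         " complete cycles")
  offs <- (keep - 1L) * cyc_n
  out <- numeric(0)
  for (i in seq_len(nrow(sched$pulses))) {
    row <- sched$pulses[i, ]
    idx <- pulse_samples(row, fs, 0)
    tr <- raw[[row$detector]]
    out[[row$channel]] <- mean(tr[rep(offs, each = length(idx)) + idx])
  }
  out
}

#' Write or read a raw recording as CSV
#'
#' Plain-text exchange format with columns `t_s pmt1_V pmt2_V eeg`
#' (the `eeg` column is written as empty when absent).
#'
#' @param raw A [raw_recording()].
#' @param path File path.
#' @return `path` (write) or a `raw_recording` (read), invisibly for write.
#' @export
write_raw_csv <- function(raw, path) {
  n <- length(raw$pmt1)
  df <- data.frame(t_s = raw$t0 + (seq_len(n) - 1L) / raw$fs,
                   pmt1_V = raw$pmt1, pmt2_V = raw$pmt2,
                   eeg = if (is.null(raw$eeg)) rep(NA_real_, n) else raw$eeg)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raw_csv
#' @param schedule,dark Metadata to attach (not stored in the CSV).
#' @export
read_raw_csv <- function(path, schedule = schedule_preset("dual"), dark = 0) {
  df <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(df$t_s))
  eeg <- if (all(is.na(df$eeg))) NULL else df$eeg
  raw_recording(df$pmt1_V, df$pmt2_V, fs = round(fs), schedule = schedule,
                dark = dark, eeg = eeg, t0 = df$t_s[1])
}
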