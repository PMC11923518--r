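#' Per-channel 1 Hz fluorescence traces
#'
#' A thin data-frame container for demultiplexed, background-corrected
#' fluorescence channels on a common 1 Hz time base.  Columns are
#' `time_s` plus any of `fCFP`, `fYFP`, `dYFP`, `TexasRed`.  Which
#' channels are present depends on the excitation configuration: the
#' dual-excitation (ATP/pyruvate) configuration records fCFP, fYFP and
#' dYFP; the triple-excitation (Texas Red) configuration records fYFP,
#' dYFP and TexasRed but no fCFP.
#'
#' @param df A data frame with a numeric `time_s` column and at least one
#'   recognised channel column.
#' @return `df` with class `channel_traces` prepended.
#' @export
channel_traces <- function(df) {
  stopifnot(is.data.frame(df), "time_s" %in% names(df))
  chans <- intersect(names(df), .fp_channels)
  if (length(chans) == 0L) stop("no recognised channel columns in 'df'")
  if (any(!is.finite(df$time_s))) stop("non-finite timestamps")
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("'time_s' must be strictly increasing")
  class(df) <- unique(c("channel_traces", class(df)))
  df
}

.fp_channels <- c("fCFP", "fYFP", "dYFP", "TexasRed")

#' Names of the fluorescence channels present in a trace table
#' @param x A `channel_traces` data frame.
#' @return Character vector of channel names.
#' @export
trace_channels <- function(x) intersect(names(x), .fp_channels)

#' A single time-stamped trace
#'
#' Used for derived signals (ligand proxies, detrended Texas Red, EEG
#' envelopes): a data frame with columns `time_s` and `value` plus
#' optional metadata attributes.
#'
#' @param time_s Numeric time stamps (s), strictly increasing.
#' @param value Numeric values, same length.
#' @param ... Metadata attributes to attach (e.g. `method`, `sensor`,
#'   `units`).
#' @return A data frame of class `fp_trace`.
#' @export
fp_trace <- function(time_s, value, ...) {
  stopifnot(length(time_s) == length(value))
  if (is.unsorted(time_s, strictly = TRUE))
    stop("'time_s' must be strictly increasing")
  out <- data.frame(time_s = time_s, value = value)
  meta <- list(...)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  class(out) <- c("fp_trace", class(out))
  out
}

# Indices of samples with time in [window[1], window[2]] (closed).
window_idx <- function(time_s, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  which(time_s >= window[1] & time_s <= window[2])
}

#' Write channel traces to a tab-separated file
#'
#' Header is `time_s` followed by the channel columns present
#' (e.g. `time_s fCFP fYFP dYFP TexasRed`).
#'
#' @param x A `channel_traces` data frame.
#' @param path Output file path.
#' @param comment Optional character vector written as `#`-prefixed
#'   header comment lines (provenance, configuration).
#' @return `path`, invisibly.
#' @export
write_channel_traces <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "channel_traces"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(x)[, c("time_s", trace_channels(x))],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read channel traces from a tab-separated file
#'
#' @param path File written by [write_channel_traces()] (lines starting
#'   with `#` are ignored).
#' @return A `channel_traces` data frame.
#' @export
read_channel_traces <- function(path) {
  channel_traces(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#"))
}

#' Read or write episode annotations
#'
#' Annotations are one row per stimulation episode with columns
#' `episode`, `stim_start_s`, `stim_end_s`, `ad_end_s`, `stage`.
#' `ad_end_s` may be `NA` (to be detected from the EEG) or a manual
#' override; `stage` is a free label (`A`, `B`, `C`, `SUDEP`, `unknown`)
#' consumed as metadata only.
#'
#' @param path File path.
#' @return For `read_annotations`, a data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("episode", "stim_start_s", "stim_end_s", "ad_end_s", "stage")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  validate_annotation(ann)
  ann
}

#' @rdname read_annotations
#' @param ann Annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  validate_annotation(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotation <- function(ann) {
  with(ann, {
    if (any(stim_start_s >= stim_end_s)) stop("stim_start_s must be < stim_end_s")
    ok <- is.na(ad_end_s) | ad_end_s >= stim_end_s
    if (!all(ok)) stop("ad_end_s must be >= stim_end_s (or NA)")
  })
  invisible(ann)
}

#' Build a single-episode annotation row
#'
#' @param stim_start,stim_end Stimulation interval (s).
#' @param ad_end After-discharge end time (s) or `NA` to detect from EEG.
#' @param stage Kindling/seizure stage label (metadata only).
#' @param episode Episode index within the session.
#' @return A one-row annotation data frame.
#' @export
annotate_episode <- function(stim_start = 0, stim_end = 10, ad_end = NA_real_,
                             stage = "unknown", episode = 1L) {
  ann <- data.frame(episode = as.integer(episode),
                    stim_start_s = stim_start, stim_end_s = stim_end,
                    ad_end_s = as.numeric(ad_end), stage = stage,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}
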