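#' Construct an EEG recording object
#'
#' Container for one condition's multichannel signal: a channels x samples
#' matrix in microvolts, the sampling rate, the 10-10 montage channel names
#' (plus an optional EOG channel flagged as non-EEG), a condition tag and an
#' event table (cue onsets/offsets, feedback, injected artifacts).
#'
#' @param data numeric matrix, channels x samples, microvolts. Row names are
#'   taken as channel names if `channel_names` is missing.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector matching `nrow(data)`.
#' @param condition `"rest"` or `"task"`.
#' @param events data.frame with columns `sample` (1-based index) and
#'   `label`, or `NULL`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          condition = c("rest", "task"), events = NULL) {
  condition <- match.arg(condition)
  stopifnot(is.matrix(data), is.numeric(data), is.numeric(fs), fs > 0)
  if (is.null(channel_names))
    stop("channel names are required")
  if (length(channel_names) != nrow(data))
    stop("channel_names must match the number of data rows")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  scalp <- intersect(channel_names, montage_channels())
  if (length(scalp) != 30)
    stop("recording must contain the 30 scalp channels of the montage")
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = character(0),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "label") %in% names(events)))
  if (nrow(events) && (any(events$sample < 1) ||
                       any(events$sample > ncol(data))))
    stop("event sample indices must lie within the recording")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 condition = condition, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, nrow(x$events)))
  invisible(x)
}

#' Names of the scalp (EEG) channels in a recording
#'
#' Channels such as EOG are carried in the data matrix but excluded from all
#' EEG-only computations (referencing, epoch screening, region averages).
#'
#' @param rec an [eeg_recording()].
#' @return character vector of the 30 scalp channel names, in montage order.
#' @export
scalp_channels <- function(rec) {
  intersect(montage_channels(), rec$channel_names)
}

#' Extract the scalp data matrix (channels x samples)
#' @param rec an [eeg_recording()].
#' @return numeric matrix restricted to the 30 scalp channels.
#' @export
scalp_data <- function(rec) {
  rec$data[scalp_channels(rec), , drop = FALSE]
}

# replace the data matrix, preserving metadata
replace_data <- function(rec, data) {
  stopifnot(identical(dim(data), dim(rec$data)))
  rec$data <- data
  rownames(rec$data) <- rec$channel_names
  rec
}

# samples (1-based) of events with a given label
event_samples <- function(rec, label) {
  rec$events$sample[rec$events$label == label]
}
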