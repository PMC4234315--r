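#' Continuous multi-channel EEG recording
#'
#' Lightweight container: a channels x samples matrix in microvolts with
#' channel labels, sampling rate, reference label, and start time.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param channel_labels character vector, unique, one per row of `data`.
#' @param sfreq sampling rate in Hz (> 0).
#' @param reference reference electrode label (default "A1", left earlobe).
#' @param start_time recording start in seconds.
#' @return object of class `continuous_recording`.
#' @examples
#' rec <- continuous_recording(matrix(0, 2, 100), c("Cz", "Pz"), 1000)
#' rec
#' @export
continuous_recording <- function(data, channel_labels, sfreq,
                                 reference = "A1", start_time = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (length(channel_labels) == 0) config_error("empty channel list")
  if (nrow(data) != length(channel_labels)) config_error(
    "%d channel labels for %d data rows", length(channel_labels), nrow(data))
  if (anyDuplicated(channel_labels)) config_error(
    "duplicate channel labels: %s",
    paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.numeric(sfreq) || sfreq <= 0) config_error("sfreq must be > 0")
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 sfreq = sfreq, reference = reference,
                 start_time = start_time),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d ch x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              x$reference))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `continuous_recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Event markers aligned to a recording
#'
#' Builds a validated, time-sorted event table. Sample indices are 0-based
#' (sample 0 is the first sample of the recording).
#'
#' @param sample_index integer vector, 0-based.
#' @param label event label (e.g. "probe").
#' @param condition workload condition: view/easy/hard.
#' @param scheme control scheme: DC/PRC.
#' @param trial_id integer trial identifier.
#' @param n_samples optional recording length for range validation.
#' @return data.frame of class `event_markers`, sorted by `sample_index`.
#' @export
event_markers <- function(sample_index, label = "probe", condition = NA,
                          scheme = NA, trial_id = NA, n_samples = NULL) {
  ev <- data.frame(sample_index = as.integer(sample_index),
                   label = label, condition = condition,
                   scheme = scheme, trial_id = trial_id,
                   stringsAsFactors = FALSE)
  if (any(ev$sample_index < 0)) data_error(
    "negative sample index in row(s) %s",
    paste(which(ev$sample_index < 0), collapse = ", "))
  if (!is.null(n_samples) && any(ev$sample_index >= n_samples)) data_error(
    "sample index out of range (>= %d) in row(s) %s", n_samples,
    paste(which(ev$sample_index >= n_samples), collapse = ", "))
  ev <- ev[order(ev$sample_index), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_markers", "data.frame")
  ev
}
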