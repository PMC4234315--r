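#' Write a recording to the native container or EDF
#'
#' The native container is a sidecar JSON header (`<stem>.json`) plus either
#' a float32 little-endian binary (`<stem>.dat`, format "bin") or a plain
#' CSV (`<stem>.csv`, format "csv", intended for tiny text fixtures). EDF's
#' 16-bit quantization makes exactness tests awkward, hence the native
#' default; EDF is provided for interoperability.
#'
#' @param rec a `continuous_recording`.
#' @param stem path without extension (for EDF, `.edf` is appended).
#' @param format one of "bin", "csv", "edf".
#' @return the main data file path, invisibly.
#' @export
write_recording <- function(rec, stem, format = c("bin", "csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "continuous_recording"))
  if (format == "edf") return(write_edf(rec, paste0(stem, ".edf")))
  hdr <- list(channel_labels = rec$channel_labels, sfreq = rec$sfreq,
              reference = rec$reference, start_time = rec$start_time,
              n_samples = ncol(rec$data), format = format)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (format == "bin") {
    con <- file(paste0(stem, ".dat"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
    invisible(paste0(stem, ".dat"))
  } else {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_labels
    write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
    invisible(paste0(stem, ".csv"))
  }
}

#' Read a recording written by [write_recording()] (or an EDF file)
#'
#' @param path for the native container, the `.json` header path (or the
#'   stem); for EDF, the `.edf` path. The format is inferred from the
#'   extension unless given.
#' @param format "auto", "bin", "csv", or "edf".
#' @return a `continuous_recording`.
#' @export
read_recording <- function(path, format = "auto") {
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", json = "native", dat = "native",
                     csv = "native", "native")
  }
  if (format == "edf") return(read_edf(path))
  stem <- sub("\\.(json|dat|csv)$", "", path)
  hpath <- paste0(stem, ".json")
  if (!file.exists(hpath)) data_error("missing container header: %s", hpath)
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  need <- c("channel_labels", "sfreq", "n_samples", "format")
  if (!all(need %in% names(hdr))) data_error(
    "corrupt container header %s (missing %s)", hpath,
    paste(setdiff(need, names(hdr)), collapse = ", "))
  nch <- length(hdr$channel_labels)
  if (nch == 0) config_error("empty channel list in %s", hpath)
  if (hdr$format == "bin") {
    dpath <- paste0(stem, ".dat")
    con <- file(dpath, "rb")
    on.exit(close(con))
    v <- readBin(con, "numeric", n = nch * hdr$n_samples + 1, size = 4,
                 endian = "little")
    if (length(v) != nch * hdr$n_samples) data_error(
      "container %s has %d values, header promises %d", dpath, length(v),
      nch * hdr$n_samples)
    dat <- t(matrix(v, ncol = nch))
  } else {
    df <- read.csv(paste0(stem, ".csv"), check.names = FALSE)
    if (nrow(df) != hdr$n_samples) data_error(
      "container %s.csv has %d rows, header promises %d", stem, nrow(df),
      hdr$n_samples)
    dat <- t(as.matrix(df[, hdr$channel_labels, drop = FALSE]))
  }
  continuous_recording(dat, hdr$channel_labels, as.numeric(hdr$sfreq),
                       reference = hdr$reference %||% "A1",
                       start_time = hdr$start_time %||% 0)
}

#' Write probe event markers to CSV
#'
#' Columns: sample_index (0-based), time_s, label, condition, scheme,
#' trial_id. Byte-deterministic given identical inputs.
#'
#' @param events an `event_markers` data.frame.
#' @param path output CSV path.
#' @param sfreq sampling rate used for the `time_s` column.
#' @export
write_events <- function(events, path, sfreq) {
  df <- as.data.frame(events)
  df <- df[order(df$sample_index), , drop = FALSE]
  out <- data.frame(sample_index = df$sample_index,
                    time_s = df$sample_index / sfreq,
                    label = df$label, condition = df$condition,
                    scheme = df$scheme, trial_id = df$trial_id)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read probe event markers from CSV
#'
#' Events are returned sorted by sample index and validated against an
#' optional recording length; an out-of-range index is an error naming the
#' offending row.
#'
#' @param path CSV path with columns sample_index, label, condition, scheme,
#'   trial_id.
#' @param n_samples optional recording length for validation.
#' @return an `event_markers` data.frame.
#' @export
read_events <- function(path, n_samples = NULL) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_index", "label", "condition", "scheme", "trial_id")
  if (!all(need %in% names(df))) data_error(
    "events file %s lacks column(s): %s", path,
    paste(setdiff(need, names(df)), collapse = ", "))
  event_markers(df$sample_index, df$label, df$condition, df$scheme,
                df$trial_id, n_samples = n_samples)
}

#' Write / read behavioral trial logs
#'
#' One row per task trial: participant, scheme, condition, trial_id,
#' success (logical), duration_s.
#'
#' @param log trial-log data.frame.
#' @param path CSV path.
#' @rdname trial_log_io
#' @export
write_trial_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_log_io
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "scheme", "condition", "trial_id", "success",
            "duration_s")
  if (!all(need %in% names(df))) data_error(
    "trial log %s lacks column(s): %s", path,
    paste(setdiff(need, names(df)), collapse = ", "))
  df$success <- as.logical(df$success)
  df
}

#' Write an amplitude table to CSV
#'
#' Long format, one row per participant x scheme x condition x component x
#' electrode with the window-mean amplitude in microvolts. Rows are sorted
#' deterministically; duplicate keys are an error.
#'
#' @param records data.frame with columns participant, scheme, condition,
#'   component, electrode, amplitude (and optionally n_epochs).
#' @param path output CSV path.
#' @export
write_amplitude_table <- function(records, path) {
  need <- c("participant", "scheme", "condition", "component", "electrode",
            "amplitude")
  if (nrow(records) > 0 && !all(need %in% names(records))) data_error(
    "amplitude records lack column(s): %s",
    paste(setdiff(need, names(records)), collapse = ", "))
  if (nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(need)), need))
    write.csv(records, path, row.names = FALSE)
    return(invisible(path))
  }
  key <- do.call(paste, c(records[c("participant", "scheme", "condition",
                                    "component", "electrode")], sep = "|"))
  if (anyDuplicated(key)) data_error(
    "duplicate amplitude-table key(s): %s",
    paste(unique(key[duplicated(key)]), collapse = "; "))
  ord <- order(records$participant,
               match(records$scheme, SCHEME_LEVELS),
               match(records$condition, WORKLOAD_LEVELS),
               match(records$component, COMPONENT_NAMES),
               records$electrode)
  write.csv(records[ord, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read an amplitude table written by [write_amplitude_table()]
#' @param path CSV path.
#' @return data.frame of amplitude records.
#' @export
read_amplitude_table <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write / read questionnaire responses
#'
#' One row per participant x scheme with columns q1..q7 holding raw 1-5
#' Likert responses (reverse scoring is applied at scoring time, not here).
#'
#' @param responses data.frame with participant, scheme, q1..q7.
#' @param path CSV path.
#' @rdname questionnaire_io
#' @export
write_questionnaire <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname questionnaire_io
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "scheme", paste0("q", 1:7))
  if (!all(need %in% names(df))) data_error(
    "questionnaire %s lacks column(s): %s", path,
    paste(setdiff(need, names(df)), collapse = ", "))
  df
}
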