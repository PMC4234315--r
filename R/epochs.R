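#' Extract epochs around probe events
#'
#' Each epoch spans `[tmin, tmax]` ms relative to probe onset, inclusive of
#' both endpoints at the native rate (at 1000 Hz and -100..1000 ms: 1101
#' samples). Events whose window would run past either end of the recording
#' are dropped and logged, not padded.
#'
#' @param rec a `continuous_recording` (typically already bandpassed).
#' @param events an `event_markers` table (0-based sample indices).
#' @param tmin,tmax epoch window in ms relative to onset.
#' @param participant participant id attached to the epoch keys.
#' @return object of class `epoch_set`: `epochs` (n_epochs x channels x
#'   samples array, microvolts), `times` (ms axis), `keys` (data.frame:
#'   participant, scheme, condition, trial_id, probe_index i.e. event row),
#'   `artifact` (logical), `artifact_reason` (character), `dropped`
#'   (data.frame of dropped events), `sfreq`, `channel_labels`.
#' @export
extract_epochs <- function(rec, events, tmin = -100, tmax = 1000,
                           participant = NA_integer_) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (tmin >= tmax) config_error("tmin must be < tmax")
  sf <- rec$sfreq
  s0 <- round(tmin * sf / 1000)
  s1 <- round(tmax * sf / 1000)
  times <- seq(s0, s1) * 1000 / sf
  nsamp <- length(times)
  n <- n_samples(rec)
  ev <- as.data.frame(events)
  first <- ev$sample_index + s0        # 0-based
  last <- ev$sample_index + s1
  ok <- first >= 0 & last <= n - 1
  dropped <- ev[!ok, , drop = FALSE]
  ev <- ev[ok, , drop = FALSE]
  nch <- nrow(rec$data)
  epochs <- array(0, dim = c(nrow(ev), nch, nsamp),
                  dimnames = list(NULL, rec$channel_labels, NULL))
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$sample_index[i] + s0 + 1L):(ev$sample_index[i] + s1 + 1L)
    epochs[i, , ] <- rec$data[, idx]
  }
  keys <- data.frame(participant = participant,
                     scheme = ev$scheme, condition = ev$condition,
                     trial_id = ev$trial_id,
                     probe_index = seq_len(nrow(ev)),
                     stringsAsFactors = FALSE)
  structure(list(epochs = epochs, times = times, keys = keys,
                 artifact = rep(FALSE, nrow(ev)),
                 artifact_reason = rep(NA_character_, nrow(ev)),
                 dropped = dropped, sfreq = sf,
                 channel_labels = rec$channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples (%g..%g ms), %d flagged, %d dropped\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              min(x$times), max(x$times), sum(x$artifact), nrow(x$dropped)))
  invisible(x)
}

#' Baseline-correct epochs on the pre-stimulus interval
#'
#' Subtracts, per epoch and channel, the mean over `[-100, 0)` ms (the
#' onset sample is excluded). Errors if the pre-stimulus interval is not
#' covered by the epoch window.
#'
#' @param epochs an `epoch_set`.
#' @param baseline two-element ms interval, end-exclusive.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times >= baseline[1] & epochs$times < baseline[2]
  if (!any(sel)) data_error(
    "epoch window [%g, %g] ms has no samples in the baseline [%g, %g) ms",
    min(epochs$times), max(epochs$times), baseline[1], baseline[2])
  # mean over baseline samples per epoch x channel
  base <- apply(epochs$epochs[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$epochs <- sweep(epochs$epochs, c(1, 2), base, FUN = "-")
  epochs$baseline <- baseline
  epochs
}

#' Flag artifact epochs by threshold rules
#'
#' The reference analysis removed blink/movement epochs by visual
#' inspection; the automated proxy flags an epoch when any EOG channel
#' (label containing "EOG") exceeds `eog_p2p` microvolts peak-to-peak, or
#' any EEG channel exceeds `eeg_abs` microvolts in absolute value. Reasons
#' are recorded ("eog_p2p", "eeg_abs", or both comma-joined). Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param eog_p2p EOG peak-to-peak threshold, microvolts.
#' @param eeg_abs EEG absolute threshold, microvolts.
#' @return the `epoch_set` with `artifact`/`artifact_reason` set.
#' @export
reject_artifacts <- function(epochs, eog_p2p = 100, eeg_abs = 75) {
  stopifnot(inherits(epochs, "epoch_set"))
  is_eog <- grepl("EOG", epochs$channel_labels, ignore.case = TRUE)
  if (!any(is_eog)) warning("no EOG channels found; applying EEG criterion only")
  ne <- dim(epochs$epochs)[1]
  art <- logical(ne)
  reason <- rep(NA_character_, ne)
  for (i in seq_len(ne)) {
    r <- character(0)
    if (any(is_eog)) {
      x <- epochs$epochs[i, is_eog, , drop = FALSE]
      p2p <- apply(x, 2, function(ch) diff(range(ch)))
      if (any(p2p > eog_p2p)) r <- c(r, "eog_p2p")
    }
    if (any(!is_eog)) {
      x <- epochs$epochs[i, !is_eog, , drop = FALSE]
      if (max(abs(x)) > eeg_abs) r <- c(r, "eeg_abs")
    }
    if (length(r)) {
      art[i] <- TRUE
      reason[i] <- paste(r, collapse = ",")
    }
  }
  epochs$artifact <- art
  epochs$artifact_reason <- reason
  epochs
}

#' Clean-epoch counts per scheme x condition cell
#'
#' @param epochs an `epoch_set` (after [reject_artifacts()]).
#' @return data.frame: scheme, condition, n_clean.
#' @export
clean_counts <- function(epochs) {
  k <- epochs$keys[!epochs$artifact, , drop = FALSE]
  if (nrow(k) == 0) {
    return(data.frame(scheme = character(0), condition = character(0),
                      n_clean = integer(0)))
  }
  ag <- aggregate(list(n_clean = rep(1L, nrow(k))),
                  by = list(scheme = k$scheme, condition = k$condition), sum)
  ag
}

#' Apply the minimum-trials inclusion rule
#'
#' A participant is included iff every scheme x condition cell has at least
#' `min_trials` clean epochs. Cells missing from `counts` are treated as 0
#' with a warning.
#'
#' @param counts data.frame with scheme, condition, n_clean (one
#'   participant), or a named list of such per participant.
#' @param min_trials inclusion floor (default 30).
#' @param schemes,conditions the full cell grid to enforce.
#' @return data.frame of class `inclusion_decision`: scheme, condition,
#'   n_clean, plus attributes `included` (logical) and `min_trials`.
#' @export
enforce_min_trials <- function(counts, min_trials = 30,
                               schemes = SCHEME_LEVELS,
                               conditions = WORKLOAD_LEVELS) {
  grid <- expand.grid(scheme = schemes, condition = conditions,
                      stringsAsFactors = FALSE)
  grid$n_clean <- 0L
  for (i in seq_len(nrow(grid))) {
    m <- counts$scheme == grid$scheme[i] & counts$condition == grid$condition[i]
    if (any(m)) grid$n_clean[i] <- sum(counts$n_clean[m])
  }
  missing_cells <- nrow(grid) - sum(
    paste(grid$scheme, grid$condition) %in% paste(counts$scheme, counts$condition))
  if (missing_cells > 0) warning(sprintf(
    "%d scheme x condition cell(s) missing from counts; treated as 0",
    missing_cells))
  attr(grid, "included") <- all(grid$n_clean >= min_trials)
  attr(grid, "min_trials") <- min_trials
  class(grid) <- c("inclusion_decision", "data.frame")
  grid
}
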