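#' Default component scoring windows
#'
#' The fixed printed windows: N100 105-120 ms (Cz, negative), P200
#' 190-205 ms (Fz/Cz/Pz, positive), P300 295-330 ms (Pz, positive), LPP
#' 570-590 ms (Pz, positive). Amplitudes are window means with both
#' endpoints inclusive. Electrodes listed per component follow the scoring
#' montage of the reference analysis; `amplitude_table()` scores every
#' component at all three midline sites regardless, and the statistics
#' layer selects cells.
#'
#' @return data.frame of class `component_windows`: component, start_ms,
#'   end_ms, polarity, electrodes (comma-joined).
#' @export
default_windows <- function() {
  out <- data.frame(
    component = COMPONENT_NAMES,
    start_ms = c(105, 190, 295, 570),
    end_ms = c(120, 205, 330, 590),
    polarity = c("negative", "positive", "positive", "positive"),
    electrodes = c("Cz", "Fz,Cz,Pz", "Pz", "Pz"),
    stringsAsFactors = FALSE)
  class(out) <- c("component_windows", "data.frame")
  out
}

#' Search ranges used by window recentering
#' @noRd
peak_search_ranges <- function() {
  data.frame(
    component = COMPONENT_NAMES,
    lo = c(80, 150, 250, 450), hi = c(160, 250, 450, 800),
    electrode = c("Cz", "Cz", "Pz", "Pz"),
    polarity = c("negative", "positive", "positive", "positive"),
    stringsAsFactors = FALSE)
}

#' Average clean epochs of one participant x scheme x condition cell
#'
#' Pointwise arithmetic mean over clean (unflagged) epochs. Refuses cells
#' below the inclusion floor unless `min_trials` is lowered.
#'
#' @param epochs an `epoch_set`.
#' @param scheme,condition cell selectors.
#' @param min_trials minimum clean epochs required (default 30).
#' @return object of class `erp_average`: `data` (channels x samples),
#'   `times`, `n_epochs`, `participant`, `scheme`, `condition`,
#'   `channel_labels`.
#' @export
average_epochs <- function(epochs, scheme, condition, min_trials = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- !epochs$artifact & epochs$keys$scheme == scheme &
    epochs$keys$condition == condition
  ne <- sum(sel)
  if (ne < min_trials) data_error(
    "cell %s x %s has %d clean epochs (< %d); see the inclusion decision",
    scheme, condition, ne, min_trials)
  dat <- apply(epochs$epochs[sel, , , drop = FALSE], c(2, 3), mean)
  structure(list(data = dat, times = epochs$times, n_epochs = ne,
                 participant = epochs$keys$participant[which(sel)[1]],
                 scheme = scheme, condition = condition,
                 channel_labels = epochs$channel_labels),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average> p=%s %s/%s, %d epochs, %d ch x %d samples\n",
              as.character(x$participant), x$scheme, x$condition, x$n_epochs,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Grand average across participant-level ERP averages
#'
#' Unweighted mean: each participant contributes equally regardless of
#' epoch count. All inputs must share the times axis and channel set.
#'
#' @param avgs list of `erp_average` objects.
#' @return an `erp_average` with `participant = "grand"` and `n_epochs` =
#'   number of participants averaged.
#' @export
grand_average <- function(avgs) {
  if (length(avgs) < 2) data_error("grand average needs >= 2 participants")
  t0 <- avgs[[1]]$times
  ch0 <- avgs[[1]]$channel_labels
  for (a in avgs) {
    if (!isTRUE(all.equal(a$times, t0)) ||
        !identical(a$channel_labels, ch0)) {
      data_error("mismatched times axis or channels across participants")
    }
  }
  dat <- Reduce(`+`, lapply(avgs, `[[`, "data")) / length(avgs)
  structure(list(data = dat, times = t0, n_epochs = length(avgs),
                 participant = "grand", scheme = avgs[[1]]$scheme,
                 condition = avgs[[1]]$condition, channel_labels = ch0),
            class = "erp_average")
}

#' Locate a component peak in a grand average
#'
#' Latency of the extremum of the stated polarity within the search range;
#' ties broken by the earliest latency. A flat signal in the range returns
#' the range start flagged `"no distinct peak"`.
#'
#' @param grand an `erp_average`.
#' @param electrode channel label to search.
#' @param search_range two-element ms range (within the epoch).
#' @param polarity "positive" or "negative".
#' @return list: `latency_ms`, `amplitude`, `flag` (NA or explanation).
#' @export
find_peak <- function(grand, electrode, search_range, polarity = "positive") {
  stopifnot(inherits(grand, "erp_average"))
  if (!electrode %in% grand$channel_labels) data_error(
    "electrode %s not present; available: %s", electrode,
    paste(grand$channel_labels, collapse = ", "))
  sel <- grand$times >= search_range[1] & grand$times <= search_range[2]
  if (!any(sel)) config_error("search range outside the epoch")
  x <- grand$data[match(electrode, grand$channel_labels), sel]
  tt <- grand$times[sel]
  if (polarity == "negative") x <- -x
  flag <- NA_character_
  if (diff(range(x)) < 1e-12) {
    return(list(latency_ms = tt[1], amplitude = grand$data[
      match(electrode, grand$channel_labels), sel][1],
      flag = "no distinct peak"))
  }
  i <- which.max(x)   # which.max returns the earliest maximum: tie-break rule
  list(latency_ms = tt[i],
       amplitude = grand$data[match(electrode, grand$channel_labels), sel][i],
       flag = flag)
}

#' Window-mean amplitude of an ERP average
#'
#' Arithmetic mean of the samples from `start_ms` to `end_ms`, both
#' endpoints inclusive (sub-ms endpoints are rounded to the nearest
#' sample), at the stated electrode.
#'
#' @param erp an `erp_average`.
#' @param electrode channel label.
#' @param start_ms,end_ms window bounds in ms.
#' @return the mean amplitude in microvolts (scalar).
#' @export
window_mean <- function(erp, electrode, start_ms, end_ms) {
  stopifnot(inherits(erp, "erp_average"))
  if (!electrode %in% erp$channel_labels) data_error(
    "electrode %s not present; available: %s", electrode,
    paste(erp$channel_labels, collapse = ", "))
  if (start_ms >= end_ms) config_error("window start must be < end")
  if (start_ms < min(erp$times) || end_ms > max(erp$times)) config_error(
    "window [%g, %g] ms outside the epoch [%g, %g] ms", start_ms, end_ms,
    min(erp$times), max(erp$times))
  sel <- erp$times >= start_ms - 1e-9 & erp$times <= end_ms + 1e-9
  mean(erp$data[match(electrode, erp$channel_labels), sel])
}

#' Recenter scoring windows on grand-average peaks
#'
#' Keeps each printed window's width but centers it on the grand-average
#' peak found in the component's standard search range (N100 80-160 ms
#' negative at Cz; P200 150-250 positive at Cz; P300 250-450 positive at
#' Pz; LPP 450-800 positive at Pz).
#'
#' @param grand grand-average `erp_average` (typically across conditions).
#' @param windows a `component_windows` table (widths are preserved).
#' @return recentered `component_windows`.
#' @export
recenter_windows <- function(grand, windows = default_windows()) {
  sr <- peak_search_ranges()
  for (i in seq_len(nrow(windows))) {
    j <- match(windows$component[i], sr$component)
    if (is.na(j)) next
    pk <- find_peak(grand, sr$electrode[j], c(sr$lo[j], sr$hi[j]),
                    sr$polarity[j])
    w <- windows$end_ms[i] - windows$start_ms[i]
    windows$start_ms[i] <- pk$latency_ms - w / 2
    windows$end_ms[i] <- pk$latency_ms + w / 2
  }
  windows
}

#' Build the long-format amplitude table
#'
#' One row per participant x scheme x condition x component x electrode:
#' the window-mean amplitude of that participant's cell average.
#'
#' @param avgs list of participant-level `erp_average` objects (all cells).
#' @param windows a `component_windows` table.
#' @param electrodes electrodes to score (default Fz, Cz, Pz intersected
#'   with available channels).
#' @return data.frame of amplitude records with n_epochs per cell.
#' @export
amplitude_table <- function(avgs, windows = default_windows(),
                            electrodes = c("Fz", "Cz", "Pz")) {
  rows <- list()
  for (a in avgs) {
    els <- intersect(electrodes, a$channel_labels)
    for (i in seq_len(nrow(windows))) {
      for (el in els) {
        rows[[length(rows) + 1]] <- data.frame(
          participant = a$participant, scheme = a$scheme,
          condition = a$condition, component = windows$component[i],
          electrode = el,
          amplitude = window_mean(a, el, windows$start_ms[i],
                                  windows$end_ms[i]),
          n_epochs = a$n_epochs, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
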