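#' Place auditory probes inside trials
#'
#' Probes are task-irrelevant novel sounds presented during the trials;
#' every epoch of the ERP analysis is locked to one. Two count regimes:
#'
#' * `"interval"` (default): probe times advance through the trial's
#'   active window by successive inter-stimulus intervals drawn uniformly
#'   from `[probe_isi_min, probe_isi_max]` seconds, capped at `probe_max`
#'   probes. Long (hard/view) trials thus carry about 3 probes and short
#'   (easy) trials 0-1, all counts within the 0-3 range.
#' * `"uniform"`: the per-trial count is drawn uniformly from
#'   `{probe_min, ..., probe_max}` and times uniformly inside the window
#'   subject to `min_probe_separation`; if the window cannot fit the drawn
#'   count, the count is reduced and the reduction logged.
#'
#' The active window is the movement interval (go cue to trial end), or
#' planning + movement when `config$probes_in_planning` is set; a 0.2 s
#' guard margin is kept at both ends.
#'
#' @param trial_log output of [simulate_behavior()].
#' @param config a [session_config()].
#' @param seed integer seed.
#' @param model count regime override (defaults to
#'   `config$probe_count_model`).
#' @return data.frame of probe events: participant, scheme, condition,
#'   trial_id, probe_index, time_in_trial_s (relative to trial start, i.e.
#'   planning onset). Attribute "reductions" records uniform-model trials
#'   whose count was reduced.
#' @export
place_probes <- function(trial_log, config, seed = config$seed,
                         model = config$probe_count_model) {
  margin <- 0.2
  sep <- config$min_probe_separation
  withr::with_seed(seed + 1L, {
    rows <- vector("list", nrow(trial_log))
    reductions <- list()
    for (i in seq_len(nrow(trial_log))) {
      tr <- trial_log[i, ]
      if (tr$duration_s <= 0) config_error(
        "trial %d (%s/%s) has non-positive duration", tr$trial_id, tr$scheme,
        tr$condition)
      t0 <- if (isTRUE(config$probes_in_planning)) 0 else config$planning_delay
      t1 <- config$planning_delay + tr$duration_s
      lo <- t0 + margin
      hi <- t1 - margin
      if (model == "interval") {
        times <- numeric(0)
        t <- lo + runif(1, 0.5, 2)
        while (t <= hi && length(times) < config$probe_max) {
          times <- c(times, t)
          t <- t + runif(1, config$probe_isi_min, config$probe_isi_max)
        }
        k <- length(times)
      } else {
        k <- sample.int(config$probe_max - config$probe_min + 1L, 1L) - 1L +
          config$probe_min
        kmax <- if (hi <= lo) 0L else as.integer(floor((hi - lo) / sep)) + 1L
        if (k > kmax) {
          reductions[[length(reductions) + 1]] <- data.frame(
            participant = tr$participant, scheme = tr$scheme,
            condition = tr$condition, trial_id = tr$trial_id,
            drawn = k, placed = kmax)
          k <- kmax
        }
        if (k > 0) {
          # uniform times with pairwise separation >= sep: draw in the
          # shrunk interval and re-expand (order statistics construction)
          u <- sort(runif(k, lo, hi - (k - 1) * sep))
          times <- u + (seq_len(k) - 1) * sep
        } else {
          times <- numeric(0)
        }
      }
      if (k == 0) next
      rows[[i]] <- data.frame(
        participant = tr$participant, scheme = tr$scheme,
        condition = tr$condition, trial_id = tr$trial_id,
        probe_index = seq_len(k), time_in_trial_s = times,
        stringsAsFactors = FALSE)
    }
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- if (!any(keep)) {
    data.frame(participant = integer(0), scheme = character(0),
               condition = character(0), trial_id = integer(0),
               probe_index = integer(0), time_in_trial_s = numeric(0))
  } else {
    do.call(rbind, rows[keep])
  }
  rownames(out) <- NULL
  attr(out, "reductions") <- if (length(reductions)) do.call(rbind, reductions)
                             else NULL
  out
}
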