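#' Preprocess one rendered session to cell averages
#'
#' filter -> epoch -> baseline -> artifact flags -> per-cell averages.
#' Returns cell averages plus clean counts; the continuous data can then
#' be discarded (the full-cohort driver processes sessions sequentially
#' for memory economy).
#'
#' @param sess a [render_session_eeg()] result.
#' @param participant participant id for the epoch keys.
#' @param low,high filter band, Hz.
#' @param tmin,tmax epoch window, ms.
#' @param eog_p2p,eeg_abs artifact thresholds, microvolts.
#' @param min_trials inclusion floor passed to averaging (0 = never refuse
#'   here; inclusion is decided at the cohort level).
#' @return list: `averages` (list of `erp_average` per condition),
#'   `counts` (clean counts), `n_events`, `n_dropped`, `n_flagged`.
#' @export
preprocess_session <- function(sess, participant, low = 1, high = 15,
                               tmin = -100, tmax = 1000,
                               eog_p2p = 100, eeg_abs = 75,
                               min_trials = 1) {
  rec <- bandpass_filter(sess$recording, low, high)
  eps <- extract_epochs(rec, sess$events, tmin, tmax,
                        participant = participant)
  eps <- baseline_correct(eps)
  eps <- reject_artifacts(eps, eog_p2p, eeg_abs)
  counts <- clean_counts(eps)
  avgs <- list()
  for (cond in unique(eps$keys$condition)) {
    ncell <- sum(!eps$artifact & eps$keys$condition == cond)
    if (ncell >= max(1, min_trials)) {
      avgs[[cond]] <- average_epochs(eps, eps$keys$scheme[1], cond,
                                     min_trials = max(1, min_trials))
    }
  }
  list(averages = avgs, counts = counts,
       n_events = nrow(sess$events),
       n_dropped = nrow(eps$dropped), n_flagged = sum(eps$artifact))
}

#' Run the full pipeline: simulate -> preprocess -> ERP -> statistics
#'
#' Generates a seeded synthetic cohort, preprocesses every participant x
#' scheme session (sequentially; continuous EEG is discarded once cell
#' averages exist), applies the >= `min_trials` inclusion rule, scores
#' window amplitudes, and computes the statistical report: omnibus
#' workload x scheme ANOVAs per component x electrode of the scoring
#' montage, Tukey-adjusted post-hoc workload contrasts, paired DC-vs-PRC
#' contrasts (easy and hard) on components with significant omnibus
#' workload effects, behavioral and self-report summaries and contrasts,
#' and per-scheme correlation matrices.
#'
#' @param config a [session_config()].
#' @param components,behavior generator tables.
#' @param out_dir optional output directory; when given, writes
#'   amplitude_table.csv, trial_log.csv, questionnaires.csv,
#'   inclusion.csv, report.json, grand_averages.csv.
#' @param min_trials inclusion floor.
#' @param recenter logical: recenter scoring windows on grand-average
#'   peaks (width-preserving) instead of the fixed printed windows.
#' @param verbose logical: stage logs to stderr.
#' @return list of class `probeerp_report`.
#' @export
run_all <- function(config = session_config(),
                    components = default_components(),
                    behavior = default_behavior(),
                    out_dir = NULL, min_trials = 30, recenter = FALSE,
                    verbose = FALSE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))
  log_msg("simulate: n=%d seed=%d", config$n_participants, config$seed)
  sim <- simulate_session(config, components, behavior, render = FALSE)

  all_avgs <- list()
  inclusion <- list()
  for (p in seq_len(config$n_participants)) {
    counts_p <- NULL
    avgs_p <- list()
    for (sc in config$schemes) {
      sess <- render_session_eeg(p, sc, sim$schedule, sim$trial_log,
                                 sim$probes, components, config,
                                 pscale = sim$pscales[p, ])
      pp <- preprocess_session(sess, p, min_trials = 1)
      counts_p <- rbind(counts_p, pp$counts)
      avgs_p[[sc]] <- pp$averages
      log_msg("p%02d %s: %d events, %d flagged, %d dropped", p, sc,
              pp$n_events, pp$n_flagged, pp$n_dropped)
      rm(sess)
    }
    dec <- enforce_min_trials(counts_p, min_trials,
                              schemes = config$schemes,
                              conditions = config$conditions)
    inclusion[[p]] <- data.frame(
      participant = p, included = attr(dec, "included"),
      min_clean = min(dec$n_clean), stringsAsFactors = FALSE)
    if (attr(dec, "included")) all_avgs[[p]] <- avgs_p
  }
  inclusion <- do.call(rbind, inclusion)
  included <- which(inclusion$included)
  log_msg("inclusion: %d of %d participants", length(included),
          config$n_participants)
  if (length(included) < 2) data_error(
    "fewer than 2 participants included; cannot run cohort statistics")

  flat <- list()
  for (p in included) for (sc in config$schemes) {
    for (cond in names(all_avgs[[p]][[sc]])) {
      flat[[length(flat) + 1]] <- all_avgs[[p]][[sc]][[cond]]
    }
  }
  windows <- default_windows()
  if (recenter) {
    grand_all <- grand_average(flat)
    windows <- recenter_windows(grand_all, windows)
  }
  amp <- amplitude_table(flat, windows)

  montage <- scoring_montage()
  anovas <- list()
  posthocs <- list()
  for (i in seq_len(nrow(montage))) {
    comp <- montage$component[i]; el <- montage$electrode[i]
    slice <- amp[amp$component == comp & amp$electrode == el, ]
    if (nrow(slice) == 0) next   # electrode not in this montage
    an <- rm_anova(slice, conditions = config$conditions,
                   schemes = config$schemes)
    key <- paste(comp, el, sep = "_")
    anovas[[key]] <- an
    posthocs[[key]] <- posthoc_workload(
      slice, conditions = config$conditions,
      omnibus_p = an$p[an$effect == "workload"])
  }

  # scheme contrasts on components with significant omnibus workload effects
  scheme_tests <- list()
  for (key in names(anovas)) {
    an <- anovas[[key]]
    if (an$p[an$effect == "workload"] >= 0.05) next
    comp <- sub("_[^_]+$", "", key); el <- sub("^.*_", "", key)
    for (cond in intersect(c("easy", "hard"), config$conditions)) {
      slice <- amp[amp$component == comp & amp$electrode == el &
                     amp$condition == cond, ]
      wide <- split(slice, slice$scheme)
      x <- wide[[config$schemes[2]]]
      y <- wide[[config$schemes[1]]]
      x <- x$amplitude[order(x$participant)]
      y <- y$amplitude[order(y$participant)]
      tt <- paired_t(x, y)
      scheme_tests[[paste(key, cond, sep = "_")]] <- data.frame(
        component = comp, electrode = el, condition = cond,
        contrast = paste(config$schemes[2], "-", config$schemes[1]),
        t = tt$t, df = tt$df, p = tt$p,
        mean_difference = tt$mean_difference, stringsAsFactors = FALSE)
    }
  }
  scheme_tests <- if (length(scheme_tests)) do.call(rbind, scheme_tests)
                  else NULL

  bh <- behavior_summary(sim$trial_log[sim$trial_log$participant %in%
                                         included, ], by_participant = TRUE)
  behavior_tests <- list()
  for (cond in intersect(c("easy", "hard"), config$conditions)) {
    pp <- bh$per_participant[bh$per_participant$condition == cond, ]
    w <- split(pp, pp$scheme)
    if (length(w) == 2) {
      common <- intersect(w[[1]]$participant, w[[2]]$participant)
      a <- w[[config$schemes[1]]]; b <- w[[config$schemes[2]]]
      for (meas in c("percent_completed", "mean_time")) {
        x <- a[[meas]][match(common, a$participant)]
        y <- b[[meas]][match(common, b$participant)]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) >= 2) {
          tt <- paired_t(x[ok], y[ok])
          behavior_tests[[paste(meas, cond, sep = "_")]] <- data.frame(
            measure = meas, condition = cond,
            contrast = paste(config$schemes[1], "-", config$schemes[2]),
            t = tt$t, df = tt$df, p = tt$p,
            mean_difference = tt$mean_difference, stringsAsFactors = FALSE)
        }
      }
    }
  }
  behavior_tests <- if (length(behavior_tests)) do.call(rbind, behavior_tests)
                    else NULL

  qs <- score_questionnaire_table(
    sim$questionnaires[sim$questionnaires$participant %in% included, ])
  qw <- split(qs, qs$scheme)
  quest_test <- NULL
  if (length(qw) == 2) {
    common <- intersect(qw[[1]]$participant, qw[[2]]$participant)
    x <- qw[[config$schemes[1]]]$total[
      match(common, qw[[config$schemes[1]]]$participant)]
    y <- qw[[config$schemes[2]]]$total[
      match(common, qw[[config$schemes[2]]]$participant)]
    tt <- paired_t(x, y)
    quest_test <- data.frame(contrast = paste(config$schemes[1], "-",
                                              config$schemes[2]),
                             t = tt$t, df = tt$df, p = tt$p,
                             mean_difference = tt$mean_difference)
  }

  correlations <- lapply(setNames(nm = config$schemes), function(sc)
    correlation_matrix(amp, bh$per_participant, qs, sc))

  report <- list(config = config, inclusion = inclusion, windows = windows,
                 amplitude_table = amp, anovas = anovas,
                 posthoc = posthocs, scheme_tests = scheme_tests,
                 behavior = bh$cells, behavior_tests = behavior_tests,
                 questionnaire = qs, questionnaire_test = quest_test,
                 correlations = correlations,
                 schedule = sim$schedule, trial_log = sim$trial_log)
  class(report) <- "probeerp_report"
  if (!is.null(out_dir)) write_report(report, out_dir, flat)
  report
}

#' @export
print.probeerp_report <- function(x, ...) {
  cat(sprintf("<probeerp_report> %d/%d participants included\n",
              sum(x$inclusion$included), nrow(x$inclusion)))
  for (key in names(x$anovas)) {
    an <- x$anovas[[key]]
    w <- an[an$effect == "workload", ]
    cat(sprintf("  %s: workload F(%d,%d) = %.2f, p = %.4g\n", key,
                w$df_num, w$df_den, w$F, w$p))
  }
  invisible(x)
}

write_report <- function(report, out_dir, flat_avgs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_amplitude_table(report$amplitude_table, fp("amplitude_table.csv"))
  write_trial_log(report$trial_log, fp("trial_log.csv"))
  write.csv(report$inclusion, fp("inclusion.csv"), row.names = FALSE)
  write.csv(report$questionnaire, fp("questionnaires.csv"),
            row.names = FALSE)
  if (!is.null(flat_avgs)) {
    rows <- lapply(flat_avgs, function(a) {
      df <- as.data.frame(t(a$data))
      names(df) <- a$channel_labels
      cbind(data.frame(participant = a$participant, scheme = a$scheme,
                       condition = a$condition, time_ms = a$times), df)
    })
    write.csv(do.call(rbind, rows), fp("waveforms.csv"), row.names = FALSE)
  }
  json <- list(
    inclusion = report$inclusion,
    windows = report$windows,
    anovas = lapply(report$anovas, as.data.frame),
    posthoc = report$posthoc,
    scheme_tests = report$scheme_tests,
    behavior = report$behavior,
    behavior_tests = report$behavior_tests,
    questionnaire_test = report$questionnaire_test,
    correlations = lapply(report$correlations, function(cm)
      list(r = as.data.frame(cm$r), p = as.data.frame(cm$p), n = cm$n)))
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = 10, dataframe = "columns", na = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' Build packaged test fixtures
#'
#' The tiny fixture is a 2-participant cohort with shortened easy blocks,
#' boosted amplitudes and a lowered inclusion floor so the full pipeline
#' runs end-to-end in seconds; `default` is the full 18-participant
#' configuration.
#'
#' @param size "tiny" or "default".
#' @param seed integer seed.
#' @return list: `config`, `components`, `behavior`, `min_trials`.
#' @export
make_fixtures <- function(size = c("tiny", "default"), seed = 7L) {
  size <- match.arg(size)
  if (size == "tiny") {
    list(config = session_config(
           n_participants = 2, trials_easy_per_dof = 8,
           trials_hard = 16, trials_view = 16, seed = seed,
           channels = c("Cz", "Pz", "VEOG")),
         components = default_components(),
         behavior = default_behavior(), min_trials = 10)
  } else {
    list(config = session_config(seed = seed),
         components = default_components(),
         behavior = default_behavior(), min_trials = 30)
  }
}
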