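#' Two-tailed paired-samples t-test
#'
#' Classical paired t on participant-matched vectors; df = n - 1. The sign
#' convention is `mean_difference = mean(x - y)`. When every difference is
#' zero the statistic is defined as t = 0, p = 1 (rather than NaN).
#'
#' @param x,y numeric vectors of equal length >= 2, paired by participant.
#' @return list of class `paired_test`: t, df, p, mean_difference, n.
#' @examples
#' paired_t(c(3, 4, 6), c(2, 2, 3))  # differences 1, 2, 3: t = 2*sqrt(3)
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) data_error("paired vectors differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) data_error("paired t needs >= 2 complete pairs")
  d <- x - y
  sdd <- sd(d)
  if (sdd < 1e-15) {
    t <- 0; p <- 1
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
  }
  structure(list(t = t, df = n - 1L, p = p, mean_difference = mean(d), n = n),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, mean diff = %.3f\n",
              x$df, x$t, x$p, x$mean_difference))
  invisible(x)
}

#' Pearson product-moment correlation with two-tailed p
#'
#' r from the covariance formula; p from the t transform on n - 2 df. Zero
#' variance in either vector yields an explicit `undefined = TRUE` result
#' instead of a silent NaN.
#'
#' @param x,y numeric vectors, equal length >= 3, finite.
#' @return list of class `correlation`: r, n, df, p, undefined.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) data_error("vectors differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) data_error("correlation needs >= 3 complete pairs")
  sx <- sd(x); sy <- sd(y)
  if (sx < 1e-15 || sy < 1e-15) {
    return(structure(list(r = NA_real_, n = n, df = n - 2L, p = NA_real_,
                          undefined = TRUE), class = "correlation"))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(abs(t), n - 2, lower.tail = FALSE)
  structure(list(r = r, n = n, df = n - 2L, p = p, undefined = FALSE),
            class = "correlation")
}

#' @export
print.correlation <- function(x, ...) {
  if (x$undefined) cat("correlation undefined (zero variance)\n")
  else cat(sprintf("r(%d) = %.3f, p = %.4g\n", x$df, x$r, x$p))
  invisible(x)
}

#' Behavioral summary per scheme x condition
#'
#' Percent of trials successfully completed and the completion-time
#' mean/SD over successful trials only (failures are excluded from the
#' timing summary). View rows (success NA) are skipped. Cells with zero
#' successes carry `mean_time = NA` and `mean_time_undefined = TRUE`.
#'
#' @param trial_log trial log with participant, scheme, condition, success,
#'   duration_s.
#' @param by_participant logical: also return per-participant cell means
#'   (needed for paired scheme comparisons).
#' @return data.frame: scheme, condition, n_trials, percent_completed,
#'   mean_time, sd_time, mean_time_undefined. With `by_participant`, a
#'   list with `cells` and `per_participant`.
#' @export
behavior_summary <- function(trial_log, by_participant = FALSE) {
  log <- trial_log[!is.na(trial_log$success), , drop = FALSE]
  summarize <- function(df, keys) {
    idx <- split(seq_len(nrow(df)), df[keys], drop = TRUE)
    rows <- lapply(idx, function(ii) {
      d <- df[ii, , drop = FALSE]
      succ <- d$duration_s[d$success]
      out <- d[1, keys, drop = FALSE]
      out$n_trials <- nrow(d)
      out$percent_completed <- 100 * sum(d$success) / nrow(d)
      out$mean_time <- if (length(succ)) mean(succ) else NA_real_
      out$sd_time <- if (length(succ) > 1) sd(succ) else NA_real_
      out$mean_time_undefined <- length(succ) == 0
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  cells <- summarize(log, c("scheme", "condition"))
  if (!by_participant) return(cells)
  list(cells = cells,
       per_participant = summarize(log, c("participant", "scheme", "condition")))
}

#' Score a 7-item Likert difficulty questionnaire
#'
#' Items are on a 1-5 scale; items 1, 3 and 7 are reverse scored
#' (x -> 6 - x) so that a high total uniformly reflects high perceived
#' difficulty. Totals therefore lie in [7, 35].
#'
#' @param responses numeric vector of exactly 7 raw responses in 1..5.
#' @return integer total score.
#' @examples
#' score_questionnaire(rep(3, 7))  # 21
#' @export
score_questionnaire <- function(responses) {
  if (length(responses) != 7) data_error(
    "expected 7 responses, got %d", length(responses))
  bad <- which(!responses %in% 1:5)
  if (length(bad)) data_error(
    "response(s) out of 1..5 at item(s): %s", paste(bad, collapse = ", "))
  scored <- responses
  scored[c(1, 3, 7)] <- 6 - scored[c(1, 3, 7)]
  as.integer(sum(scored))
}

#' Score a questionnaire table (one row per participant x scheme)
#'
#' @param responses data.frame with participant, scheme, q1..q7.
#' @return data.frame: participant, scheme, total.
#' @export
score_questionnaire_table <- function(responses) {
  qcols <- paste0("q", 1:7)
  out <- responses[c("participant", "scheme")]
  out$total <- vapply(seq_len(nrow(responses)), function(i) {
    score_questionnaire(as.numeric(responses[i, qcols]))
  }, integer(1))
  out
}

#' Full correlation matrix across ERP, behavior, and self-report measures
#'
#' For each scheme: correlates (over participants) each component's
#' hard-condition amplitude at its scoring electrode, the behavioral
#' summaries (percent completed and mean time, easy and hard), and the
#' questionnaire total. Which amplitude entered each reported correlation
#' was not specified in the reference analysis, so the full matrix is
#' computed.
#'
#' @param amplitudes amplitude table.
#' @param behavior_pp per-participant behavior summary.
#' @param quest_scores scored questionnaire table.
#' @param scheme scheme to slice on.
#' @return list: `r` and `p` matrices, `n` pairs used.
#' @export
correlation_matrix <- function(amplitudes, behavior_pp, quest_scores, scheme) {
  vars <- list()
  subs <- sort(unique(amplitudes$participant))
  amp_slice <- amplitudes[amplitudes$scheme == scheme &
                            amplitudes$condition == "hard", ]
  wtab <- default_windows()
  for (i in seq_len(nrow(wtab))) {
    comp <- wtab$component[i]
    el <- strsplit(wtab$electrodes[i], ",")[[1]][
      length(strsplit(wtab$electrodes[i], ",")[[1]])]
    vars[[paste0(comp, "_", el, "_hard")]] <- vapply(subs, function(p) {
      v <- amp_slice$amplitude[amp_slice$participant == p &
                                 amp_slice$component == comp &
                                 amp_slice$electrode == el]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  }
  for (cond in c("easy", "hard")) {
    bp <- behavior_pp[behavior_pp$scheme == scheme &
                        behavior_pp$condition == cond, ]
    vars[[paste0("pct_", cond)]] <- bp$percent_completed[match(subs, bp$participant)]
    vars[[paste0("time_", cond)]] <- bp$mean_time[match(subs, bp$participant)]
  }
  qs <- quest_scores[quest_scores$scheme == scheme, ]
  vars[["self_report"]] <- qs$total[match(subs, qs$participant)]

  k <- length(vars)
  nm <- names(vars)
  R <- P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { R[i, j] <- 1; next }
    ok <- is.finite(vars[[i]]) & is.finite(vars[[j]])
    if (sum(ok) < 3) next
    ct <- pearson_corr(vars[[i]][ok], vars[[j]][ok])
    if (!ct$undefined) { R[i, j] <- ct$r; P[i, j] <- ct$p }
  }
  list(r = R, p = P, n = length(subs))
}
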