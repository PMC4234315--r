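#' Build the counterbalanced session schedule
#'
#' Scheme order (DC-first vs PRC-first) alternates across participants, and
#' within each scheme-order stratum the view condition is placed first for
#' half the participants and last for the other half ("view, easy, hard"
#' vs "easy, hard, view"); easy always precedes hard. With an even cohort
#' the global view-first fraction is exactly 50%. Counterbalancing is a
#' deterministic design, not a random draw, so the assignment depends only
#' on participant index; with an odd cohort the remainder participant gets
#' view-first and a warning record is attached.
#'
#' @param config a [session_config()].
#' @return data.frame of class `session_schedule`: one row per participant x
#'   scheme x condition with `phase_order` (position of the condition within
#'   the scheme's session), `scheme_order` (1 = first visit), `view_first`,
#'   and `n_trials`. A "warnings" attribute carries remainder notes.
#' @examples
#' sch <- build_schedule(session_config(n_participants = 4))
#' subset(sch, participant == 1)
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_participants
  warnings <- character(0)
  if (n %% 2 == 1) {
    warnings <- sprintf(
      "odd cohort (n=%d): participant %d assigned view-first by convention", n, n)
  }
  scheme_first <- rep(config$schemes, length.out = n)   # alternate DC/PRC first
  # within each scheme-order stratum, alternate view-first; offset the
  # second stratum so the global view-first count is exactly floor(n/2)+rem
  view_first <- logical(n)
  for (s in seq_along(config$schemes)) {
    idx <- which(scheme_first == config$schemes[s])
    view_first[idx] <- (seq_along(idx) + s) %% 2 == 0
  }
  if (n %% 2 == 1) view_first[n] <- TRUE

  n_trials_for <- function(cond) switch(
    cond,
    easy = config$trials_easy_per_dof * config$n_dofs,
    hard = config$trials_hard,
    view = config$trials_view)

  rows <- list()
  for (p in seq_len(n)) {
    schemes_p <- if (scheme_first[p] == config$schemes[1]) config$schemes
                 else rev(config$schemes)
    conds <- if (view_first[p]) c("view", "easy", "hard")
             else c("easy", "hard", "view")
    for (si in seq_along(schemes_p)) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, scheme = schemes_p[si], scheme_order = si,
        condition = conds, phase_order = seq_along(conds),
        view_first = view_first[p],
        n_trials = vapply(conds, n_trials_for, numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "warnings") <- warnings
  class(out) <- c("session_schedule", "data.frame")
  out
}
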