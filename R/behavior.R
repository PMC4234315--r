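#' Simulate behavioral trial logs
#'
#' Success is Bernoulli per trial; completion times for successful trials
#' follow a log-normal law truncated at the trial timeout (rejection
#' sampling), parameterized by the target mean/SD of the body. Failed
#' trials carry the timeout duration and `success = FALSE`. The view
#' condition is passive: its "trials" replay the 3-DOF task, so trial
#' durations are drawn from the hard-condition law but no success flag is
#' meaningful (success is NA, and view rows are excluded from behavioral
#' summaries).
#'
#' @param schedule a [build_schedule()] result.
#' @param params behavior parameter table, see [default_behavior()].
#' @param config the [session_config()] (timeout).
#' @param seed integer seed.
#' @return data.frame trial log: participant, scheme, condition, trial_id,
#'   success, duration_s.
#' @export
simulate_behavior <- function(schedule, params = default_behavior(),
                              config, seed = config$seed) {
  stopifnot(inherits(schedule, "session_schedule"))
  active <- unique(schedule$condition)
  active <- setdiff(active, "view")
  for (sc in unique(schedule$scheme)) {
    for (cond in active) {
      if (!any(params$scheme == sc & params$condition == cond)) {
        config_error("no behavior parameters for cell %s x %s", sc, cond)
      }
    }
  }
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(schedule)), function(i) {
      r <- schedule[i, ]
      cond_for_time <- if (r$condition == "view") "hard" else r$condition
      pr <- params[params$scheme == r$scheme &
                     params$condition == cond_for_time, ]
      if (nrow(pr) == 0) {  # view replay when no hard cell defined
        pr <- data.frame(success_probability = 1,
                         completion_time_mean = config$trial_timeout / 2,
                         completion_time_sd = 0)
      }
      nt <- r$n_trials
      succ <- rbinom(nt, 1, pr$success_probability) == 1
      dur <- rtrunc_lnorm(nt, pr$completion_time_mean, pr$completion_time_sd,
                          config$trial_timeout)
      dur[!succ] <- config$trial_timeout
      data.frame(participant = r$participant, scheme = r$scheme,
                 condition = r$condition, trial_id = seq_len(nt),
                 success = if (r$condition == "view") NA else succ,
                 duration_s = dur, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Truncated log-normal draws parameterized by body mean and SD
#'
#' `meanlog`/`sdlog` are chosen so the *untruncated* law has the stated mean
#' and SD; draws above `upper` are rejected and redrawn. With the default
#' behavioral cells the truncated mass is < 0.1%, so the sample mean matches
#' the stated mean to well within Monte-Carlo error.
#'
#' @param n number of draws.
#' @param mean,sd target mean and SD in seconds.
#' @param upper truncation bound (trial timeout).
#' @return numeric vector of durations, all `< upper`.
#' @export
rtrunc_lnorm <- function(n, mean, sd, upper) {
  if (n == 0) return(numeric(0))
  if (mean >= upper) config_error(
    "completion-time mean %g s is not below the timeout %g s", mean, upper)
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  x <- rlnorm(n, mu, sqrt(sigma2))
  bad <- which(x >= upper)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    x[bad] <- rlnorm(length(bad), mu, sqrt(sigma2))
    bad <- bad[x[bad] >= upper]
    guard <- guard + 1
  }
  x[x >= upper] <- upper * 0.999  # pathological parameterizations only
  x
}
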