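#' Two-way repeated-measures ANOVA (workload x scheme)
#'
#' Classical within-subject sums-of-squares decomposition for a fully
#' balanced design: main effects tested against their own
#' subject-by-effect interaction terms. Reports the uncorrected
#' degrees of freedom (the convention of the reference analysis, e.g. a
#' workload main effect at n = 18 has df = (2, 34)) plus a
#' Greenhouse-Geisser corrected p-value as a supplementary column, and
#' partial eta squared.
#'
#' @param amplitudes long data.frame with columns participant, condition,
#'   scheme, and the response named by `value`; exactly one row per
#'   participant x condition x scheme cell.
#' @param value name of the response column (default "amplitude").
#' @param conditions,schemes factor level orders.
#' @return data.frame of class `anova_result`: effect, df_num, df_den, F,
#'   p, eps_gg, p_gg, pes.
#' @examples
#' d <- expand.grid(participant = 1:6, condition = c("view", "easy", "hard"),
#'                  scheme = c("DC", "PRC"))
#' d$amplitude <- rnorm(nrow(d))
#' rm_anova(d)
#' @export
rm_anova <- function(amplitudes, value = "amplitude",
                     conditions = WORKLOAD_LEVELS, schemes = SCHEME_LEVELS) {
  df <- amplitudes
  need <- c("participant", "condition", "scheme", value)
  if (!all(need %in% names(df))) data_error(
    "amplitude slice lacks column(s): %s",
    paste(setdiff(need, names(df)), collapse = ", "))
  subs <- sort(unique(df$participant))
  a <- length(conditions); b <- length(schemes); n <- length(subs)
  if (n < 2) data_error("repeated-measures ANOVA needs >= 2 participants")
  # cell array Y[subject, condition, scheme]; missing cells are an error
  Y <- array(NA_real_, c(n, a, b))
  for (r in seq_len(nrow(df))) {
    i <- match(df$participant[r], subs)
    j <- match(df$condition[r], conditions)
    k <- match(df$scheme[r], schemes)
    if (is.na(j) || is.na(k)) next
    if (!is.na(Y[i, j, k])) data_error(
      "duplicate cell for participant %s, %s x %s", df$participant[r],
      df$condition[r], df$scheme[r])
    Y[i, j, k] <- df[[value]][r]
  }
  if (anyNA(Y)) {
    bad <- unique(subs[which(apply(Y, 1, anyNA))])
    data_error("incomplete design; exclude participant(s): %s",
               paste(bad, collapse = ", "))
  }
  G <- mean(Y)
  Si <- apply(Y, 1, mean)
  Aj <- apply(Y, 2, mean)
  Bk <- apply(Y, 3, mean)
  SAij <- apply(Y, c(1, 2), mean)
  SBik <- apply(Y, c(1, 3), mean)
  ABjk <- apply(Y, c(2, 3), mean)

  ss_a <- n * b * sum((Aj - G)^2)
  ss_b <- n * a * sum((Bk - G)^2)
  ss_as <- b * sum(sweep(sweep(SAij, 1, Si), 2, Aj - G)^2)
  ss_bs <- a * sum(sweep(sweep(SBik, 1, Si), 2, Bk - G)^2)
  ss_ab <- n * sum(sweep(sweep(ABjk, 1, Aj), 2, Bk - G)^2)
  resid <- Y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b)) {
    resid[i, j, k] <- Y[i, j, k] - SAij[i, j] - SBik[i, k] - ABjk[j, k] +
      Si[i] + Aj[j] + Bk[k] - G
  }
  ss_abs <- sum(resid^2)

  f_of <- function(ss_eff, df1, ss_err, df2) {
    if (ss_err <= 0) {
      f <- if (ss_eff <= 1e-24) 0 else Inf
    } else {
      f <- (ss_eff / df1) / (ss_err / df2)
    }
    p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
    c(f, p)
  }
  # Greenhouse-Geisser epsilon from the covariance of effect contrasts
  eps_gg <- function(M, dfe) {
    # M: n x levels matrix of per-subject effect responses
    C <- contr_orth(ncol(M))
    S <- stats::cov(M)
    Sc <- t(C) %*% S %*% C
    tr <- sum(diag(Sc))
    denom <- dfe * sum(Sc^2)
    if (denom <= 0) return(1)
    min(1, max(1 / dfe, tr^2 / denom))
  }
  MA <- apply(Y, c(1, 2), mean)
  MB <- apply(Y, c(1, 3), mean)
  MAB <- matrix(Y, n, a * b)          # cells in (condition, scheme) order
  CA <- contr_orth(a); CB <- contr_orth(b)
  eps <- c(workload = eps_gg(MA, a - 1),
           scheme = eps_gg(MB, b - 1),
           interaction = {
             C <- kronecker(CB, CA)   # matches matrix(Y, n, a*b) layout
             S <- stats::cov(MAB)
             Sc <- t(C) %*% S %*% C
             dfe <- (a - 1) * (b - 1)
             denom <- dfe * sum(Sc^2)
             if (denom <= 0) 1 else min(1, max(1 / dfe, sum(diag(Sc))^2 / denom))
           })

  eff <- list(
    workload = list(ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
    scheme = list(ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
    `workload:scheme` = list(ss_ab, (a - 1) * (b - 1), ss_abs,
                             (a - 1) * (b - 1) * (n - 1)))
  out <- do.call(rbind, lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    fp <- f_of(e[[1]], e[[2]], e[[3]], e[[4]])
    ep <- eps[[match(nm, names(eff))]]
    p_gg <- if (is.infinite(fp[1])) 0 else
      stats::pf(fp[1], e[[2]] * ep, e[[4]] * ep, lower.tail = FALSE)
    data.frame(effect = nm, df_num = as.integer(e[[2]]),
               df_den = as.integer(e[[4]]), F = fp[1],
               p = fp[2], eps_gg = ep, p_gg = p_gg,
               pes = if (e[[1]] + e[[3]] > 0) e[[1]] / (e[[1]] + e[[3]]) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

# orthonormal contrast matrix (levels x levels-1), Helmert-based
contr_orth <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Tukey-adjusted pairwise workload comparisons
#'
#' All three pairwise comparisons of the workload conditions on
#' scheme-averaged per-participant amplitudes, as within-subject (paired)
#' contrasts with a Tukey-HSD-style familywise adjustment: the studentized
#' range statistic `q = |t| * sqrt(2)` referred to the range distribution
#' with 3 means and n - 1 df. Reported regardless of the omnibus result,
#' with a flag carrying the omnibus significance.
#'
#' @param amplitudes long amplitude slice as in [rm_anova()].
#' @param value response column name.
#' @param conditions workload level order.
#' @param omnibus_p optional omnibus workload p-value for the flag.
#' @return data.frame: pair, mean_diff (first minus second), t, df, p,
#'   p_adj, omnibus_significant.
#' @export
posthoc_workload <- function(amplitudes, value = "amplitude",
                             conditions = WORKLOAD_LEVELS,
                             omnibus_p = NA_real_) {
  subs <- sort(unique(amplitudes$participant))
  M <- sapply(conditions, function(cond) {
    vapply(subs, function(p) {
      mean(amplitudes[[value]][amplitudes$participant == p &
                                 amplitudes$condition == cond])
    }, numeric(1))
  })
  n <- length(subs)
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    d <- M[, pr[1]] - M[, pr[2]]
    sdd <- sd(d)
    if (sdd < 1e-12) {
      t <- 0; p <- 1; padj <- 1
    } else {
      t <- mean(d) / (sdd / sqrt(n))
      p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
      padj <- suppressWarnings(
        ptukey(abs(t) * sqrt(2), nmeans = length(conditions),
               df = n - 1, lower.tail = FALSE))
      # ptukey is NaN at df = 1 (2-participant cohorts): Bonferroni fallback
      if (!is.finite(padj)) padj <- min(1, choose(length(conditions), 2) * p)
    }
    data.frame(pair = paste(pr, collapse = " vs "), mean_diff = mean(d),
               t = t, df = n - 1L, p = p, p_adj = padj,
               omnibus_significant = !is.na(omnibus_p) && omnibus_p < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
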