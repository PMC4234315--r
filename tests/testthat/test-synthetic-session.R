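test_that("counterbalancing: view-first split and easy-before-hard", {
  sch <- build_schedule(session_config(n_participants = 18))
  per_p <- unique(sch[c("participant", "view_first")])
  expect_identical(sum(per_p$view_first), 9L)        # exactly 50%
  # scheme order split 9/9
  first_scheme <- sch$scheme[sch$scheme_order == 1 & sch$phase_order == 1]
  expect_identical(as.vector(table(first_scheme)), c(9L, 9L))
  # easy always precedes hard, in both schemes, for everyone
  for (p in 1:18) for (sc in c("DC", "PRC")) {
    rows <- sch[sch$participant == p & sch$scheme == sc, ]
    expect_lt(rows$phase_order[rows$condition == "easy"],
              rows$phase_order[rows$condition == "hard"])
  }
  # trial counts per condition
  expect_identical(unique(sch$n_trials[sch$condition == "easy"]), 72)
  expect_identical(unique(sch$n_trials[sch$condition == "hard"]), 32)

  sch2 <- build_schedule(session_config(n_participants = 2))
  pp2 <- unique(sch2[c("participant", "view_first")])
  expect_identical(sum(pp2$view_first), 1L)

  sch3 <- build_schedule(session_config(n_participants = 3))
  expect_gt(length(attr(sch3, "warnings")), 0)
})

test_that("behavior simulation: truncation, degenerate cells, printed means", {
  cfg <- session_config(n_participants = 2, seed = 41)
  sch <- build_schedule(cfg)
  log <- simulate_behavior(sch, default_behavior(), cfg)
  expect_true(all(log$duration_s <= cfg$trial_timeout))
  expect_true(all(is.na(log$success[log$condition == "view"])))
  # degenerate: sd 0, p 1 -> every time equals the mean
  bp <- default_behavior()
  bp$completion_time_sd <- 0
  bp$success_probability <- 1
  log0 <- simulate_behavior(sch, bp, cfg)
  act <- log0[log0$condition == "easy" & log0$scheme == "DC", ]
  expect_true(all(act$duration_s == 2.4))
  # p = 0 -> completion rate 0, mean-time undefined flag
  bp$success_probability <- 0
  logf <- simulate_behavior(sch, bp, cfg)
  bs <- behavior_summary(logf)
  expect_true(all(bs$percent_completed == 0))
  expect_true(all(bs$mean_time_undefined))
  # missing cell -> configuration error naming the cell
  expect_error(simulate_behavior(sch, bp[bp$condition != "hard", ], cfg),
               regexp = "hard", class = "probeerp_config_error")
})

test_that("10,000 draws per cell reproduce the printed completion means", {
  withr::with_seed(17, {
    for (cell in list(c("DC", 2.4, 0.81), c("PRC", 2.8, 0.81),
                      c("DC", 15.1, 2.18), c("PRC", 12.5, 2.19))) {
      m <- as.numeric(cell[2]); s <- as.numeric(cell[3])
      x <- rtrunc_lnorm(10000, m, s, 24)
      expect_lt(abs(mean(x) - m), 3 * s / sqrt(10000) + 0.02)
      expect_true(all(x < 24))
    }
  })
})

test_that("probe placement: counts, separation, interval containment", {
  for (model in c("interval", "uniform")) {
    cfg <- session_config(n_participants = 4, seed = 51,
                          probe_count_model = model)
    sch <- build_schedule(cfg)
    log <- simulate_behavior(sch, default_behavior(), cfg)
    pr <- place_probes(log, cfg)
    # counts bounded by 3 over > 1000 trials
    cnt <- table(paste(pr$participant, pr$scheme, pr$condition, pr$trial_id))
    expect_lte(max(cnt), 3)
    # all pairwise within-trial gaps >= min separation (exhaustive)
    minsep <- if (model == "interval") cfg$probe_isi_min
              else cfg$min_probe_separation
    by_trial <- split(pr$time_in_trial_s,
                      paste(pr$participant, pr$scheme, pr$condition,
                            pr$trial_id))
    gaps <- unlist(lapply(by_trial, function(tt) diff(sort(tt))))
    expect_true(all(gaps >= minsep - 1e-9))
    # probes strictly inside the movement interval
    key_log <- paste(log$participant, log$scheme, log$condition, log$trial_id)
    key_pr <- paste(pr$participant, pr$scheme, pr$condition, pr$trial_id)
    dur <- log$duration_s[match(key_pr, key_log)]
    expect_true(all(pr$time_in_trial_s > cfg$planning_delay))
    expect_true(all(pr$time_in_trial_s < cfg$planning_delay + dur))
  }
  # uniform model: counts follow the configured draw; long trials carry
  # every drawn count unreduced
  cfgu <- session_config(n_participants = 4, seed = 52,
                         probe_count_model = "uniform")
  logu <- simulate_behavior(build_schedule(cfgu), default_behavior(), cfgu)
  hard <- logu[logu$condition %in% c("hard", "view"), ]
  pru <- place_probes(hard, cfgu)
  cnts <- table(factor(
    as.vector(table(paste(pru$participant, pru$scheme, pru$condition,
                          pru$trial_id))), levels = 0:3))
  n_zero <- nrow(hard) - sum(cnts[c("1", "2", "3")])
  # roughly uniform over {0,1,2,3} (chi-squared at alpha = 1e-6)
  obs <- c(n_zero, cnts[c("1", "2", "3")])
  expect_gt(chisq.test(obs)$p.value, 1e-6)
  # no probes at all when probe_max = 0
  cfg0 <- session_config(n_participants = 2, probe_max = 0,
                         probe_count_model = "uniform")
  pr0 <- place_probes(simulate_behavior(build_schedule(cfg0),
                                        default_behavior(), cfg0), cfg0)
  expect_identical(nrow(pr0), 0L)
})

test_that("seed determinism: identical config + seed give identical outputs", {
  cfg <- tiny_config(seed = 61)
  s1 <- simulate_session(cfg, render = FALSE)
  s2 <- simulate_session(cfg, render = FALSE)
  expect_identical(s1$trial_log, s2$trial_log)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$questionnaires, s2$questionnaires)
  r1 <- render_session_eeg(1, "DC", s1$schedule, s1$trial_log, s1$probes,
                           default_components(), cfg)
  r2 <- render_session_eeg(1, "DC", s2$schedule, s2$trial_log, s2$probes,
                           default_components(), cfg)
  expect_identical(r1$recording$data, r2$recording$data)
  expect_identical(r1$truth$blink_times, r2$truth$blink_times)
})

test_that("questionnaire generator produces valid, recoverable responses", {
  q <- simulate_questionnaires(18, seed = 71)
  expect_identical(nrow(q), 36L)
  expect_true(all(as.matrix(q[paste0("q", 1:7)]) %in% 1:5))
  sc <- score_questionnaire_table(q)
  expect_true(all(sc$total >= 7 & sc$total <= 35))
  # cohort means near the printed summaries (3 SE-ish slack)
  expect_lt(abs(mean(sc$total[sc$scheme == "DC"]) - 15.1), 3 * 3.8 / sqrt(18))
  expect_lt(abs(mean(sc$total[sc$scheme == "PRC"]) - 16.3), 3 * 4.4 / sqrt(18))
})
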