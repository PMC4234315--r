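test_that("rm_anova: null identity, df structure, missing cells", {
  d <- expand.grid(participant = 1:18, condition = c("view", "easy", "hard"),
                   scheme = c("DC", "PRC"), stringsAsFactors = FALSE)
  d$amplitude <- rep(rnorm(18), 6)    # constant within participant
  an <- rm_anova(d)
  expect_true(all(an$F == 0))
  expect_identical(an$df_num[an$effect == "workload"], 2L)
  expect_identical(an$df_den[an$effect == "workload"], 34L)
  expect_identical(an$df_num[an$effect == "scheme"], 1L)
  expect_identical(an$df_den[an$effect == "scheme"], 17L)
  expect_identical(an$df_den[an$effect == "workload:scheme"], 34L)
  expect_error(rm_anova(d[-1, ]), regexp = "participant",
               class = "probeerp_data_error")
})

test_that("rm_anova matches the aov sums-of-squares oracle", {
  for (seed in c(101, 202, 303)) {
    d <- random_slice(n = 6, seed = seed)
    mine <- rm_anova(d)
    dd <- transform(d, participant = factor(participant),
                    condition = factor(condition), scheme = factor(scheme))
    fit <- summary(aov(amplitude ~ condition * scheme +
                         Error(participant / (condition * scheme)),
                       data = dd))
    f_or <- c(fit[["Error: participant:condition"]][[1]]["condition", "F value"],
              fit[["Error: participant:scheme"]][[1]]["scheme", "F value"],
              fit[["Error: participant:condition:scheme"]][[1]][
                "condition:scheme", "F value"])
    expect_equal(mine$F, unname(f_or), tolerance = 1e-10)
  }
})

test_that("Greenhouse-Geisser epsilon is sane", {
  d <- random_slice(n = 10, seed = 404)
  an <- rm_anova(d)
  expect_true(all(an$eps_gg <= 1 + 1e-12))
  expect_gte(an$eps_gg[an$effect == "workload"], 0.5)   # lower bound 1/(a-1)
  expect_identical(an$eps_gg[an$effect == "scheme"], 1) # 2 levels: exact
  # for a 2-level effect the correction is a no-op
  expect_equal(an$p_gg[an$effect == "scheme"], an$p[an$effect == "scheme"])
  # and for F > 1 shrinking both dfs cannot make the effect look stronger
  big <- an[an$F > 1, ]
  if (nrow(big)) expect_true(all(big$p_gg >= big$p - 1e-12))
})

test_that("post-hoc workload contrasts: degenerate and monotone", {
  d <- expand.grid(participant = 1:18, condition = c("view", "easy", "hard"),
                   scheme = c("DC", "PRC"), stringsAsFactors = FALSE)
  d$amplitude <- rep(rnorm(18), 6)
  ph <- posthoc_workload(d)
  expect_true(all(ph$p_adj > 0.99))
  d2 <- random_slice(n = 18, seed = 505)
  ph2 <- posthoc_workload(d2, omnibus_p = 0.5)
  expect_true(all(ph2$p_adj >= ph2$p - 1e-12))
  expect_identical(nrow(ph2), 3L)
  expect_false(any(ph2$omnibus_significant))
})

test_that("post-hoc power: view vs hard significant under defaults", {
  g <- default_gain()
  sig <- vapply(1:200, function(s) {
    tab <- simulate_amplitude_cohort(18, gain = g, sigma_m = measurement_sd(),
                                     channels = "Pz", seed = 7000 + s)
    slice <- tab[tab$component == "P300" & tab$electrode == "Pz", ]
    ph <- posthoc_workload(slice)
    ph$p_adj[ph$pair == "view vs hard"] < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("paired t: identity, df, hand computation, antisymmetry", {
  x <- rnorm(18)
  t0 <- paired_t(x, x)
  expect_identical(t0$t, 0)
  expect_identical(t0$p, 1)
  expect_identical(t0$df, 17L)
  # differences {1,2,3}: mean 2, sd 1 -> t = 2*sqrt(3)
  th <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(th$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(th$df, 2L)
  y <- rnorm(18)
  expect_equal(paired_t(x, y)$t, -paired_t(y, x)$t, tolerance = 1e-12)
})

test_that("pearson correlation: exact cases and zero-variance flag", {
  x <- rnorm(17)
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_true(pearson_corr(x, rep(1, 17))$undefined)
  y <- rnorm(17)
  pc <- pearson_corr(x, y)
  # covariance-formula oracle
  r_or <- cov(x, y) / (sd(x) * sd(y))
  expect_equal(pc$r, r_or, tolerance = 1e-12)
  expect_identical(pc$df, 15L)
})

test_that("behavior summary: arithmetic and success-only rule", {
  log <- data.frame(participant = 1, scheme = "DC", condition = "hard",
                    trial_id = 1:32, success = c(rep(TRUE, 24), rep(FALSE, 8)),
                    duration_s = c(rep(5, 24), rep(24, 8)))
  bs <- behavior_summary(log)
  expect_equal(bs$percent_completed, 75)
  log2 <- data.frame(participant = 1, scheme = "DC", condition = "easy",
                     trial_id = 1:3, success = c(TRUE, TRUE, FALSE),
                     duration_s = c(2, 3, 24))
  expect_equal(behavior_summary(log2)$mean_time, 2.5)   # failure excluded
})

test_that("questionnaire scoring: reversals, bounds, errors", {
  expect_identical(score_questionnaire(rep(3, 7)), 21L)
  expect_identical(score_questionnaire(rep(5, 7)), 23L)  # 4*5 + 3*1
  expect_identical(score_questionnaire(rep(1, 7)), 19L)  # 4*1 + 3*5
  expect_error(score_questionnaire(rep(3, 6)), class = "probeerp_data_error")
  expect_error(score_questionnaire(c(rep(3, 6), 6)), regexp = "7",
               class = "probeerp_data_error")
  # reversal is an involution
  withr::with_seed(15, raw <- sample(1:5, 7, replace = TRUE))
  rev1 <- raw; rev1[c(1, 3, 7)] <- 6L - rev1[c(1, 3, 7)]
  rev2 <- rev1; rev2[c(1, 3, 7)] <- 6L - rev2[c(1, 3, 7)]
  expect_identical(rev2, raw)
  # totals bounded for all-extreme responses
  for (r in list(rep(1, 7), rep(5, 7), c(1, 5, 1, 5, 1, 5, 1))) {
    tot <- score_questionnaire(r)
    expect_gte(tot, 7); expect_lte(tot, 35)
  }
})
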