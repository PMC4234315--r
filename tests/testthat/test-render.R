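test_that("templates are zero-mean with compact support away from windows", {
  cmp <- default_components()
  t <- seq(-200, 1100, by = 0.5)
  for (j in seq_len(nrow(cmp))) {
    h <- erp_template(t, cmp$peak_latency[j], cmp$half_width[j],
                      ifelse(cmp$polarity[j] == "negative", -1, 1) *
                        cmp$base_amplitude[j])
    expect_lt(abs(sum(h) * 0.5), 1e-6)                 # zero area
    supp <- range(t[h != 0])
    expect_gte(supp[1], 0)                             # no pre-stimulus energy
    expect_lte(supp[2], 1000)
    pk <- t[which.max(abs(h))]
    expect_lt(abs(pk - cmp$peak_latency[j]), 1)
  }
})

test_that("noiseless rendering reproduces the injected template exactly", {
  cfg <- tiny_config(seed = 3)
  sim <- simulate_session(cfg, render = FALSE)
  cmp <- default_components()
  sess <- render_session_eeg(1, "DC", sim$schedule, sim$trial_log,
                             sim$probes, cmp, cfg, noise = FALSE,
                             blinks = FALSE)
  eps <- extract_epochs(sess$recording, sess$events, participant = 1)
  ok <- which(!sess$truth$probes$overlap)
  expect_gt(length(ok), 5)
  for (i in ok[1:5]) {
    cond <- eps$keys$condition[i]
    amps <- sess$truth$injected[[cond]]
    for (ch in c("Cz", "Pz")) {
      tpl <- numeric(length(eps$times))
      for (j in seq_len(nrow(cmp))) {
        tpl <- tpl + cmp[[paste0("topo_", ch)]][j] *
          erp_template(eps$times, cmp$peak_latency[j], cmp$half_width[j],
                       amps[j])
      }
      expect_lt(max(abs(eps$epochs[i, ch, ] - tpl)), 1e-9)
    }
  }
})

test_that("rendering is linear in the component list", {
  cfg <- tiny_config(seed = 13)
  sim <- simulate_session(cfg, render = FALSE)
  cmp <- default_components()
  early <- cmp[1:2, ]; late <- cmp[3:4, ]
  # same seed: the noise and blinks are drawn identically regardless of the
  # component list, so render(all) - render(early) = render(late, silent)
  r_all <- render_session_eeg(1, "DC", sim$schedule, sim$trial_log,
                              sim$probes, cmp, cfg, pscale = rep(1, 4))
  r_early <- render_session_eeg(1, "DC", sim$schedule, sim$trial_log,
                                sim$probes, early, cfg, pscale = rep(1, 2))
  r_late <- render_session_eeg(1, "DC", sim$schedule, sim$trial_log,
                               sim$probes, late, cfg, pscale = rep(1, 2),
                               noise = FALSE, blinks = FALSE)
  expect_equal(r_all$recording$data,
               r_early$recording$data + r_late$recording$data,
               tolerance = 1e-12)
})

test_that("noiseless signal is zero outside template supports", {
  cfg <- tiny_config(seed = 23)
  sim <- simulate_session(cfg, render = FALSE)
  sess <- render_session_eeg(1, "PRC", sim$schedule, sim$trial_log,
                             sim$probes, default_components(), cfg,
                             noise = FALSE, blinks = FALSE)
  x <- sess$recording$data["Pz", ]
  # knock out +/- 1.1 s around every probe; the rest must be exactly 0
  mask <- rep(TRUE, length(x))
  for (s in sess$events$sample_index) {
    mask[max(1, s - 100):min(length(x), s + 1101)] <- FALSE
  }
  expect_identical(max(abs(x[mask])), 0)
})

test_that("blink ground truth matches artifact flags", {
  cfg <- tiny_config(seed = 33)
  sim <- simulate_session(cfg, render = FALSE)
  sess <- render_session_eeg(2, "DC", sim$schedule, sim$trial_log,
                             sim$probes, default_components(), cfg,
                             noise = FALSE, blinks = TRUE)
  pp <- preprocess_session(sess, 2)
  eps <- bandpass_filter(sess$recording)
  eps <- extract_epochs(eps, sess$events, participant = 2)
  eps <- baseline_correct(eps)
  eps <- reject_artifacts(eps)
  # every epoch overlapping an injected blink must be flagged as eog_p2p
  onsets <- sess$events$sample_index / cfg$sfreq
  overlaps <- vapply(onsets, function(t0) {
    any(sess$truth$blink_times > t0 - 0.45 & sess$truth$blink_times < t0 + 1.05)
  }, logical(1))
  expect_gt(sum(overlaps), 0)
  expect_true(all(eps$artifact[overlaps]))
  expect_true(all(grepl("eog_p2p", eps$artifact_reason[overlaps])))
  # without noise, no clean epoch should be flagged
  expect_false(any(eps$artifact[!overlaps]))
})

test_that("window amplitudes are recovered without bias (Monte Carlo)", {
  # P300 8 uV at Pz, attenuation 1, 40 epochs, realistic noise, 100 seeds
  cfg <- session_config()
  cmp <- default_components()
  g <- default_gain()
  w <- default_windows()
  amps <- injected_amplitude(cmp, "view", "DC")
  expc <- expected_amplitudes(cmp, "view", "DC", gain = g, channels = "Pz")
  meas <- vapply(1:100, function(s) {
    eps <- render_cell_epochs(amps, cmp, cfg, n_epochs = 40,
                              channels = "Pz", seed = 9000 + s)
    avg <- average_epochs(eps, "sim", "sim", min_trials = 1)
    window_mean(avg, "Pz", w$start_ms[3], w$end_ms[3])   # P300
  }, numeric(1))
  se <- sd(meas) / sqrt(100)
  expect_lt(abs(mean(meas) - expc["P300", 1]), 3 * se)
})

test_that("measured condition means decrease with workload per participant", {
  cfg <- session_config()
  cmp <- default_components()
  w <- default_windows()
  n_sim <- 60
  dec <- vapply(seq_len(n_sim), function(s) {
    vals <- vapply(c("view", "easy", "hard"), function(cond) {
      amps <- injected_amplitude(cmp, cond, "DC")
      eps <- render_cell_epochs(amps, cmp, cfg, n_epochs = 40,
                                channels = "Pz", seed = 20000 + 10 * s +
                                  match(cond, c("view", "easy", "hard")))
      avg <- average_epochs(eps, "sim", "sim", min_trials = 1)
      window_mean(avg, "Pz", w$start_ms[3], w$end_ms[3])
    }, numeric(1))
    vals["view"] > vals["easy"] && vals["easy"] > vals["hard"]
  }, logical(1))
  expect_gte(mean(dec), 0.95)
})
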