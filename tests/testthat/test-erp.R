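test_that("averaging basics: symmetry, idempotence, sqrt-n law", {
  tpl <- erp_template(seq(-100, 1000), 312, 70, 8)
  arr <- array(0, c(2, 1, 1101))
  arr[1, 1, ] <- 1; arr[2, 1, ] <- -1
  eps <- make_epoch_set(arr, channel_labels = "Pz")
  expect_identical(max(abs(average_epochs(eps, "DC", "easy",
                                          min_trials = 1)$data)), 0)
  arr40 <- array(rep(tpl, each = 40), c(40, 1, 1101))
  eps40 <- make_epoch_set(arr40, channel_labels = "Pz")
  expect_equal(as.vector(average_epochs(eps40, "DC", "easy",
                                        min_trials = 1)$data), tpl,
               tolerance = 1e-12)
  # residual SD of the 40-epoch average of white noise ~ sigma/sqrt(40)
  withr::with_seed(12, {
    ratio <- vapply(1:100, function(s) {
      a <- array(rnorm(40 * 1101, sd = 2), c(40, 1, 1101))
      e <- make_epoch_set(a, channel_labels = "Pz")
      sd(average_epochs(e, "DC", "easy", min_trials = 1)$data)
    }, numeric(1))
  })
  expect_lt(abs(mean(ratio) - 2 / sqrt(40)), 0.2 * 2 / sqrt(40))
})

test_that("grand average: identity, midpoint, axis checks", {
  mk_avg <- function(scale) {
    arr <- array(scale * rep(erp_template(seq(-100, 1000), 312, 70, 1),
                             each = 31), c(31, 1, 1101))
    average_epochs(make_epoch_set(arr, channel_labels = "Pz"), "DC", "easy",
                   min_trials = 30)
  }
  a2 <- mk_avg(2); a4 <- mk_avg(4)
  g <- grand_average(list(a2, a4))
  expect_equal(max(g$data), 3, tolerance = 1e-9)       # midpoint of 2 and 4
  gid <- grand_average(list(a2, a2))
  expect_equal(gid$data, a2$data, tolerance = 1e-12)
  expect_error(grand_average(list(a2)), class = "probeerp_data_error")
  b <- a2; b$times <- b$times + 1
  expect_error(grand_average(list(a2, b)), class = "probeerp_data_error")
})

test_that("peak finding: noiseless identity, tie-break, flat flag", {
  tpl <- erp_template(seq(-100, 1000), 312, 70, 8)
  arr <- array(rep(tpl, each = 31), c(31, 1, 1101))
  avg <- average_epochs(make_epoch_set(arr, channel_labels = "Pz"),
                        "DC", "easy", min_trials = 1)
  pk <- find_peak(avg, "Pz", c(250, 450), "positive")
  expect_equal(pk$latency_ms, 312)
  flat <- average_epochs(make_epoch_set(array(1, c(31, 1, 1101)),
                                        channel_labels = "Pz"),
                         "DC", "easy", min_trials = 1)
  pf <- find_peak(flat, "Pz", c(250, 450), "positive")
  expect_equal(pf$latency_ms, 250)
  expect_identical(pf$flag, "no distinct peak")
  expect_error(find_peak(avg, "Cz", c(250, 450)),
               class = "probeerp_data_error")
})

test_that("grand-average peak latency is recovered under noise", {
  cfg <- session_config()
  cmp <- default_components()
  hits <- vapply(1:40, function(s) {
    avgs <- lapply(1:6, function(p) {   # 6 participants is enough to average
      eps <- render_cell_epochs(injected_amplitude(cmp, "view", "DC"),
                                cmp, cfg, n_epochs = 40, channels = "Pz",
                                seed = 50000 + 100 * s + p)
      average_epochs(eps, "sim", "sim", min_trials = 1)
    })
    g <- grand_average(avgs)
    abs(find_peak(g, "Pz", c(250, 450), "positive")$latency_ms - 312) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("window means: constants, endpoint arithmetic, hand-summed ramp", {
  cst <- average_epochs(make_epoch_set(array(4, c(31, 1, 1101)),
                                       channel_labels = "Pz"),
                        "DC", "easy", min_trials = 1)
  expect_equal(window_mean(cst, "Pz", 295, 330), 4)
  # P300 window 295-330 at 1000 Hz = 36 samples inclusive; ramp 0..35
  arr <- array(0, c(1, 1, 1101))
  arr[1, 1, (295 + 101):(330 + 101)] <- 0:35
  ramp <- average_epochs(make_epoch_set(arr, channel_labels = "Pz"),
                         "DC", "easy", min_trials = 1)
  expect_equal(window_mean(ramp, "Pz", 295, 330), 17.5)
  expect_error(window_mean(cst, "Fz", 295, 330),
               class = "probeerp_data_error")
  expect_error(window_mean(cst, "Pz", -200, 330),
               class = "probeerp_config_error")
})

test_that("averaging and windowing commute (linearity)", {
  withr::with_seed(14, {
    arr <- array(rnorm(40 * 1101), c(40, 1, 1101))
  })
  eps <- make_epoch_set(arr, channel_labels = "Pz")
  avg <- average_epochs(eps, "DC", "easy", min_trials = 1)
  w <- default_windows()
  for (i in seq_len(nrow(w))) {
    per_epoch <- vapply(1:40, function(k) {
      a1 <- make_epoch_set(arr[k, , , drop = FALSE], channel_labels = "Pz")
      window_mean(average_epochs(a1, "DC", "easy", min_trials = 1), "Pz",
                  w$start_ms[i], w$end_ms[i])
    }, numeric(1))
    expect_equal(mean(per_epoch),
                 window_mean(avg, "Pz", w$start_ms[i], w$end_ms[i]),
                 tolerance = 1e-10)
  }
})

test_that("recentering preserves window widths and finds injected peaks", {
  tpl <- function(peak, hw, amp) erp_template(seq(-100, 1000), peak, hw, amp)
  x <- tpl(118, 35, -5) + tpl(205, 45, 5) + tpl(330, 70, 8) + tpl(600, 80, 4)
  arr <- array(0, c(31, 3, 1101))
  for (ch in 1:3) arr[, ch, ] <- rep(x, each = 31)
  g <- average_epochs(make_epoch_set(arr, channel_labels = c("Fz", "Cz", "Pz")),
                      "DC", "easy", min_trials = 1)
  w0 <- default_windows()
  wr <- recenter_windows(g, w0)
  expect_equal(wr$end_ms - wr$start_ms, w0$end_ms - w0$start_ms)
  # windows recentred on the (shifted) injected peaks; overlapping
  # component tails can move the argmax by a sample or two
  expect_equal(wr$start_ms + (wr$end_ms - wr$start_ms) / 2,
               c(118, 205, 330, 600), tolerance = 2e-2)
})
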