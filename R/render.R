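#' Zero-mean biphasic ERP component template
#'
#' `h(t) = A * (2*hann(t, hw) - hann(t, 2*hw))` on support `peak +/- 2*hw`
#' (ms): a raised-cosine central lobe of the stated polarity flanked by
#' gentle opposite-sign lobes that cancel the pulse's DC content exactly.
#' A zero-area template passes the 1 Hz high-pass of the analysis band
#' without the broad undershoot a unipolar bump acquires, so components do
#' not bleed into neighboring scoring windows or the baseline.
#'
#' @param times_ms numeric vector of times (ms) at which to evaluate.
#' @param peak peak latency, ms.
#' @param half_width half-width `hw` of the central lobe, ms.
#' @param amplitude signed peak amplitude, microvolts.
#' @return numeric vector, same length as `times_ms`.
#' @examples
#' t <- seq(-100, 1000)
#' sum(erp_template(t, 312, 70, 8))  # ~0: zero-mean
#' @export
erp_template <- function(times_ms, peak, half_width, amplitude) {
  d <- times_ms - peak
  h1 <- ifelse(abs(d) <= half_width,
               0.5 * (1 + cos(pi * d / half_width)), 0)
  h2 <- ifelse(abs(d) <= 2 * half_width,
               0.5 * (1 + cos(pi * d / (2 * half_width))), 0)
  amplitude * (2 * h1 - h2)
}

#' Pink (1/f) background noise
#'
#' Spectral shaping in the frequency domain: amplitude proportional to
#' `f^-1/2` (power 1/f) above 0.5 Hz, flat below, random phases; scaled to
#' the requested RMS. Uses the current RNG stream.
#'
#' @param n number of samples.
#' @param sfreq sampling rate, Hz.
#' @param rms target RMS, microvolts.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sfreq, rms) {
  if (rms == 0) return(numeric(n))
  pink_noise_matrix(1, n, sfreq, rms)[1, ]
}

#' Several independent pink-noise channels at once
#'
#' Same construction as [pink_noise()] (Gaussian spectral amplitudes shaped
#' as f^-1/2, flat below 0.5 Hz), but two real channels are synthesized per
#' inverse FFT via the real/imaginary-part trick, which halves the dominant
#' cost when rendering multi-channel recordings.
#'
#' @param nch number of channels.
#' @param n samples per channel.
#' @param sfreq sampling rate, Hz.
#' @param rms target RMS per channel, microvolts.
#' @return `nch` x `n` numeric matrix.
#' @export
pink_noise_matrix <- function(nch, n, sfreq, rms) {
  out <- matrix(0, nch, n)
  if (rms == 0) return(out)
  nfft <- stats::nextn(n, c(2, 3, 5))
  if (nfft %% 2 == 1) nfft <- nfft + 1
  nf <- nfft %/% 2 - 1
  f <- seq_len(nf) * sfreq / nfft
  shape <- 1 / sqrt(pmax(f, 0.5))
  for (pair in seq_len(ceiling(nch / 2))) {
    spec1 <- shape * complex(real = rnorm(nf), imaginary = rnorm(nf))
    spec2 <- shape * complex(real = rnorm(nf), imaginary = rnorm(nf))
    # Hermitian X1 + i * Hermitian X2: ifft real part -> ch1, imag -> ch2
    full <- c(0, spec1 + 1i * spec2, 0,
              Conj(rev(spec1)) + 1i * Conj(rev(spec2)))
    z <- fft(full, inverse = TRUE)[seq_len(n)]
    x1 <- Re(z); x2 <- Im(z)
    i1 <- 2 * pair - 1
    out[i1, ] <- x1 * rms / sqrt(mean(x1^2))
    if (i1 + 1 <= nch) out[i1 + 1, ] <- x2 * rms / sqrt(mean(x2^2))
  }
  out
}

blink_shape <- function(sfreq, duration_s = 0.4, amplitude = 150) {
  t <- seq_len(round(duration_s * sfreq)) / sfreq
  amplitude * 0.5 * (1 - cos(2 * pi * t / duration_s))
}

blink_topography <- function(channels) {
  w <- setNames(numeric(length(channels)), channels)
  known <- c(VEOG = 1, HEOG = 0.1, Fz = 0.4, Cz = 0.15, Pz = 0.05)
  for (nm in names(known)) if (nm %in% channels) w[nm] <- known[nm]
  w
}

alpha_topography <- function(channels) {
  w <- setNames(numeric(length(channels)), channels)
  known <- c(Pz = 1, Cz = 0.6, Fz = 0.3, VEOG = 0.05, HEOG = 0.05)
  for (nm in names(known)) if (nm %in% channels) w[nm] <- known[nm]
  w
}

component_topography <- function(components, channels) {
  topo <- matrix(0, nrow(components), length(channels),
                 dimnames = list(components$name, channels))
  for (ch in channels) {
    col <- paste0("topo_", ch)
    if (col %in% names(components)) topo[, ch] <- components[[col]]
  }
  topo
}

signed_base <- function(components) {
  ifelse(components$polarity == "negative", -1, 1) * components$base_amplitude
}

#' Injected (ground-truth) signed peak amplitude for one cell
#'
#' base * attenuation(condition) * participant scale, plus the additive
#' scheme delta (PRC, hard condition only), with the component's polarity
#' sign applied. Channel topography is multiplicative on top of this.
#'
#' @param components component spec table.
#' @param condition,scheme cell labels.
#' @param pscale per-participant, per-component scale factors (length =
#'   number of components; default 1).
#' @return named numeric vector of signed peak amplitudes, microvolts.
#' @export
injected_amplitude <- function(components, condition, scheme, pscale = 1) {
  att <- components[[paste0("att_", condition)]]
  amp <- signed_base(components) * att * pscale
  if (scheme == "PRC" && condition == "hard") {
    amp <- amp + sign(signed_base(components)) * components$scheme_delta_PRC_hard
  }
  setNames(amp, components$name)
}

#' Render one participant x scheme session to continuous EEG
#'
#' Builds the session timeline (inter-trial interval, planning window,
#' movement of the logged duration per trial, conditions in schedule
#' order), then renders per channel: pink noise + spatially coherent 10 Hz
#' alpha + per-probe component templates scaled by condition attenuation,
#' scheme delta, participant scale, and topography + eyeblink transients.
#'
#' @param participant participant index.
#' @param scheme scheme label.
#' @param schedule full [build_schedule()] table.
#' @param trial_log full [simulate_behavior()] log.
#' @param probes full [place_probes()] table.
#' @param components component spec table.
#' @param config a [session_config()].
#' @param pscale participant amplitude scale factors (per component).
#' @param noise logical: include pink/alpha background (FALSE renders the
#'   noiseless deterministic signal).
#' @param blinks logical: include eyeblink transients.
#' @param seed integer seed for noise and blink draws.
#' @return list: `recording` (continuous_recording), `events`
#'   (event_markers), `truth` (list with probe table incl. absolute times,
#'   blink times, injected amplitudes per condition, overlap flags).
#' @export
render_session_eeg <- function(participant, scheme, schedule, trial_log,
                               probes, components, config,
                               pscale = rep(1, nrow(components)),
                               noise = TRUE, blinks = TRUE,
                               seed = config$seed) {
  validate_components(components)
  epoch_len_s <- 1.1
  if (max(components$peak_latency + 2 * components$half_width) / 1000 >
      epoch_len_s) config_error("component support exceeds the epoch length")
  sched <- schedule[schedule$participant == participant &
                      schedule$scheme == scheme, ]
  sched <- sched[order(sched$phase_order), ]
  log_ps <- trial_log[trial_log$participant == participant &
                        trial_log$scheme == scheme, ]
  pr_ps <- probes[probes$participant == participant &
                    probes$scheme == scheme, ]
  sf <- config$sfreq
  iti <- config$inter_trial_interval

  # timeline: absolute start of each trial (s)
  starts <- list()
  t_cur <- 1.0   # lead-in so the first epoch window fits
  for (ci in seq_len(nrow(sched))) {
    cond <- sched$condition[ci]
    lg <- log_ps[log_ps$condition == cond, ]
    lg <- lg[order(lg$trial_id), ]
    st <- numeric(nrow(lg))
    for (ti in seq_len(nrow(lg))) {
      t_cur <- t_cur + iti
      st[ti] <- t_cur
      t_cur <- t_cur + config$planning_delay + lg$duration_s[ti]
    }
    starts[[cond]] <- st
  }
  total_s <- t_cur + 2.0
  n <- as.integer(ceiling(total_s * sf))
  channels <- config$channels
  nch <- length(channels)

  # absolute probe times and event table
  if (nrow(pr_ps) > 0) {
    pr_ps$time_abs_s <- vapply(seq_len(nrow(pr_ps)), function(i) {
      starts[[pr_ps$condition[i]]][pr_ps$trial_id[i]] + pr_ps$time_in_trial_s[i]
    }, numeric(1))
    pr_ps <- pr_ps[order(pr_ps$time_abs_s), ]
    pr_ps$sample_index <- as.integer(round(pr_ps$time_abs_s * sf))
    gaps <- diff(pr_ps$sample_index) / sf
    pr_ps$overlap <- c(gaps < epoch_len_s, FALSE) | c(FALSE, gaps < epoch_len_s)
  } else {
    pr_ps$time_abs_s <- numeric(0)
    pr_ps$sample_index <- integer(0)
    pr_ps$overlap <- logical(0)
  }

  topo <- component_topography(components, channels)
  atopo <- alpha_topography(channels)
  btopo <- blink_topography(channels)

  blink_rate <- config$blink_rate_per_min *
    (if (participant %in% config$noisy_participants) 10 else 1)

  data <- matrix(0, nch, n, dimnames = list(channels, NULL))
  seed_ps <- as.integer((seed + 7919L * participant +
                           131L * match(scheme, config$schemes)) %% .Machine$integer.max)
  withr::with_seed(seed_ps, {
    if (noise) {
      alpha_phase <- runif(1, 0, 2 * pi)
      alpha <- config$noise_alpha_rms * sqrt(2) *
        sin(2 * pi * 10 * seq_len(n) / sf + alpha_phase)
      data <- pink_noise_matrix(nch, n, sf, config$noise_pink_rms)
      dimnames(data) <- list(channels, NULL)
      for (ch in seq_len(nch)) {
        data[ch, ] <- data[ch, ] + atopo[ch] * alpha
      }
    }
    blink_times <- numeric(0)
    if (blinks && blink_rate > 0) {
      nb <- rpois(1, blink_rate / 60 * total_s)
      blink_times <- sort(runif(nb, 0, total_s - 0.5))
      bs <- blink_shape(sf)
      for (bt in blink_times) {
        i0 <- as.integer(round(bt * sf)) + 1L
        idx <- i0:(i0 + length(bs) - 1L)
        keep <- idx <= n
        for (ch in seq_len(nch)) {
          if (btopo[ch] != 0) {
            data[ch, idx[keep]] <- data[ch, idx[keep]] + btopo[ch] * bs[keep]
          }
        }
      }
    }
  })

  # deterministic part: component templates at each probe
  amp_by_cond <- lapply(setNames(nm = unique(sched$condition)), function(cond)
    injected_amplitude(components, cond, scheme, pscale))
  if (nrow(pr_ps) > 0) {
    # post-stimulus sample grid covering every component's support
    s_hi <- ceiling(max(components$peak_latency +
                          2 * components$half_width) * sf / 1000) + 1L
    rel_ms <- (0:s_hi) * 1000 / sf
    for (i in seq_len(nrow(pr_ps))) {
      cond <- pr_ps$condition[i]
      amps <- amp_by_cond[[cond]]
      i0 <- pr_ps$sample_index[i] + 1L        # 1-based onset sample
      for (j in seq_len(nrow(components))) {
        cj <- components[j, ]
        wave <- erp_template(rel_ms, cj$peak_latency, cj$half_width, amps[j])
        nz <- which(wave != 0)
        if (length(nz) == 0) next
        idx <- i0 + nz - 1L
        keep <- idx >= 1 & idx <= n
        w <- wave[nz][keep]
        for (ch in seq_len(nch)) {
          if (topo[j, ch] != 0) {
            data[ch, idx[keep]] <- data[ch, idx[keep]] + topo[j, ch] * w
          }
        }
      }
    }
  }

  rec <- continuous_recording(data, channels, sf)
  events <- event_markers(pr_ps$sample_index, "probe", pr_ps$condition,
                          scheme, pr_ps$trial_id, n_samples = n)
  truth <- list(participant = participant, scheme = scheme,
                probes = pr_ps, blink_times = blink_times,
                injected = amp_by_cond, pscale = pscale,
                topography = topo, trial_starts = starts)
  list(recording = rec, events = events, truth = truth)
}

#' Simulate Likert questionnaire responses
#'
#' Per participant x scheme, a target scored total is drawn from a normal
#' law matching the printed cohort summaries (DC mean 15.1, SD 3.8; PRC
#' mean 16.3, SD 4.4), clamped to the feasible range, and split across the
#' 7 items; items 1, 3 and 7 are then inverse reverse-scored so that
#' [score_questionnaire()] recovers the drawn total.
#'
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param means,sds named per-scheme total means and SDs.
#' @return data.frame: participant, scheme, q1..q7 (raw responses, 1-5).
#' @export
simulate_questionnaires <- function(n_participants, seed = 1L,
                                    means = c(DC = 15.1, PRC = 16.3),
                                    sds = c(DC = 3.8, PRC = 4.4)) {
  withr::with_seed(seed + 2L, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      for (sc in names(means)) {
        total <- round(rnorm(1, means[sc], sds[sc]))
        total <- min(max(total, 7L), 35L)
        scored <- rep(as.integer(round(total / 7)), 7)
        scored <- pmin(pmax(scored, 1L), 5L)
        guard <- 0
        while (sum(scored) != total && guard < 200) {
          i <- sample.int(7, 1)
          if (sum(scored) < total && scored[i] < 5) scored[i] <- scored[i] + 1L
          if (sum(scored) > total && scored[i] > 1) scored[i] <- scored[i] - 1L
          guard <- guard + 1
        }
        raw <- scored
        raw[c(1, 3, 7)] <- 6L - scored[c(1, 3, 7)]
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, scheme = sc, t(setNames(raw, paste0("q", 1:7))),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort session
#'
#' Orchestrates schedule, behavior, probe placement, questionnaires, and
#' per-participant-scheme EEG rendering. For memory economy the EEG can be
#' rendered lazily: with `render = FALSE` only the renderer closures'
#' inputs are returned and [render_session_eeg()] is called downstream.
#'
#' @param config a [session_config()].
#' @param components component table, see [default_components()].
#' @param behavior behavior table, see [default_behavior()].
#' @param render logical: render EEG for all participant x scheme cells now.
#' @return list of class `synthetic_session`: schedule, trial_log, probes,
#'   questionnaires, pscales (participants x components), and (if rendered)
#'   `sessions`, a list of render_session_eeg() results keyed
#'   "participant_scheme".
#' @export
simulate_session <- function(config = session_config(),
                             components = default_components(),
                             behavior = default_behavior(),
                             render = TRUE) {
  schedule <- build_schedule(config)
  trial_log <- simulate_behavior(schedule, behavior, config)
  probes <- place_probes(trial_log, config)
  quest <- simulate_questionnaires(config$n_participants, config$seed)
  pscales <- withr::with_seed(config$seed + 3L, {
    matrix(rnorm(config$n_participants * nrow(components), 1,
                 config$participant_scale_sd),
           config$n_participants, nrow(components),
           dimnames = list(NULL, components$name))
  })
  out <- list(config = config, components = components, behavior = behavior,
              schedule = schedule, trial_log = trial_log, probes = probes,
              questionnaires = quest, pscales = pscales)
  if (render) {
    out$sessions <- list()
    for (p in seq_len(config$n_participants)) {
      for (sc in config$schemes) {
        key <- paste(p, sc, sep = "_")
        out$sessions[[key]] <- render_session_eeg(
          p, sc, schedule, trial_log, probes, components, config,
          pscale = pscales[p, ])
      }
    }
  }
  class(out) <- "synthetic_session"
  out
}
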