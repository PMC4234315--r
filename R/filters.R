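#' Design a Butterworth bandpass filter as second-order sections
#'
#' Analog Butterworth prototype of the given order, lowpass-to-bandpass
#' transform, bilinear transform with prewarping. Returned as a cascade of
#' biquads (second-order sections) rather than a single b/a pair: at narrow
#' normalized bands (e.g. 1-15 Hz on 1000 Hz data) the direct-form order-2n
#' recursion is numerically unusable, while the SOS cascade is stable.
#'
#' @param order prototype order (the bandpass filter has `2*order` poles).
#' @param low,high band edges in Hz.
#' @param sfreq sampling rate in Hz.
#' @return list with `sos` (n x 6 matrix, columns b0 b1 b2 a0 a1 a2) and
#'   `gain` (scalar applied once per filtering pass).
#' @examples
#' d <- butter_bandpass(4, 1, 15, 1000)
#' dim(d$sos)
#' @export
butter_bandpass <- function(order, low, high, sfreq) {
  if (low <= 0 || high <= low) config_error("need 0 < low < high, got %g, %g", low, high)
  if (high >= sfreq / 2) config_error("high edge %g Hz is not below Nyquist (%g Hz)", high, sfreq / 2)
  fs2 <- 2 * sfreq
  w1 <- fs2 * tan(pi * low / sfreq)
  w2 <- fs2 * tan(pi * high / sfreq)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  p <- c(pb + disc, pb - disc)
  gain <- Re(bw^order * fs2^order / prod(fs2 - p))
  pz <- (fs2 + p) / (fs2 - p)
  pu <- pz[Im(pz) > 0]
  if (length(pu) != order) config_error("pole pairing failed; use an even order")
  # zeros: `order` at z=+1 (from s=0) and `order` at z=-1 (from s=Inf).
  # Pair z=-1 zeros with the largest-angle poles (upper band edge), z=+1
  # with the smallest-angle poles (lower edge); run least-resonant first.
  pu <- pu[order(abs(Arg(pu)), decreasing = TRUE)]
  half <- ceiling(order / 2)
  sos <- t(vapply(seq_along(pu), function(i) {
    b <- if (i <= half) c(1, 2, 1) else c(1, -2, 1)
    c(b, 1, -2 * Re(pu[i]), Mod(pu[i])^2)
  }, numeric(6)))
  sos <- sos[order(Mod(pu)), , drop = FALSE]
  list(sos = sos, gain = gain, sfreq = sfreq, band = c(low, high))
}

# One IIR pass of a biquad cascade with step-matched initial conditions:
# the filter state is initialized as if the input had been constant at its
# first sample since -Inf (scipy lfilter_zi semantics), which suppresses
# startup transients without very long padding. Implemented with
# stats::filter (C speed): FIR part by convolution, AR part recursively.
sosfilt_step <- function(x, sos, gain) {
  x0 <- x[1] * gain
  y <- x * gain
  n <- length(y)
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]
    a <- sos[i, 4:6]
    # FIR part, vectorized: v[t] = b0 y[t] + b1 y[t-1] + b2 y[t-2]
    v <- b[1] * y
    v[2:n] <- v[2:n] + b[2] * y[1:(n - 1)]
    v[1] <- v[1] + b[2] * x0
    v[3:n] <- v[3:n] + b[3] * y[1:(n - 2)]
    v[1:2] <- v[1:2] + b[3] * c(x0, x0)   # past inputs are x0, x0
    ybar <- x0 * sum(b) / sum(a)
    y <- as.numeric(stats::filter(v, -a[-1], method = "recursive",
                                  init = c(ybar, ybar)))
    x0 <- ybar
  }
  y
}

#' Zero-phase (forward-backward) filtering of a numeric vector
#'
#' Applies the SOS cascade forward and backward with odd-reflection padding,
#' giving zero group delay and the squared magnitude response.
#'
#' @param x numeric vector.
#' @param design filter design from [butter_bandpass()].
#' @param pad reflection pad length in samples (clamped to `length(x) - 1`).
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_sos <- function(x, design, pad = 3 * design$sfreq) {
  n <- length(x)
  if (n < 8) config_error("signal too short to filter (%d samples)", n)
  pad <- min(pad, n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sosfilt_step(xp, design$sos, design$gain)
  y <- rev(sosfilt_step(rev(y), design$sos, design$gain))
  y[(pad + 1):(pad + n)]
}

#' Bandpass-filter a continuous recording (zero phase)
#'
#' 1-15 Hz by default; 4th-order Butterworth applied forward-backward so that
#' event-locked features keep their latency. EOG channels are filtered with
#' the same band (artifact thresholds below are applied to filtered data).
#'
#' @param rec a `continuous_recording`.
#' @param low,high band edges in Hz.
#' @param order Butterworth prototype order.
#' @return a filtered `continuous_recording`.
#' @export
bandpass_filter <- function(rec, low = 1, high = 15, order = 4) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (high >= rec$sfreq / 2) config_error(
    "high edge %g Hz must be below Nyquist (%g Hz)", high, rec$sfreq / 2)
  d <- butter_bandpass(order, low, high, rec$sfreq)
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- filtfilt_sos(rec$data[i, ], d)
  }
  out$filtered <- c(low, high)
  out
}
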