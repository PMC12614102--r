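# Radio channel model: per-antenna complex gains (amplitude and phase
# trajectories), additive receiver noise, and intermediate-band rendering.
#
# Fading is modeled as prescribed smooth amplitude/phase trajectories rather
# than ray-traced multipath: the downstream receiver only ever sees the
# complex gains, so this is the minimal faithful abstraction of destructive
# multipath interference.

ANTENNAS <- c("A", "B", "C", "D")

#' Construct a channel realization from gain trajectories
#'
#' Gain trajectories are given at knot times and interpolated linearly at
#' render time; they must change slowly relative to the vocal modulation.
#'
#' @param knot_t knot times (s), increasing, common to all antennas.
#' @param amp n_knots x 4 matrix of gain amplitudes (>= 0), or a scalar /
#'   length-4 vector for constant gains.
#' @param phase n_knots x 4 matrix of gain phases (rad), or scalar / length-4.
#' @param noise_sigma per-antenna complex-noise standard deviation
#'   (sqrt(E|n|^2)); scalar or length 4.
#' @param fade_intervals optional ground-truth data.frame
#'   (antenna, onset, offset) recorded by scenario builders.
#' @return object of class `channel_realization`.
#' @export
channel_realization <- function(knot_t, amp, phase = 0, noise_sigma = 0,
                                fade_intervals = NULL) {
  nk <- length(knot_t)
  stopifnot(nk >= 2, !is.unsorted(knot_t))
  expand <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == nk, ncol(x) == 4)
      x
    } else {
      matrix(rep(rep_len(x, 4), each = nk), nk, 4)
    }
  }
  amp <- expand(amp); phase <- expand(phase)
  stopifnot(all(amp >= 0), all(is.finite(amp)), all(is.finite(phase)))
  colnames(amp) <- colnames(phase) <- ANTENNAS
  structure(list(knot_t = knot_t, amp = amp, phase = phase,
                 noise_sigma = rep_len(noise_sigma, 4),
                 fade_intervals = fade_intervals),
            class = "channel_realization")
}

#' Adversarial fading scenario
#'
#' Builds the worst plausible single-antenna world: every antenna suffers one
#' deep fade (amplitude dips to 0.005 < 0.02), the fades are pairwise
#' disjoint in time, and at every instant at least three antennas have
#' amplitude >= 0.5 (outside its fade every antenna sits at amplitude 1).
#' Gain phases drift smoothly and independently. Ground-truth fade intervals
#' (amplitude < 0.02) are computed in closed form from the raised-cosine dip
#' shape and stored in the returned object.
#'
#' @param duration_s scenario duration (s); must fit 4 disjoint fades.
#' @param seed integer seed (placement and phase drift).
#' @param noise_sigma per-antenna complex noise sd, default 0.02
#'   (single-antenna tone SNR of 34 dB at unit gain).
#' @param fade_width_s full width of the amplitude dip (default
#'   `min(0.5, 0.8 * duration_s / 4)`).
#' @return a [channel_realization()] with `fade_intervals` filled in.
#' @export
make_fading_scenario <- function(duration_s, seed = 1, noise_sigma = 0.02,
                                 fade_width_s = NULL) {
  stopifnot(duration_s > 0.2)
  set.seed(seed)
  slot <- duration_s / 4
  w <- if (is.null(fade_width_s)) min(0.5, 0.8 * slot) else fade_width_s
  stopifnot(w < slot)
  floor_amp <- 0.005
  knot_dt <- min(0.001, w / 50)
  knot_t <- seq(0, duration_s, by = knot_dt)
  nk <- length(knot_t)
  order_a <- sample(4)                       # which antenna fades in which slot
  amp <- matrix(1, nk, 4)
  centers <- numeric(4)
  for (s in 1:4) {
    a <- order_a[s]
    lo <- (s - 1) * slot + w / 2
    hi <- s * slot - w / 2
    centers[a] <- runif(1, lo, hi)
    amp[, a] <- 1 - (1 - floor_amp) * raised_cosine(knot_t, centers[a], w)
  }
  # phases: smooth spline through sparse random knots, independent per antenna
  tp <- seq(0, duration_s, length.out = max(4, ceiling(duration_s / 0.5) + 1))
  phase <- sapply(1:4, function(a) {
    spline(tp, cumsum(rnorm(length(tp), 0, 0.4)), xout = knot_t)$y
  })
  # closed-form fade intervals: amplitude < 0.02
  # 1 - (1-floor)*rc < 0.02  <=>  rc > 0.98/(1-floor)
  thr <- 0.98 / (1 - floor_amp)
  half <- w * acos(2 * thr - 1) / (2 * pi)
  fades <- data.frame(antenna = ANTENNAS,
                      onset = centers - half, offset = centers + half)
  fades <- fades[order(fades$onset), ]
  rownames(fades) <- NULL
  channel_realization(knot_t, amp, phase, noise_sigma, fade_intervals = fades)
}

channel_at <- function(channel, t) {
  amp <- sapply(ANTENNAS, function(a)
    approx(channel$knot_t, channel$amp[, a], xout = t, rule = 2)$y)
  phase <- sapply(ANTENNAS, function(a)
    approx(channel$knot_t, channel$phase[, a], xout = t, rule = 2)$y)
  list(amp = amp, phase = phase)
}

#' Render per-antenna intermediate-band signals
#'
#' Produces the complex signals the receiver sees after (emulated) analog
#' down-conversion to the band around the local oscillator:
#' `z_a(t) = amp_a(t) * exp(i * [2*pi * integral(omega_T - lo) + phase_a(t)])
#'  + n_a(t)` with circularly symmetric white Gaussian noise of per-antenna
#' standard deviation sigma_a, independent across antennas. The phase
#' integral is accumulated in double precision and wrapped.
#'
#' @param omega_t instantaneous transmitter frequency (Hz) from
#'   [fm_encode()], carrying a `rate_hz` attribute, or a plain vector with
#'   `omega_rate_hz` supplied.
#' @param channel a [channel_realization()].
#' @param lo_hz local oscillator frequency (Hz).
#' @param rate_hz output complex sample rate F_z (Hz).
#' @param seed integer seed for the noise draws.
#' @param omega_rate_hz sample rate of `omega_t` when not an attribute.
#' @return object of class `signal_set`: list of four complex vectors `z`
#'   plus `rate_hz`, `lo_hz`, `duration_s`.
#' @export
render_antennas <- function(omega_t, channel, lo_hz = 300e6,
                            rate_hz = 100e6 / 128, seed = 1,
                            omega_rate_hz = attr(omega_t, "rate_hz")) {
  stopifnot(inherits(channel, "channel_realization"), !is.null(omega_rate_hz))
  duration_s <- length(omega_t) / omega_rate_hz
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  f <- approx((seq_along(omega_t) - 1) / omega_rate_hz, as.numeric(omega_t),
              xout = t, rule = 2)$y - lo_hz
  bad <- which(abs(f) >= rate_hz / 2)
  if (length(bad))
    stop(sprintf("aliasing: |omega_T - lo| >= rate/2 at t = %.6f s", t[bad[1]]))
  phi <- (2 * pi * cumsum(f / rate_hz)) %% (2 * pi)
  ch <- channel_at(channel, t)
  set.seed(seed)
  z <- vector("list", 4)
  names(z) <- ANTENNAS
  for (a in seq_along(ANTENNAS)) {
    za <- ch$amp[, a] * exp(1i * (phi + ch$phase[, a]))
    s <- channel$noise_sigma[a]
    if (s > 0)
      za <- za + s / sqrt(2) * complex(real = rnorm(n), imaginary = rnorm(n))
    z[[a]] <- za
  }
  structure(list(z = z, rate_hz = rate_hz, lo_hz = lo_hz,
                 duration_s = duration_s),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> 4 antennas, %.3f s at %.4g S/s, LO %.6g Hz\n",
              x$duration_s, x$rate_hz, x$lo_hz))
  invisible(x)
}
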