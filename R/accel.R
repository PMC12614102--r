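# Transmitter-side simulation: ground-truth accelerometer traces and their
# FM encoding onto a radio carrier.

#' Transmitter description
#'
#' Physical parameters of one FM transmitter. The accelerometer signal a(t)
#' (units g) is encoded as instantaneous transmitter frequency
#' `omega_T(t) = carrier(t) + sensitivity * a_hp(t) + excursions(t)`, where
#' `a_hp` is the trace after the transmitter's analog high-pass and the
#' excursion term carries carrier-frequency effects (proximity, wing flaps)
#' that exist independently of the accelerometer.
#'
#' @param carrier_hz carrier frequency omega_c (Hz). Default 300.1 MHz, i.e.
#'   100 kHz above the usual 300 MHz local oscillator.
#' @param sensitivity_hz_per_g FM sensitivity c (Hz per g); the measured
#'   end-to-end value is 5 kHz/g.
#' @param hardware_highpass_hz cutoff of the transmitter-side analog
#'   high-pass (Hz), default 15.
#' @param drift_hz_per_s slow linear carrier drift (Hz/s), default 0. Battery
#'   depletion and temperature produce drifts of hundreds of kHz over hours.
#' @return object of class `transmitter_spec`.
#' @export
transmitter_spec <- function(carrier_hz = 300.1e6, sensitivity_hz_per_g = 5000,
                             hardware_highpass_hz = 15, drift_hz_per_s = 0) {
  stopifnot(carrier_hz > 0, sensitivity_hz_per_g > 0, hardware_highpass_hz >= 0)
  structure(list(carrier_hz = carrier_hz,
                 sensitivity_hz_per_g = sensitivity_hz_per_g,
                 hardware_highpass_hz = hardware_highpass_hz,
                 drift_hz_per_s = drift_hz_per_s),
            class = "transmitter_spec")
}

#' Vocalization event specification
#'
#' Describes vocal events as harmonic stacks, either explicitly (`onset`,
#' `duration`, ... vectors of equal length) or as a random process
#' (`rate_per_s` events drawn uniformly in time with the other arguments as
#' ranges). Harmonics above `max_hz` (default 7 kHz, the upper end of
#' body-vibration vocal content) or above Nyquist are dropped.
#'
#' @param onset,duration explicit event times (s), or NULL for random events.
#' @param f0_hz fundamental frequency per event (or range when random).
#' @param amp_g peak acceleration amplitude per event in g (or range).
#' @param n_harmonics harmonics per stack (amplitude rolls off as 1/h).
#' @param rate_per_s event rate for random generation.
#' @param envelope `"flat"` (5 ms raised-cosine ramps) or `"hann"`.
#' @param max_hz harmonic band limit (Hz).
#' @return object of class `vocal_spec`.
#' @export
vocal_spec <- function(onset = NULL, duration = 0.1, f0_hz = 600, amp_g = 0.3,
                       n_harmonics = 1, rate_per_s = 1,
                       envelope = c("flat", "hann"), max_hz = 7000) {
  envelope <- match.arg(envelope)
  stopifnot(all(duration > 0), all(f0_hz > 0), all(amp_g >= 0),
            n_harmonics >= 1, rate_per_s >= 0, max_hz > 0)
  structure(list(onset = onset, duration = duration, f0_hz = f0_hz,
                 amp_g = amp_g, n_harmonics = n_harmonics,
                 rate_per_s = rate_per_s, envelope = envelope, max_hz = max_hz),
            class = "vocal_spec")
}

#' Wing-flap excursion specification
#'
#' Wing flaps appear as brief downward dips of the carrier frequency (a
#' proximity effect of the moving wing, not accelerometer output). Dips are
#' raised-cosine shaped, `depth_hz` deep and `width_s` wide, repeating at
#' `rate_hz` (the zebra finch flaps at 26-30 Hz) between `start_s` and
#' `stop_s`.
#'
#' @param rate_hz dip repetition rate (Hz), default 28.
#' @param depth_hz dip depth (Hz), default 300 kHz.
#' @param width_s full dip width (s), default 8 ms.
#' @param start_s,stop_s bout limits (s); NULL = whole trace.
#' @return object of class `flap_spec`.
#' @export
flap_spec <- function(rate_hz = 28, depth_hz = 3e5, width_s = 0.008,
                      start_s = NULL, stop_s = NULL) {
  stopifnot(rate_hz > 0, depth_hz >= 0, width_s > 0)
  structure(list(rate_hz = rate_hz, depth_hz = depth_hz, width_s = width_s,
                 start_s = start_s, stop_s = stop_s), class = "flap_spec")
}

#' Proximity-effect excursion specification
#'
#' Large carrier-frequency excursions caused by body parts (head, partner
#' bird) near the transmitter coil; amplitudes can reach 2.5 MHz, roughly a
#' thousand times the vocal modulation. Modeled as raised-cosine bumps.
#'
#' @param onset_s event onset times (s).
#' @param amp_hz signed peak excursion per event (Hz), default 2.5 MHz.
#' @param width_s full bump width (s), default 50 ms.
#' @return object of class `proximity_spec`.
#' @export
proximity_spec <- function(onset_s, amp_hz = 2.5e6, width_s = 0.05) {
  stopifnot(all(width_s > 0))
  structure(list(onset_s = onset_s,
                 amp_hz = rep_len(amp_hz, length(onset_s)),
                 width_s = rep_len(width_s, length(onset_s))),
            class = "proximity_spec")
}

raised_cosine <- function(t, center, width) {
  u <- (t - center) / width
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Synthesize a ground-truth accelerometer trace
#'
#' Builds the transmitter-side world: an acceleration trace (vocal harmonic
#' stacks, units g), a separate carrier-frequency excursion trajectory (wing
#' flap dips and proximity bumps, units Hz), and ground-truth annotations for
#' every injected event. The excursion trajectory is kept apart from the
#' acceleration samples because these effects modulate the carrier directly.
#'
#' @param duration_s trace duration (s), > 0.
#' @param rate_hz sample rate (default the audio clock rate 24,414.0625 Hz;
#'   must be at least twice the highest vocal harmonic).
#' @param vocal a [vocal_spec()] or NULL.
#' @param flaps a [flap_spec()] or NULL.
#' @param proximity a [proximity_spec()] or NULL.
#' @param seed integer seed for random event placement (NULL = no seeding).
#' @return object of class `accel_trace`: list with `samples` (g), `rate_hz`,
#'   `excursion_hz` (carrier excursion trajectory at trace rate),
#'   `annotations` (data.frame onset/offset/label), and `events` (per-type
#'   ground-truth details, e.g. flap dip times).
#' @export
synthesize_accel_trace <- function(duration_s, rate_hz = 200e6 / 2^13,
                                   vocal = NULL, flaps = NULL,
                                   proximity = NULL, seed = NULL) {
  stopifnot(duration_s > 0, rate_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  samples <- numeric(n)
  excursion <- numeric(n)
  ann <- list()
  events <- list()

  if (!is.null(vocal)) {
    stopifnot(inherits(vocal, "vocal_spec"))
    if (is.null(vocal$onset)) {
      n_ev <- rpois(1, vocal$rate_per_s * duration_s)
      onset <- sort(runif(n_ev, 0, max(0, duration_s - max(vocal$duration))))
      duration <- runif(n_ev, min(vocal$duration), max(vocal$duration))
      f0 <- runif(n_ev, min(vocal$f0_hz), max(vocal$f0_hz))
      amp <- runif(n_ev, min(vocal$amp_g), max(vocal$amp_g))
    } else {
      onset <- vocal$onset
      duration <- rep_len(vocal$duration, length(onset))
      f0 <- rep_len(vocal$f0_hz, length(onset))
      amp <- rep_len(vocal$amp_g, length(onset))
    }
    if (length(onset) && (min(onset) < 0 ||
                          max(onset + duration) > duration_s))
      stop("vocal events must lie within [0, duration_s]")
    if (rate_hz < 2 * max(c(f0, 0)))
      stop("trace rate below twice the vocal fundamental")
    for (e in seq_along(onset)) {
      idx <- which(t >= onset[e] & t < onset[e] + duration[e])
      if (!length(idx)) next
      te <- t[idx] - onset[e]
      tone <- numeric(length(idx))
      hmax <- 0
      for (h in seq_len(vocal$n_harmonics)) {
        fh <- h * f0[e]
        if (fh > vocal$max_hz || fh >= rate_hz / 2) break
        tone <- tone + sin(2 * pi * fh * te) / h
        hmax <- hmax + 1 / h
      }
      if (hmax == 0) next
      env <- if (vocal$envelope == "hann") {
        0.5 - 0.5 * cos(2 * pi * te / duration[e])
      } else {
        ramp <- min(0.005, duration[e] / 4)
        pmin(1, pmin(te, duration[e] - te) / ramp)
      }
      samples[idx] <- samples[idx] + amp[e] / hmax * env * tone
      ann[[length(ann) + 1L]] <-
        data.frame(onset = onset[e], offset = onset[e] + duration[e],
                   label = "vocal")
    }
    events$vocal <- data.frame(onset = onset, duration = duration,
                               f0_hz = f0, amp_g = amp)
  }

  if (!is.null(flaps)) {
    stopifnot(inherits(flaps, "flap_spec"))
    t0 <- if (is.null(flaps$start_s)) flaps$width_s else flaps$start_s
    t1 <- if (is.null(flaps$stop_s)) duration_s - flaps$width_s else flaps$stop_s
    dip_times <- seq(t0, t1, by = 1 / flaps$rate_hz)
    for (d in dip_times) {
      excursion <- excursion - flaps$depth_hz * raised_cosine(t, d, flaps$width_s)
      ann[[length(ann) + 1L]] <-
        data.frame(onset = d - flaps$width_s / 2, offset = d + flaps$width_s / 2,
                   label = "flap")
    }
    events$flap <- data.frame(dip_time = dip_times,
                              depth_hz = flaps$depth_hz,
                              width_s = flaps$width_s)
  }

  if (!is.null(proximity)) {
    stopifnot(inherits(proximity, "proximity_spec"))
    for (e in seq_along(proximity$onset_s)) {
      c0 <- proximity$onset_s[e] + proximity$width_s[e] / 2
      excursion <- excursion +
        proximity$amp_hz[e] * raised_cosine(t, c0, proximity$width_s[e])
      ann[[length(ann) + 1L]] <-
        data.frame(onset = proximity$onset_s[e],
                   offset = proximity$onset_s[e] + proximity$width_s[e],
                   label = "proximity")
    }
    events$proximity <- data.frame(onset = proximity$onset_s,
                                   amp_hz = proximity$amp_hz,
                                   width_s = proximity$width_s)
  }

  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(onset = numeric(0), offset = numeric(0), label = character(0))
  if (nrow(annotations) &&
      (min(annotations$onset) < -1e-9 ||
       max(annotations$offset) > duration_s + 1e-9))
    stop("annotations outside [0, duration_s]")
  stopifnot(all(is.finite(samples)))
  structure(list(samples = samples, rate_hz = rate_hz,
                 excursion_hz = excursion, annotations = annotations,
                 events = events, duration_s = duration_s),
            class = "accel_trace")
}

#' Transmitter analog high-pass (single-pole RC)
#'
#' First-order recursive high-pass emulating the transmitter's input RC
#' filter: `y[n] = a * (y[n-1] + x[n] - x[n-1])` with
#' `a = 1 / (1 + 2*pi*fc/Fs)`.
#'
#' @param x signal.
#' @param rate_hz sample rate.
#' @param cutoff_hz -3 dB cutoff; 0 returns `x` unchanged.
#' @return filtered signal.
#' @export
transmitter_highpass <- function(x, rate_hz, cutoff_hz = 15) {
  if (cutoff_hz <= 0) return(x)
  a <- 1 / (1 + 2 * pi * cutoff_hz / rate_hz)
  n <- length(x)
  dx <- c(x[1], diff(x))      # x[0] taken as 0 before the first sample? no:
  # steady state assumption: treat x[-1] = x[1] so the filter starts at rest
  dx[1] <- 0
  y <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- a * (acc + dx[i])
    y[i] <- acc
  }
  y
}

#' FM-encode an acceleration trace
#'
#' Instantaneous transmitter frequency at the trace rate:
#' `omega_T = carrier + drift*t + sensitivity * highpass(a) + excursions`.
#'
#' @param trace an [accel_trace].
#' @param spec a [transmitter_spec()].
#' @param excursions carrier excursion trajectory (Hz, trace rate); defaults
#'   to the trace's own `excursion_hz`.
#' @param band_hz optional length-2 vector; if given, an error names the
#'   first time at which `omega_T` leaves this band.
#' @return numeric vector of instantaneous frequency (Hz) with attributes
#'   `rate_hz` and `spec`.
#' @export
fm_encode <- function(trace, spec = transmitter_spec(), excursions = NULL,
                      band_hz = NULL) {
  stopifnot(inherits(trace, "accel_trace"), inherits(spec, "transmitter_spec"))
  if (is.null(excursions)) excursions <- trace$excursion_hz
  stopifnot(length(excursions) == length(trace$samples))
  n <- length(trace$samples)
  t <- (seq_len(n) - 1) / trace$rate_hz
  a_hp <- transmitter_highpass(trace$samples, trace$rate_hz,
                               spec$hardware_highpass_hz)
  omega <- spec$carrier_hz + spec$drift_hz_per_s * t +
    spec$sensitivity_hz_per_g * a_hp + excursions
  if (!is.null(band_hz)) {
    bad <- which(omega < band_hz[1] | omega > band_hz[2])
    if (length(bad))
      stop(sprintf("omega_T leaves the intermediate band at t = %.6f s",
                   t[bad[1]]))
  }
  structure(omega, rate_hz = trace$rate_hz, spec = spec)
}

#' Decode an instantaneous-frequency trajectory back to acceleration
#'
#' The documented inverse of [fm_encode()] up to the transmitter high-pass:
#' subtract carrier and drift, divide by the sensitivity. Excursion terms are
#' not removed (they are not accelerometer output).
#'
#' @param omega_t output of [fm_encode()].
#' @param spec the [transmitter_spec()] used for encoding (default: taken
#'   from the attribute).
#' @return acceleration estimate (g) at the trace rate.
#' @export
fm_decode <- function(omega_t, spec = attr(omega_t, "spec")) {
  rate <- attr(omega_t, "rate_hz")
  t <- (seq_along(omega_t) - 1) / rate
  (as.numeric(omega_t) - spec$carrier_hz - spec$drift_hz_per_s * t) /
    spec$sensitivity_hz_per_g
}
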