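# Shared DSP primitives: FIR design, zero-phase filtering, Welch spectra.
#
# No dedicated signal-processing package is available in the target library,
# so the handful of primitives needed here (windowed-sinc design, overlap-free
# FFT convolution, Welch averaging) are implemented directly on top of
# stats::fft.

#' Design a lowpass FIR filter with a Kaiser window
#'
#' Windowed-sinc design. The cutoff is placed halfway between the passband and
#' stopband edges; the Kaiser shape parameter and tap count follow the standard
#' empirical formulas for the requested stopband attenuation, which also bounds
#' the passband ripple (60 dB stopband corresponds to < 0.01 dB ripple).
#'
#' @param rate_hz sample rate of the signal the filter will run at.
#' @param passband_hz passband edge (Hz); response is flat below this.
#' @param stopband_hz stopband edge (Hz); response is down by
#'   `atten_db` above this. Must exceed `passband_hz`.
#' @param atten_db target stopband attenuation in dB (default 60).
#' @return numeric vector of filter taps, odd length, unit DC gain.
#' @examples
#' h <- fir_lowpass(1e5, 1e4, 2e4)
#' sum(h)  # 1
#' @export
fir_lowpass <- function(rate_hz, passband_hz, stopband_hz, atten_db = 60) {
  stopifnot(rate_hz > 0, passband_hz > 0, stopband_hz > passband_hz,
            stopband_hz <= rate_hz / 2)
  df <- (stopband_hz - passband_hz) / rate_hz
  n <- ceiling((atten_db - 7.95) / (2.285 * 2 * pi * df))
  if (n %% 2L == 1L) n <- n + 1L           # force odd length n + 1
  beta <- if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db >= 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else 0
  fc <- (passband_hz + stopband_hz) / 2 / rate_hz   # cycles/sample
  k <- seq(-n / 2, n / 2)
  h <- 2 * fc * sinc(2 * fc * k)
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * k / n)^2)), 0) / besselI(beta, 0)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' FFT-based linear convolution
#'
#' @param x signal (numeric or complex).
#' @param h filter taps.
#' @param conv_type `"full"` returns length `n + k - 1`; `"same"` returns the
#'   centered part of length `n` (zero-phase for symmetric `h`).
#' @return convolved sequence; complex if either input is complex.
#' @export
convolve_fft <- function(x, h, conv_type = c("same", "full")) {
  conv_type <- match.arg(conv_type)
  n <- length(x); k <- length(h)
  m <- n + k - 1L
  nfft <- 2^ceiling(log2(m))
  y <- fft(fft(c(x, rep(0, nfft - n))) * fft(c(h, rep(0, nfft - k))),
           inverse = TRUE)[seq_len(m)] / nfft
  if (is.numeric(x) && is.numeric(h)) y <- Re(y)
  if (conv_type == "full") return(y)
  off <- (k - 1L) %/% 2L
  y[off + seq_len(n)]
}

#' Zero-phase FIR high-pass filter
#'
#' Spectral-inversion design: a unit impulse minus a Kaiser lowpass, applied
#' with `"same"` (delay-compensated) convolution, giving exactly zero phase and
#' an exact spectral null at DC. Because the taps are symmetric and sum to
#' zero, constant and (in the interior) linear trends are removed exactly;
#' this is what makes the filter suitable for stripping carrier drift from
#' demodulated frequency traces. Edges are handled by reflection padding.
#'
#' @param x numeric signal.
#' @param rate_hz sample rate (Hz).
#' @param cutoff_hz high-pass cutoff; the transition band spans
#'   `cutoff_hz * c(0.5, 1.5)`.
#' @return filtered signal, same length as `x`.
#' @export
highpass_zerophase <- function(x, rate_hz, cutoff_hz) {
  stopifnot(cutoff_hz > 0, cutoff_hz < rate_hz / 2)
  h <- fir_lowpass(rate_hz, 0.5 * cutoff_hz, 1.5 * cutoff_hz)
  k <- length(h)
  hp <- -h
  hp[(k + 1L) %/% 2L] <- hp[(k + 1L) %/% 2L] + 1
  pad <- (k - 1L) %/% 2L
  if (length(x) <= pad + 1L) stop("signal too short for the requested cutoff")
  xe <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
  y <- convolve_fft(xe, hp, "same")
  y[pad + seq_along(x)]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

#' Welch power / cross spectral density
#'
#' One-sided Welch estimate with Hann window and 50% overlap. With `y`
#' supplied the cross-spectrum S_xy is returned (complex), otherwise the PSD
#' of `x`. Scaling is density (units^2 per Hz): the integral of the PSD over
#' frequency equals the signal variance-plus-mean-square.
#'
#' @param x,y signals (same length); `y` optional.
#' @param rate_hz sample rate.
#' @param nfft segment length (default 1024, truncated to the signal length).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return data.frame with `freq` and `psd` (or complex `csd`).
#' @export
psd_welch <- function(x, rate_hz, nfft = 1024L, overlap = 0.5, y = NULL) {
  n <- length(x)
  nfft <- min(as.integer(nfft), n)
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- hann_window(nfft)
  norm <- rate_hz * sum(w^2)
  acc <- complex(real = numeric(nfft %/% 2L + 1L))
  idx <- seq_len(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    fx <- fft((seg - mean(seg)) * w)
    if (is.null(y)) {
      acc <- acc + (Conj(fx) * fx)[idx]
    } else {
      segy <- y[s:(s + nfft - 1L)]
      fy <- fft((segy - mean(segy)) * w)
      acc <- acc + (Conj(fx) * fy)[idx]
    }
  }
  sxx <- acc / (length(starts) * norm)
  # one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- rep(2, length(idx)); dbl[1] <- 1
  if (nfft %% 2L == 0L) dbl[length(idx)] <- 1
  sxx <- sxx * dbl
  freq <- (idx - 1L) * rate_hz / nfft
  if (is.null(y)) data.frame(freq = freq, psd = Re(sxx))
  else data.frame(freq = freq, csd = sxx)
}

#' Express an amplitude in dB relative to a reference
#'
#' Field convention for frequency-excursion amplitudes: `20 log10(x / ref)`,
#' e.g. a 2.5 MHz excursion is 68 dB re 1 kHz and a 3.4 kHz vocal deviation
#' is 11 dB re 1 kHz (both after integer rounding).
#'
#' @param x amplitude(s).
#' @param ref reference amplitude (default 1 kHz).
#' @return dB values (not rounded).
#' @export
db_re <- function(x, ref = 1e3) 20 * log10(x / ref)
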