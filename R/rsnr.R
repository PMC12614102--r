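# Radio signal-to-noise statistics of rotated baseband signals.
#
# RSNR^a(t_k) = 10*log10(p^a(t_k) / v^a) over non-overlapping 21-ms radio
# frames, where p is the squared magnitude of the frame-mean rotated vector,
# the per-frame variance is <|r|^2> - |<r>|^2, and v^a is the per-file
# median of the per-frame variances ("smooth" noise estimate).

#' Per-frame RSNR series
#'
#' Aggregates the demodulator's per-block rotated-vector statistics into
#' radio frames and computes signal power, noise variance and RSNR for the
#' four antennas and the compensated sum M. The default frame length is
#' 512 logged samples (about 21 ms), the radio-frame convention aligned to
#' one video frame.
#'
#' @param demod a [run_demodulator()] output (block statistics are used).
#' @param frame_s frame duration in seconds; rounded to a whole number of
#'   compensation blocks (default: 512 logged samples).
#' @return object of class `rsnr_frames`: data.frame-backed list with
#'   `t` (frame centers), matrices `p` and `v_frame` (frames x sources),
#'   per-file median noise `v` (named vector), `rsnr` (frames x sources, dB;
#'   `Inf` sentinel where v = 0), `frame_s`, `sources`.
#' @export
rsnr_frames <- function(demod, frame_s = NULL) {
  stopifnot(inherits(demod, "demod_output"))
  cfg <- demod$cfg
  if (is.null(frame_s))
    frame_s <- 512 * cfg$log_decimation / demod$rate_bb
  fpb <- max(1L, round(frame_s * demod$block_rate))
  nb <- nrow(demod$r_mean)
  nf <- nb %/% fpb
  if (nf < 1) stop("trace shorter than one radio frame")
  sources <- colnames(demod$r_mean)
  p <- matrix(NA_real_, nf, length(sources), dimnames = list(NULL, sources))
  vf <- p
  for (k in seq_len(nf)) {
    rows <- ((k - 1) * fpb + 1):(k * fpb)
    for (s in seq_along(sources)) {
      m1 <- mean(demod$r_mean[rows, s])        # frame mean of r
      m2 <- mean(demod$r_pow[rows, s])         # frame mean of |r|^2
      p[k, s] <- Mod(m1)^2
      vf[k, s] <- m2 - Mod(m1)^2
    }
  }
  v <- apply(vf, 2, median)
  rsnr <- sapply(seq_along(sources), function(s) {
    if (v[s] <= 0) rep(Inf, nf) else 10 * log10(p[, s] / v[s])
  })
  colnames(rsnr) <- sources
  frame_len_s <- fpb / demod$block_rate
  structure(list(t = (seq_len(nf) - 0.5) * frame_len_s,
                 p = p, v_frame = vf, v = v, rsnr = rsnr,
                 frame_s = frame_len_s, sources = sources),
            class = "rsnr_frames")
}

#' @export
print.rsnr_frames <- function(x, ...) {
  fin <- is.finite(x$rsnr)
  cat(sprintf("<rsnr_frames> %d frames of %.4f s; mean RSNR (dB):\n",
              nrow(x$rsnr), x$frame_s))
  print(round(colMeans(ifelse(fin, x$rsnr, NA), na.rm = TRUE), 2))
  invisible(x)
}

#' Best single antenna
#'
#' Selects, per file, the antenna whose time-averaged RSNR is largest and
#' returns its per-frame RSNR trace (the RSNR* reference against which the
#' multi-antenna gain is quoted). Ties break to the lowest antenna label.
#'
#' @param series an [rsnr_frames()] object.
#' @return list `antenna` (label) and `rsnr` (per-frame dB trace).
#' @export
best_single_antenna <- function(series) {
  stopifnot(inherits(series, "rsnr_frames"))
  ants <- intersect(ANTENNAS, series$sources)
  avg <- colMeans(series$rsnr[, ants, drop = FALSE])
  best <- ants[which.max(avg)]       # which.max takes the first (lowest label)
  list(antenna = best, rsnr = series$rsnr[, best])
}

#' Fading statistics
#'
#' Fraction of time with critically low RSNR (below 13 dB, the operational
#' definition of signal fading), per source.
#'
#' @param series an [rsnr_frames()] object.
#' @param threshold_db fading threshold (dB).
#' @return named vector of percent time below threshold.
#' @export
fading_stats <- function(series, threshold_db = 13) {
  stopifnot(inherits(series, "rsnr_frames"))
  100 * colMeans(series$rsnr < threshold_db)
}

#' Noise power of the demodulated signal
#'
#' P_N: the power spectral density of the high-pass-filtered demodulated
#' signal, Welch-averaged over periods without vocalization and integrated
#' from 0 to 8 kHz; reported in dB re 1 Hz^2. Together with the RSNR this is
#' the quality measure of a demodulated trace: P_N decreases monotonically
#' as RSNR grows.
#'
#' @param x demodulated (high-pass-filtered) frequency trace (Hz).
#' @param rate_hz sample rate of `x`.
#' @param non_vocal data.frame with `onset`/`offset` (s) of non-vocal
#'   periods; must be non-empty.
#' @param band_hz integration band (default 0-8 kHz, clipped to Nyquist).
#' @param nfft Welch segment length (Hann window, 50% overlap).
#' @return list `P_N_db`, `P_N_hz2` (linear), `psd` (averaged data.frame).
#' @export
noise_power <- function(x, rate_hz, non_vocal, band_hz = c(0, 8000),
                        nfft = 1024L) {
  if (is.null(non_vocal) || nrow(non_vocal) == 0)
    stop("no non-vocal segments supplied")
  segs <- lapply(seq_len(nrow(non_vocal)), function(i) {
    i0 <- max(1L, floor(non_vocal$onset[i] * rate_hz) + 1L)
    i1 <- min(length(x), floor(non_vocal$offset[i] * rate_hz))
    if (i1 - i0 + 1L < 2L) return(NULL)
    x[i0:i1]
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) stop("non-vocal segments contain no samples")
  # Welch-average each segment's PSD, weighted by its length
  acc <- NULL; wtot <- 0
  for (s in segs) {
    if (length(s) < 64L) next
    ps <- psd_welch(s, rate_hz, nfft = min(nfft, length(s)))
    # resample onto the grid of the first (full-nfft) estimate if needed
    if (is.null(acc)) {
      acc <- ps$psd * length(s); freq <- ps$freq; wtot <- length(s)
    } else if (length(ps$psd) == length(acc)) {
      acc <- acc + ps$psd * length(s); wtot <- wtot + length(s)
    } else {
      acc <- acc + approx(ps$freq, ps$psd, xout = freq, rule = 2)$y * length(s)
      wtot <- wtot + length(s)
    }
  }
  if (is.null(acc)) stop("non-vocal segments too short for a PSD estimate")
  psd <- acc / wtot
  band_hz[2] <- min(band_hz[2], rate_hz / 2)
  sel <- freq >= band_hz[1] & freq <= band_hz[2]
  df <- mean(diff(freq))
  pn <- sum(psd[sel]) * df
  list(P_N_db = 10 * log10(pn), P_N_hz2 = pn,
       psd = data.frame(freq = freq, psd = psd))
}
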