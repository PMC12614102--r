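# Transient detectors on the demodulated frequency trace: large frequency
# jumps (proximity effects) and wing-flap dips.

#' Detect radio-frequency jumps
#'
#' Jumps are deviations larger than 50 kHz from the running median of the
#' tracking frequency (0.2 s sliding windows, centered, edge-truncated).
#' Threshold-crossing runs separated by less than 50 ms are concatenated;
#' the jump amplitude is the maximum absolute deviation within the event.
#' Being median-relative, detection is invariant to a constant offset.
#'
#' @param x tracking-frequency trace (Hz); carrier offset irrelevant.
#' @param rate_hz sample rate of `x`.
#' @param threshold_hz deviation threshold (default 50 kHz).
#' @param median_window_s running-median window (default 0.2 s).
#' @param merge_gap_s events closer than this are merged (default 50 ms).
#' @return data.frame with `onset`, `offset` (s) and `amplitude_hz`.
#' @export
detect_jumps <- function(x, rate_hz, threshold_hz = 5e4,
                         median_window_s = 0.2, merge_gap_s = 0.05) {
  n <- length(x)
  k <- round(median_window_s * rate_hz)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, if (n %% 2 == 0) n - 1 else n)
  med <- if (k >= 3) runmed(x, k, endrule = "median") else x * 0 + median(x)
  dev <- x - med
  hit <- abs(dev) > threshold_hz
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude_hz = numeric(0))
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  s <- starts[r$values]; e <- ends[r$values]
  # merge runs separated by less than merge_gap_s
  if (length(s) > 1) {
    gap <- (s[-1] - e[-length(e)] - 1L) / rate_hz
    keep_new <- c(TRUE, gap >= merge_gap_s)
    grp <- cumsum(keep_new)
    s <- tapply(s, grp, min); e <- tapply(e, grp, max)
  }
  amp <- mapply(function(i0, i1) max(abs(dev[i0:i1])), s, e)
  data.frame(onset = (s - 1L) / rate_hz, offset = e / rate_hz,
             amplitude_hz = as.numeric(amp), row.names = NULL)
}

#' Detect wing-flap dips
#'
#' Wing flaps produce brief downward dips of the tracking frequency. The
#' trace is down-sampled, differentiated, and an event is recognized when
#' the derivative first falls below `-W` (W = 60 MHz/s) and subsequently
#' rises above `+W` within a 2-12 ms window after the initial crossing. The
#' dip time is the minimum of the original-rate trace between the crossings.
#' Events are validated against the signal range in a +/-10.5 ms window
#' (one video frame period) around the dip: ranges below 200 kHz are
#' discarded and abrupt changes above 1,000 kHz excluded (`valid = FALSE`).
#'
#' @param x tracking-frequency trace (Hz).
#' @param rate_hz sample rate of `x` (the logged demodulated rate).
#' @param downsample down-sampling factor before differentiation (32).
#' @param W_hz_per_s derivative threshold (Hz/s).
#' @param window_s length-2 vector: allowed delay range of the positive
#'   crossing after the negative one (s).
#' @param range_bounds_hz length-2 vector of signal-range validity bounds.
#' @param range_window_s full width of the range-check window (s).
#' @return data.frame with `dip_time` (s), `signal_range_hz`, `valid`.
#' @export
detect_wing_flaps <- function(x, rate_hz, downsample = 32L, W_hz_per_s = 6e7,
                              window_s = c(0.002, 0.012),
                              range_bounds_hz = c(2e5, 1e6),
                              range_window_s = 0.021) {
  idx <- seq(1L, length(x), by = downsample)
  xd <- x[idx]
  rd <- rate_hz / downsample
  if (rd < 2 / max(window_s))
    stop("downsampled rate too low for the crossing window")
  d <- diff(xd) * rd                      # derivative at the downsampled rate
  td <- (idx[-1] - 1L) / rate_hz          # time of each derivative sample
  neg <- which(d < -W_hz_per_s)
  empty <- data.frame(dip_time = numeric(0), signal_range_hz = numeric(0),
                      valid = logical(0))
  if (!length(neg)) return(empty)
  out <- list()
  i <- 1L
  while (i <= length(neg)) {
    i0 <- neg[i]
    lo_t <- td[i0] + window_s[1]; hi_t <- td[i0] + window_s[2]
    cand <- which(d > W_hz_per_s & td >= lo_t & td <= hi_t & seq_along(d) > i0)
    if (length(cand)) {
      i1 <- cand[1]
      # dip minimum on the original-rate trace between the crossings
      j0 <- idx[i0]; j1 <- min(length(x), idx[i1 + 1L])
      jmin <- j0 - 1L + which.min(x[j0:j1])
      dip_t <- (jmin - 1L) / rate_hz
      half <- range_window_s / 2
      w0 <- max(1L, floor((dip_t - half) * rate_hz) + 1L)
      w1 <- min(length(x), ceiling((dip_t + half) * rate_hz) + 1L)
      rng <- max(x[w0:w1]) - min(x[w0:w1])
      out[[length(out) + 1L]] <-
        data.frame(dip_time = dip_t, signal_range_hz = rng,
                   valid = rng >= range_bounds_hz[1] & rng <= range_bounds_hz[2])
      # resume after the positive crossing
      i <- i + 1L
      while (i <= length(neg) && neg[i] <= i1) i <- i + 1L
    } else {
      # skip the rest of this below-threshold run
      i <- i + 1L
      while (i <= length(neg) && i > 1L && neg[i] == neg[i - 1L] + 1L)
        i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
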