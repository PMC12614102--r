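# Shared-clock timeline arithmetic and sub-frame-rate phase reconstruction:
# all acquisition devices derive their sample triggers from one base clock,
# so audio, demodulated radio, and video timelines are related by exact
# integer divisors.

#' Clock plan from shared divisors
#'
#' The receiver's base clock (200 MHz) divided by 2^13 gives the audio
#' sample rate 24,414.0625 Hz (prints as 24.414 kHz); a further division by
#' 2^9 gives the 47.684 Hz video frame rate, so one video frame spans
#' exactly 512 audio (= logged radio) samples.
#'
#' @param base_hz base clock (Hz).
#' @param audio_div divisor base -> audio rate.
#' @param video_div divisor audio -> video rate.
#' @return object of class `clock_plan` with `audio_rate_hz`,
#'   `video_rate_hz`, `samples_per_frame`.
#' @export
clock_plan <- function(base_hz = 2e8, audio_div = 2^13, video_div = 2^9) {
  stopifnot(base_hz > 0, audio_div >= 1, video_div >= 1)
  audio <- base_hz / audio_div
  structure(list(base_hz = base_hz, audio_div = audio_div,
                 video_div = video_div, audio_rate_hz = audio,
                 video_rate_hz = audio / video_div,
                 samples_per_frame = video_div),
            class = "clock_plan")
}

#' @export
print.clock_plan <- function(x, ...) {
  cat(sprintf("<clock_plan> base %.6g Hz; audio %.4f Hz; video %.3f Hz; %d samples/frame\n",
              x$base_hz, x$audio_rate_hz, x$video_rate_hz,
              as.integer(x$samples_per_frame)))
  invisible(x)
}

#' Video frame timeline
#'
#' Frame-stamp skeletons for a recording: exposure onsets on the exact
#' video-rate grid starting at t = 0, with the (short) exposure window
#' attached. Exposure is much shorter than the frame period, which is what
#' makes sub-frame phase reconstruction possible.
#'
#' @param plan a [clock_plan()].
#' @param duration_s timeline duration (s).
#' @param exposure_s exposure time per frame (default 3 ms).
#' @return data.frame `frame_index` (0-based), `exposure_onset` (s),
#'   `exposure_s`.
#' @export
timestamp_frames <- function(plan, duration_s, exposure_s = 0.003) {
  stopifnot(inherits(plan, "clock_plan"), duration_s > 0)
  n <- floor(duration_s * plan$video_rate_hz) + 1L
  onset <- (seq_len(n) - 1L) / plan$video_rate_hz
  keep <- onset < duration_s
  data.frame(frame_index = seq_len(n)[keep] - 1L,
             exposure_onset = onset[keep],
             exposure_s = exposure_s)
}

#' Assign wing-flap phase bins to video frames
#'
#' For each valid wing-flap dip, the frame whose exposure onset is nearest
#' the dip minimum is the first event frame and the subsequent frame the
#' second. Each event frame is time-stamped by the lag between its exposure
#' onset and the dip minimum; lags are wrapped modulo the frame period and
#' quantized into `n_bins` phase bins. Because dips are asynchronous to the
#' camera, the lags sample the flap cycle uniformly, giving a temporal
#' resolution of `n_bins / 2` times the camera's two frames per cycle.
#'
#' @param events data.frame from [detect_wing_flaps()] (rows with
#'   `valid == FALSE` are dropped).
#' @param frames data.frame from [timestamp_frames()].
#' @param n_bins number of phase bins (default 8).
#' @return data.frame `event`, `frame_index`, `role` ("first"/"second"),
#'   `lag_s`, `bin` (0-based); attribute `n_skipped` counts events outside
#'   the frame timeline (skipped with a warning).
#' @export
assign_phase_bins <- function(events, frames, n_bins = 8L) {
  stopifnot(nrow(frames) >= 2)
  ev <- events[events$valid %||% TRUE, , drop = FALSE]
  period <- frames$exposure_onset[2] - frames$exposure_onset[1]
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(ev))) {
    dip <- ev$dip_time[i]
    j <- which.min(abs(frames$exposure_onset - dip))
    if (dip < frames$exposure_onset[1] - period / 2 ||
        j >= nrow(frames)) {       # no subsequent frame available
      skipped <- skipped + 1L
      next
    }
    for (role in c("first", "second")) {
      jj <- if (role == "first") j else j + 1L
      lag <- frames$exposure_onset[jj] - dip
      ph <- ((lag %% period) + period) %% period
      bin <- floor(n_bins * ph / period)
      out[[length(out) + 1L]] <-
        data.frame(event = i, frame_index = frames$frame_index[jj],
                   role = role, lag_s = lag, bin = as.integer(bin))
    }
  }
  if (skipped > 0)
    warning(sprintf("%d event(s) outside the frame timeline skipped", skipped))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event = integer(0), frame_index = integer(0),
               role = character(0), lag_s = numeric(0), bin = integer(0))
  attr(res, "n_skipped") <- skipped
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
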