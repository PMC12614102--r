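# Shared fixture builders. Everything is generated in code at test time.

FZ_DESK <- 100e6 / 128       # desk intermediate-band sample rate
LO_HZ <- 300e6
CENTER_HZ <- 300.1e6

# Four-antenna complex tone at a fixed offset from the channel center, with
# per-antenna phases/gains and independent circular Gaussian noise.
make_tone_signals <- function(f_offset = 1e4, phases = c(0, 0, 0, 0),
                              gains = c(1, 1, 1, 1), noise_sigma = 0,
                              duration = 0.3, fz = FZ_DESK, lo = LO_HZ,
                              center = CENTER_HZ, seed = 1) {
  n <- floor(duration * fz)
  f <- (center - lo) + f_offset
  phi <- (2 * pi * f / fz * (seq_len(n) - 1)) %% (2 * pi)
  set.seed(seed)
  z <- lapply(1:4, function(a) {
    za <- gains[a] * exp(1i * (phi + phases[a]))
    if (noise_sigma > 0)
      za <- za + noise_sigma / sqrt(2) *
        complex(real = rnorm(n), imaginary = rnorm(n))
    za
  })
  names(z) <- c("A", "B", "C", "D")
  structure(list(z = z, rate_hz = fz, lo_hz = lo, duration_s = duration),
            class = "signal_set")
}

raised_cosine_test <- function(t, center, width) {
  u <- (t - center) / width
  ifelse(abs(u) < 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# NCO phase trajectory matching render_antennas()' accumulation convention.
render_phase <- function(f_rel_hz, n, fz) {
  (2 * pi * cumsum(rep(f_rel_hz, n) / fz)) %% (2 * pi)
}

# Simulate one transmitter end-to-end and demodulate it.
sim_and_demod <- function(trace, tspec = transmitter_spec(),
                          channel = NULL, cfg = demod_config("desk"),
                          noise_sigma = 0, seed = 1, fz = FZ_DESK,
                          lo = LO_HZ) {
  if (is.null(channel))
    channel <- channel_realization(c(0, trace$duration_s), amp = 1,
                                   phase = 0, noise_sigma = noise_sigma)
  omega_t <- fm_encode(trace, tspec)
  sig <- render_antennas(omega_t, channel, lo_hz = lo, rate_hz = fz,
                         seed = seed)
  out <- run_demodulator(sig, cfg)
  list(trace = trace, omega_t = omega_t, signals = sig, demod = out)
}
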