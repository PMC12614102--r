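# PLL demodulator: DDC contract, lock-in, phase compensation, limiting
# range, loss detection, demodulated signal, closed-loop measurement.

test_that("ddc shifts a tone to DC and honors the phase offset", {
  fz <- FZ_DESK; n <- 2^16
  f0 <- 3e4
  z <- exp(1i * render_phase(f0, n, fz))
  u0 <- ddc(z, fz, f0, decimation = 8, passband_hz = 1e4)
  mid <- 1000:7000
  expect_lt(sd(Arg(u0[mid])), 1e-6)                   # constant phase
  expect_equal(mean(Mod(u0[mid])), 1, tolerance = 1e-3)  # tone amplitude
  u90 <- ddc(z, fz, f0, phase_offset = pi / 2, decimation = 8,
             passband_hz = 1e4)
  rot <- u90[mid] / u0[mid]
  expect_equal(Arg(mean(rot)), pi / 2, tolerance = 1e-9)
})

test_that("ddc attenuates a tone 1.2x the passband by >= 60 dB", {
  fz <- FZ_DESK; n <- 2^16
  pb <- 1e4
  zin <- exp(1i * render_phase(0.5 * pb, n, fz))
  zout <- exp(1i * render_phase(1.2 * pb, n, fz))
  mid <- 1000:7000
  p_in <- mean(Mod(ddc(zin, fz, 0, decimation = 8, passband_hz = pb)[mid])^2)
  p_out <- mean(Mod(ddc(zout, fz, 0, decimation = 8, passband_hz = pb)[mid])^2)
  expect_gte(10 * log10(p_in / p_out), 60)
  expect_error(ddc(c(1 + 1i, NA), fz, 0), "non-finite")
})

test_that("PLL locks onto an offset tone; compensation aligns antennas", {
  sig <- make_tone_signals(f_offset = 1e4, phases = c(0, pi / 2, pi, 3 * pi / 2),
                           duration = 0.3)
  out <- run_demodulator(sig, demod_config("desk"))
  n <- length(out$omega)
  tail_i <- floor(n * 0.8):n
  expect_lt(max(abs(out$omega[tail_i] - (CENTER_HZ + 1e4))), 1)
  expect_true(all(out$lock))
  nb <- nrow(out$alpha)
  expect_lt(max(abs(out$alpha[nb, ])), 1e-2)     # compensation fixed point
  expect_equal(unname(Mod(out$r_mean[nb, "M"])), 4, tolerance = 1e-3)
  # compensation off: destructive sum stays destructive
  out0 <- run_demodulator(sig, demod_config("desk", gamma = 0))
  expect_lt(Mod(out0$r_mean[nrow(out0$r_mean), "M"]), 1e-3)
})

test_that("theta is continuously unwrapped during acquisition", {
  sig <- make_tone_signals(f_offset = 4e4, duration = 0.02)
  out <- run_demodulator(sig, demod_config("desk", log_decimation = 1L))
  expect_lt(max(abs(diff(out$theta))), pi)
})

test_that("out-of-range excursion pins omega at the limit, lock drops", {
  # transmitter ramps to center + 2*limit and stays out: the loss interval
  # must match the commanded window to within one log sample at both ends
  fz <- FZ_DESK
  dur <- 0.6
  rate_tr <- 24414.0625
  nt <- floor(dur * rate_tr)
  tt <- (seq_len(nt) - 1) / rate_tr
  lim <- 3e4
  exc <- approx(c(0, 0.3, 0.4, dur), 2 * lim * c(0, 0, 1, 1), xout = tt)$y
  om <- structure(CENTER_HZ + exc, rate_hz = rate_tr)
  chan <- channel_realization(c(0, dur), amp = 1)
  sig <- render_antennas(om, chan, lo_hz = LO_HZ, rate_hz = fz, seed = 1)
  cfg <- demod_config("desk", limit_hz = lim)
  out <- run_demodulator(sig, cfg)
  t_log <- (seq_along(out$omega) - 1) / out$rate_omega
  on_true <- 0.35                       # ramp crosses center + lim here
  inside <- t_log > on_true + 0.005
  expect_true(all(out$omega[inside] == CENTER_HZ + lim))   # pinned exactly
  expect_true(all(!out$lock[inside]))
  expect_true(all(out$lock[t_log < on_true - 0.005]))
  loss <- detect_tracking_loss(out$omega, out$rate_omega, CENTER_HZ, lim)
  expect_identical(nrow(loss$intervals), 1L)
  expect_equal(loss$intervals$onset[1], on_true,
               tolerance = 1.5 / out$rate_omega)
  expect_equal(loss$intervals$offset[1], dur,
               tolerance = 1.5 / out$rate_omega)
})

test_that("PLL relocks after an out-and-back excursion", {
  fz <- FZ_DESK
  dur <- 0.8
  rate_tr <- 24414.0625
  tt <- (seq_len(floor(dur * rate_tr)) - 1) / rate_tr
  lim <- 3e4
  exc <- approx(c(0, 0.2, 0.25, 0.45, 0.5, dur), 2 * lim * c(0, 0, 1, 1, 0, 0),
                xout = tt)$y
  om <- structure(CENTER_HZ + exc, rate_hz = rate_tr)
  chan <- channel_realization(c(0, dur), amp = 1)
  sig <- render_antennas(om, chan, lo_hz = LO_HZ, rate_hz = fz, seed = 1)
  out <- run_demodulator(sig, demod_config("desk", limit_hz = lim))
  t_log <- (seq_along(out$omega) - 1) / out$rate_omega
  mid <- t_log > 0.25 & t_log < 0.45
  expect_true(all(out$omega[mid] == CENTER_HZ + lim))
  # relocked: by 100 ms after reentry the tracking error is < 1 Hz
  late <- t_log > 0.575
  expect_lt(max(abs(out$omega[late] - CENTER_HZ)), 1)
})

test_that("tracking-loss detector arithmetic", {
  om <- rep(CENTER_HZ, 1000)
  loss <- detect_tracking_loss(om, 10, CENTER_HZ, 1e5)
  expect_identical(nrow(loss$intervals), 0L)
  expect_equal(loss$percent, 0)
  om[101:110] <- CENTER_HZ + 1e5       # 10 of 1000 samples = 1 s of 100 s
  loss <- detect_tracking_loss(om, 10, CENTER_HZ, 1e5)
  expect_identical(nrow(loss$intervals), 1L)
  expect_equal(loss$percent, 1.0)
  expect_equal(loss$intervals$onset, 10.0)
  expect_equal(loss$intervals$offset, 11.0)
})

test_that("demodulated_signal removes constants and slow drift", {
  fs <- 24414.0625
  om <- rep(3.001e8, 4096)
  y <- demodulated_signal(om, fs)
  expect_lt(max(abs(y[1000:3000])), 1e-6)
  t <- (seq_len(2^15) - 1) / fs
  om_drift <- 3.001e8 + 2e4 * t
  yd <- demodulated_signal(om_drift, fs)
  expect_lt(max(abs(yd[5000:28000])), 1)        # < 1 Hz residual
})

test_that("closed loop is low-pass; weaker gains give lower bandwidth", {
  cl <- measure_closed_loop(demod_config("desk"), probe_level = 2000,
                            seed = 2, duration_s = 0.25)
  bw <- attr(cl, "bw_3db_hz")
  expect_true(is.finite(bw))
  # coarse-grained monotone decrease above the -3 dB point
  above <- cl[cl$freq > bw, ]
  qs <- quantile(above$freq, c(0, 0.25, 0.5, 0.75, 1))
  gbin <- sapply(1:4, function(i)
    mean(above$gain[above$freq >= qs[i] & above$freq < qs[i + 1]]))
  expect_true(all(diff(gbin) < 0.05))
  expect_lt(gbin[4], 0.2)
  cl_slow <- measure_closed_loop(
    demod_config("desk", pid = c(kp = 400, ki = 0, kd = 0)),
    probe_level = 2000, seed = 2, duration_s = 0.25)
  expect_lt(attr(cl_slow, "bw_3db_hz"), bw)
  expect_error(measure_closed_loop(demod_config("desk"), probe_level = 0),
               "probe_level")
})

test_that("channel center outside the simulated band is rejected", {
  sig <- make_tone_signals(duration = 0.01)
  expect_error(run_demodulator(sig, demod_config("desk", center_hz = 301e6)),
               "outside simulated band")
})
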