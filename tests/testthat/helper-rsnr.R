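# Build a demod_output skeleton directly from rotated baseband samples,
# bypassing the receiver: used to test the RSNR accounting against closed
# forms. `r` is a list of four complex vectors (antennas A-D); M is their
# sample-wise sum.
fake_demod_from_r <- function(r, block = 512L, rate_bb = FZ_DESK / 8,
                              log_dec = 4L) {
  n <- length(r[[1]])
  nb <- n %/% block
  sources <- c("A", "B", "C", "D", "M")
  rM <- r[[1]] + r[[2]] + r[[3]] + r[[4]]
  all_r <- c(r, list(rM))
  r_mean <- matrix(0 + 0i, nb, 5, dimnames = list(NULL, sources))
  r_pow <- matrix(0, nb, 5, dimnames = list(NULL, sources))
  for (b in seq_len(nb)) {
    ix <- ((b - 1) * block + 1):(b * block)
    for (s in 1:5) {
      r_mean[b, s] <- mean(all_r[[s]][ix])
      r_pow[b, s] <- mean(Mod(all_r[[s]][ix])^2)
    }
  }
  cfg <- demod_config("desk", block = block, log_decimation = log_dec)
  structure(list(r_mean = r_mean, r_pow = r_pow,
                 block_rate = rate_bb / block, rate_bb = rate_bb,
                 rate_omega = rate_bb / log_dec, cfg = cfg),
            class = "demod_output")
}
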