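# Independent brute-force recount of the vocalization statistics, written
# as plainly as possible (explicit loops, no shared helpers) to serve as an
# oracle for voc_statistics().
brute_force_stats <- function(cons, tx, mic, first_mic = "Mic1",
                              bin_s = 96 / 24414.0625) {
  n <- nrow(cons)
  miss_tx <- 0L; miss_all <- 0L; miss_m1 <- 0L; unass <- 0L
  for (i in seq_len(n)) {
    if (cons$transmitter_tag[i] == "None") miss_tx <- miss_tx + 1L
    if (cons$firstmic_tag[i] == "None") miss_all <- miss_all + 1L
    if (cons$firstmic_tag[i] != "None" &&
        cons$firstmic_tag[i] != first_mic) miss_m1 <- miss_m1 + 1L
    if (cons$bird_tag[i] == "None") unass <- unass + 1L
  }
  ovl <- 0L
  for (i in seq_len(n)) {
    hit <- FALSE
    for (j in seq_len(n)) {
      if (i == j) next
      if (cons$bird_tag[i] == cons$bird_tag[j]) next
      lo <- max(cons$onset[i], cons$onset[j])
      hi <- min(cons$offset[i], cons$offset[j])
      if (hi - lo >= bin_s - 1e-12) hit <- TRUE
    }
    if (hit) ovl <- ovl + 1L
  }
  ct <- 0L
  for (i in seq_len(nrow(tx)))
    if (!tx$unsure[i] && tx$crosstalk[i] != "No") ct <- ct + 1L
  uns <- 0L
  for (i in seq_len(nrow(tx))) if (tx$unsure[i]) uns <- uns + 1L
  for (i in seq_len(nrow(mic))) if (mic$unsure[i]) uns <- uns + 1L
  list(n = n, miss_tx = miss_tx, miss_all = miss_all, miss_m1 = miss_m1,
       unass = unass, ovl = ovl, ct = ct, uns = uns)
}

expect_stats_match <- function(st, bf) {
  expect_identical(st$n_vocalizations, bf$n)
  expect_identical(st$n_missed_transmitter, bf$miss_tx)
  expect_identical(st$n_missed_all_mics, bf$miss_all)
  expect_identical(st$n_missed_mic1, bf$miss_m1)
  expect_identical(st$n_unassigned, bf$unass)
  expect_identical(st$n_overlapping, bf$ovl)
  expect_identical(st$n_crosstalk, bf$ct)
  expect_identical(st$n_uncertain, bf$uns)
}

# order-insensitive comparison of consolidated tables
expect_consolidated_equal <- function(a, b, tol = 1e-9) {
  ord <- function(d) d[order(d$onset, d$offset, d$bird_tag), , drop = FALSE]
  a <- ord(a); b <- ord(b)
  expect_identical(nrow(a), nrow(b))
  expect_equal(a$onset, b$onset, tolerance = tol)
  expect_equal(a$offset, b$offset, tolerance = tol)
  expect_identical(a$bird_tag, b$bird_tag)
  expect_identical(a$transmitter_tag, b$transmitter_tag)
  expect_identical(a$firstmic_tag, b$firstmic_tag)
}
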