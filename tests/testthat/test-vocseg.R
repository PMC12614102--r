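# Vocal segment consolidation, statistics, synthetic annotation generator,
# spectrogram, and selection-table round trip.

BIN_S <- 96 / 24414.0625

test_that("consolidation of empty inputs is empty", {
  out <- consolidate(vocal_segments(), vocal_segments())
  expect_identical(nrow(out), 0L)
})

test_that("a 1:1 pair becomes the union interval with both tags", {
  tx <- vocal_segments("bird01", 1.0, 1.4)
  mic <- vocal_segments("Mic1", 1.05, 1.5)
  out <- consolidate(tx, mic)
  expect_identical(nrow(out), 1L)
  expect_equal(out$onset, 1.0)
  expect_equal(out$offset, 1.5)
  expect_identical(out$bird_tag, "bird01")
  expect_identical(out$transmitter_tag, "bird01")
  expect_identical(out$firstmic_tag, "Mic1")
})

test_that("a mic segment spanning two transmitter segments is split", {
  tx <- vocal_segments(c("bird01", "bird02"), c(1.0, 1.5), c(1.3, 1.9))
  mic <- vocal_segments("Mic2", 0.95, 1.95)
  out <- consolidate(tx, mic)
  expect_identical(nrow(out), 2L)
  expect_equal(out$onset, c(1.0, 1.5))       # split at transmitter bounds
  expect_equal(out$offset, c(1.3, 1.9))
  expect_identical(out$firstmic_tag, c("Mic2", "Mic2"))
  expect_identical(out$transmitter_tag, c("bird01", "bird02"))
})

test_that("unpaired segments keep their intervals and miss tags", {
  tx <- vocal_segments("bird01", 1.0, 1.2)
  mic <- vocal_segments("Mic1", 5.0, 5.2)
  out <- consolidate(tx, mic, bird_guess = "bird02")
  expect_identical(nrow(out), 2L)
  expect_identical(out$firstmic_tag, c("None", "Mic1"))
  expect_identical(out$transmitter_tag, c("bird01", "None"))
  expect_identical(out$bird_tag, c("bird01", "bird02"))   # guess applied
  # invariant: a transmitter tag implies the same bird tag
  has_tx <- out$transmitter_tag != "None"
  expect_identical(out$bird_tag[has_tx], out$transmitter_tag[has_tx])
})

test_that("crosstalk and unsure segments are excluded up front", {
  tx <- vocal_segments(c("bird01", "bird02", "bird01"),
                       c(1.0, 1.02, 3.0), c(1.2, 1.21, 3.1),
                       crosstalk = c("No", "bird01", "No"),
                       unsure = c(FALSE, FALSE, TRUE))
  out <- consolidate(tx, vocal_segments())
  expect_identical(nrow(out), 1L)            # only the clean segment
  expect_equal(out$onset, 1.0)
})

test_that("annotation-invariant violations raise errors", {
  tx2 <- vocal_segments(c("bird01", "bird01"), c(1.0, 1.1), c(1.2, 1.3))
  expect_error(consolidate(tx2, vocal_segments()), "overlapping transmitter")
  tx <- vocal_segments("bird01", 1.0, 2.0)
  mic2 <- vocal_segments(c("Mic1", "Mic2"), c(1.0, 1.5), c(1.4, 1.9))
  expect_error(consolidate(tx, mic2), "multiple microphone")
})

test_that("every clean transmitter segment is covered exactly once", {
  gen <- generate_annotations(n_birds = 3, n_mics = 2, duration_s = 120,
                              overlap_prob = 0.3, miss_tx_prob = 0.1,
                              miss_allmic_prob = 0.1, seed = 4)
  out <- consolidate(gen$transmitter, gen$mics)
  tx <- gen$transmitter
  tx <- tx[!tx$unsure & tx$crosstalk == "No", ]
  for (i in seq_len(nrow(tx))) {
    cover <- which(out$transmitter_tag == tx$source[i] &
                     out$onset <= tx$onset[i] + 1e-9 &
                     out$offset >= tx$offset[i] - 1e-9)
    expect_identical(length(cover), 1L)
  }
})

test_that("consolidation is idempotent on non-overlapping output", {
  gen <- generate_annotations(n_birds = 2, n_mics = 2, duration_s = 90,
                              miss_tx_prob = 0.15, miss_allmic_prob = 0.1,
                              seed = 7)
  out1 <- consolidate(gen$transmitter, gen$mics)
  tx2 <- vocal_segments(out1$bird_tag[out1$transmitter_tag != "None"],
                        out1$onset[out1$transmitter_tag != "None"],
                        out1$offset[out1$transmitter_tag != "None"])
  mic2 <- vocal_segments(out1$firstmic_tag[out1$firstmic_tag != "None"],
                         out1$onset[out1$firstmic_tag != "None"],
                         out1$offset[out1$firstmic_tag != "None"])
  out2 <- consolidate(tx2, mic2)
  keep <- out1$transmitter_tag != "None" | out1$firstmic_tag != "None"
  expect_consolidated_equal(out2, out1[keep, c("onset", "offset", "bird_tag",
                                               "transmitter_tag",
                                               "firstmic_tag")])
})

test_that("statistics trivials", {
  st <- voc_statistics(consolidate(vocal_segments(), vocal_segments()),
                       vocal_segments(), vocal_segments())
  expect_identical(st$n_vocalizations, 0L)
  expect_identical(st$n_overlapping, 0L)
  # three of 100 missing the transmitter tag
  cons <- data.frame(onset = seq(0, by = 1, length.out = 100),
                     offset = seq(0.5, by = 1, length.out = 100),
                     bird_tag = "bird01", transmitter_tag = "bird01",
                     firstmic_tag = "Mic1")
  cons$transmitter_tag[c(5, 50, 95)] <- "None"
  st <- voc_statistics(cons, vocal_segments(), vocal_segments(),
                       mic_order = "Mic1")
  expect_identical(st$n_missed_transmitter, 3L)
  expect_equal(st$pct_missed_transmitter, 3.0)
})

test_that("disjoint segments have no overlaps; one shared bin makes two", {
  cons <- data.frame(onset = c(1, 2), offset = c(1.5, 2.5),
                     bird_tag = c("bird01", "bird02"),
                     transmitter_tag = c("bird01", "bird02"),
                     firstmic_tag = "Mic1")
  st <- voc_statistics(cons, vocal_segments(), vocal_segments())
  expect_identical(st$n_overlapping, 0L)
  cons$onset[2] <- 1.5 - BIN_S               # share exactly one bin
  st2 <- voc_statistics(cons, vocal_segments(), vocal_segments())
  expect_identical(st2$n_overlapping, 2L)    # both members count
})

test_that("generator: exact recovery without misses; determinism", {
  gen <- generate_annotations(n_birds = 2, n_mics = 2, duration_s = 60,
                              overlap_prob = 0, miss_tx_prob = 0,
                              miss_allmic_prob = 0, seed = 12)
  out <- consolidate(gen$transmitter, gen$mics)
  expect_consolidated_equal(out, gen$ground_truth)
  gen2 <- generate_annotations(n_birds = 2, n_mics = 2, duration_s = 60,
                               overlap_prob = 0, miss_tx_prob = 0,
                               miss_allmic_prob = 0, seed = 12)
  expect_identical(gen$transmitter, gen2$transmitter)
  expect_identical(gen$mics, gen2$mics)
})

test_that("generator ground truth matches consolidate under misses/overlaps", {
  for (seed in 1:5) {
    gen <- generate_annotations(n_birds = 3, n_mics = 3, duration_s = 100,
                                overlap_prob = 0.25, miss_tx_prob = 0.15,
                                miss_mic1_prob = 0.2, miss_allmic_prob = 0.1,
                                crosstalk_prob = 0.1, unsure_prob = 0.05,
                                seed = seed)
    out <- consolidate(gen$transmitter, gen$mics)
    expect_consolidated_equal(out, gen$ground_truth)
    st <- voc_statistics(out, gen$transmitter, gen$mics,
                         mic_order = c("Mic1", "Mic2", "Mic3"))
    bf <- brute_force_stats(out, gen$transmitter, gen$mics)
    expect_stats_match(st, bf)
  }
})

test_that("measured miss rates recover the generator parameters", {
  p_tx <- 0.2; p_all <- 0.1
  gen <- generate_annotations(n_birds = 2, n_mics = 2, duration_s = 2000,
                              rate_per_s = 1, overlap_prob = 0,
                              miss_tx_prob = p_tx, miss_allmic_prob = p_all,
                              seed = 13)
  out <- consolidate(gen$transmitter, gen$mics)
  st <- voc_statistics(out, gen$transmitter, gen$mics,
                       mic_order = c("Mic1", "Mic2"))
  n <- st$n_vocalizations
  ci <- function(p) 3 * sqrt(p * (1 - p) / n) * 100
  expect_lt(abs(st$pct_missed_transmitter - 100 * p_tx), ci(p_tx))
  expect_lt(abs(st$pct_missed_all_mics - 100 * p_all), ci(p_all))
})

test_that("spectrogram basics", {
  fs <- 24414.0625
  t <- (seq_len(2^14) - 1) / fs
  tone <- sin(2 * pi * 3000 * t)
  sp <- spectrogram(tone, fs)
  expect_equal(sp$bin_s, 96 / fs)
  expect_identical(ncol(sp$mag), as.integer((2^14 - 384) %/% 96 + 1))
  peak_rows <- apply(sp$mag, 2, which.max)
  expect_true(all(abs(sp$freq[peak_rows] - 3000) < fs / 384 * 1.5))
  set.seed(2)
  noisy <- tone + rnorm(length(tone), sd = 0.1)
  spn <- spectrogram(noisy, fs)
  row3k <- which.min(abs(spn$freq - 3000))
  expect_gt(mean(spn$mag[row3k, ]), 10 * mean(spn$mag[-row3k, ]))
})

test_that("selection tables round-trip through TSV", {
  gen <- generate_annotations(duration_s = 30, crosstalk_prob = 0.2,
                              unsure_prob = 0.1, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_selection_table(gen$transmitter, path)
  back <- read_selection_table(path)
  expect_equal(back$onset, gen$transmitter$onset)
  expect_identical(back$source, gen$transmitter$source)
  expect_identical(back$crosstalk, gen$transmitter$crosstalk)
  expect_identical(back$unsure, gen$transmitter$unsure)
})
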