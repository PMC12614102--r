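# Multichannel vocal-annotation data model: transmitter-based and
# microphone-based vocal segments, consolidation into per-vocalization
# records with Bird/Transmitter/FirstMic attribution, and summary
# statistics. A seeded synthetic annotation generator provides ground truth
# for end-to-end verification.

#' Construct a vocal-segment table
#'
#' @param source channel name per segment (transmitter channel = bird name,
#'   or microphone name).
#' @param onset,offset segment boundaries (s), onset < offset.
#' @param crosstalk `"No"`, or the transmitter channel of the bird that
#'   generated the crosstalk (transmitter segments only).
#' @param unsure logical; uncertain segments are treated as non-vocal noise
#'   and excluded from all statistics except the uncertainty count.
#' @return data.frame with class `vocal_segments`.
#' @export
vocal_segments <- function(source = character(0), onset = numeric(0),
                           offset = numeric(0), crosstalk = "No",
                           unsure = FALSE) {
  n <- length(onset)
  df <- data.frame(source = rep_len(as.character(source), n),
                   onset = onset, offset = offset,
                   crosstalk = rep_len(as.character(crosstalk), n),
                   unsure = rep_len(as.logical(unsure), n))
  if (n && any(df$onset >= df$offset)) stop("onset must precede offset")
  class(df) <- c("vocal_segments", "data.frame")
  df
}

seg_overlap <- function(on1, off1, on2, off2) {
  pmax(0, pmin(off1, off2) - pmax(on1, on2))
}

#' Consolidate transmitter- and microphone-based vocal segments
#'
#' Merges the two annotation modalities into one record per vocalization.
#' Unsure segments and crosstalk-tagged transmitter segments are excluded
#' first. A microphone segment and a transmitter segment are *paired* when
#' they overlap by at least one spectrogram bin (`bin_s`). Rules:
#' \itemize{
#'   \item mic paired with exactly one transmitter segment: one consolidated
#'     segment spanning the union interval; Bird and Transmitter tags are the
#'     transmitter channel, FirstMic is the microphone channel.
#'   \item unpaired transmitter segment: same interval, FirstMic `"None"`.
#'   \item unpaired mic segment: same interval, Transmitter `"None"`, Bird
#'     from `bird_guess` (default `"None"`), FirstMic the mic channel.
#'   \item mic paired with several transmitter segments: one consolidated
#'     segment per transmitter segment, split at the transmitter-segment
#'     boundaries (automated stand-in for manually chosen onsets).
#'   \item a transmitter segment paired with several mic segments is an
#'     error (never encountered in practice; annotation convention places
#'     each vocalization on a single first microphone).
#' }
#'
#' @param tx transmitter-based [vocal_segments()].
#' @param mic microphone-based [vocal_segments()].
#' @param bin_s pairing resolution: one spectrogram bin
#'   (default 96 / 24,414.0625 s).
#' @param bird_guess optional per-mic-segment bird guess (character,
#'   recycled) used for unpaired mic segments.
#' @return data.frame `onset`, `offset`, `bird_tag`, `transmitter_tag`,
#'   `firstmic_tag`, sorted by onset.
#' @export
consolidate <- function(tx, mic, bin_s = 96 / (200e6 / 2^13),
                        bird_guess = "None") {
  tx <- tx[!tx$unsure & tx$crosstalk == "No", , drop = FALSE]
  mic <- mic[!mic$unsure, , drop = FALSE]
  # transmitter annotations may not overlap within one channel
  for (ch in unique(tx$source)) {
    s <- tx[tx$source == ch, , drop = FALSE]
    s <- s[order(s$onset), ]
    if (nrow(s) > 1 && any(s$onset[-1] < s$offset[-nrow(s)] - 1e-12))
      stop(sprintf("overlapping transmitter segments on channel %s", ch))
  }
  guess <- rep_len(as.character(bird_guess), max(1L, nrow(mic)))
  nt <- nrow(tx); nm <- nrow(mic)
  pairs <- if (nt && nm) {
    ov <- outer(seq_len(nm), seq_len(nt), function(i, j)
      seg_overlap(mic$onset[i], mic$offset[i], tx$onset[j], tx$offset[j]))
    ov >= bin_s - 1e-12
  } else matrix(FALSE, nm, nt)
  if (nt && any(colSums(pairs) > 1))
    stop("transmitter segment paired with multiple microphone segments")
  rows <- list()
  add <- function(onset, offset, bird, txch, firstmic)
    rows[[length(rows) + 1L]] <<- data.frame(
      onset = onset, offset = offset, bird_tag = bird,
      transmitter_tag = txch, firstmic_tag = firstmic)
  for (i in seq_len(nm)) {
    js <- which(pairs[i, ])
    if (length(js) == 0) {
      add(mic$onset[i], mic$offset[i], guess[i], "None", mic$source[i])
    } else if (length(js) == 1) {
      j <- js
      add(min(mic$onset[i], tx$onset[j]), max(mic$offset[i], tx$offset[j]),
          tx$source[j], tx$source[j], mic$source[i])
    } else {
      for (j in js)
        add(tx$onset[j], tx$offset[j], tx$source[j], tx$source[j],
            mic$source[i])
    }
  }
  for (j in seq_len(nt)) {
    if (nm == 0 || !any(pairs[, j]))
      add(tx$onset[j], tx$offset[j], tx$source[j], tx$source[j], "None")
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset = numeric(0), offset = numeric(0),
               bird_tag = character(0), transmitter_tag = character(0),
               firstmic_tag = character(0))
  res <- res[order(res$onset, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Vocalization statistics
#'
#' The per-file summary counts over consolidated segments: vocalizations,
#' misses per modality, unassigned and overlapping vocalizations; plus
#' crosstalk and uncertainty counts over the raw segment tables.
#' "Missed on the first microphone" counts consolidated segments whose
#' FirstMic tag is neither the first microphone in `mic_order` nor `"None"`.
#' A vocalization "overlaps" when it shares at least one spectrogram bin
#' with a consolidated segment carrying a different bird tag (both members
#' of such a pair are counted).
#'
#' @param consolidated output of [consolidate()].
#' @param tx,mic the raw segment tables (incl. Unsure/Crosstalk rows).
#' @param mic_order microphone names in order; first entry defines "Mic1".
#' @param bin_s spectrogram-bin duration (s), the overlap quantum.
#' @return object of class `voc_stats`: named list of counts and
#'   percentages (percent of consolidated vocalizations).
#' @export
voc_statistics <- function(consolidated, tx, mic,
                           mic_order = sort(unique(mic$source)),
                           bin_s = 96 / (200e6 / 2^13)) {
  n <- nrow(consolidated)
  first_mic <- if (length(mic_order)) mic_order[1] else "Mic1"
  n_missed_tx <- sum(consolidated$transmitter_tag == "None")
  n_missed_all_mics <- sum(consolidated$firstmic_tag == "None")
  n_missed_mic1 <- sum(consolidated$firstmic_tag != first_mic &
                         consolidated$firstmic_tag != "None")
  n_unassigned <- sum(consolidated$bird_tag == "None")
  n_overlapping <- 0L
  if (n > 1) {
    ovl <- logical(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (consolidated$bird_tag[i] != consolidated$bird_tag[j] &&
          seg_overlap(consolidated$onset[i], consolidated$offset[i],
                      consolidated$onset[j], consolidated$offset[j]) >=
            bin_s - 1e-12) {
        ovl[i] <- TRUE; ovl[j] <- TRUE
      }
    }
    n_overlapping <- sum(ovl)
  }
  n_crosstalk <- sum(tx$crosstalk != "No" & !tx$unsure)
  n_uncertain <- sum(tx$unsure) + sum(mic$unsure)
  pct <- function(k) if (n > 0) 100 * k / n else NA_real_
  structure(list(
    n_vocalizations = n,
    n_missed_transmitter = n_missed_tx, pct_missed_transmitter = pct(n_missed_tx),
    n_missed_all_mics = n_missed_all_mics, pct_missed_all_mics = pct(n_missed_all_mics),
    n_missed_mic1 = n_missed_mic1, pct_missed_mic1 = pct(n_missed_mic1),
    n_unassigned = n_unassigned, pct_unassigned = pct(n_unassigned),
    n_overlapping = n_overlapping, pct_overlapping = pct(n_overlapping),
    n_crosstalk = n_crosstalk, pct_crosstalk = pct(n_crosstalk),
    n_uncertain = n_uncertain), class = "voc_stats")
}

#' @export
print.voc_stats <- function(x, ...) {
  cat("Vocalization statistics\n")
  cat(sprintf("  # vocalizations           %d\n", x$n_vocalizations))
  f <- function(k, p) sprintf("%d (%.1f%%)", k, p)
  cat(sprintf("  # missed on tr. channel   %s\n",
              f(x$n_missed_transmitter, x$pct_missed_transmitter)))
  cat(sprintf("  # missed on all mics      %s\n",
              f(x$n_missed_all_mics, x$pct_missed_all_mics)))
  cat(sprintf("  # missed on first mic     %s\n",
              f(x$n_missed_mic1, x$pct_missed_mic1)))
  cat(sprintf("  # unassigned              %s\n",
              f(x$n_unassigned, x$pct_unassigned)))
  cat(sprintf("  # with overlaps           %s\n",
              f(x$n_overlapping, x$pct_overlapping)))
  cat(sprintf("  # with crosstalk          %s\n",
              f(x$n_crosstalk, x$pct_crosstalk)))
  cat(sprintf("  # uncertain segments      %d\n", x$n_uncertain))
  invisible(x)
}

#' Generate synthetic annotation tables with ground truth
#'
#' Emulates a multichannel annotation session: vocal events are placed in
#' well-separated clusters (a cluster is either one event or, with
#' probability `overlap_prob`, two temporally overlapping events of
#' different birds). Each event appears on its bird's transmitter channel
#' unless missed (probability `miss_tx_prob`); each cluster appears as one
#' microphone segment on its first visible microphone (the first microphone
#' unless displaced with probability `miss_mic1_prob`; entirely missed with
#' probability `miss_allmic_prob`). Optional crosstalk and unsure segments
#' are added. The intended consolidated outcome is recorded per cluster by
#' applying the consolidation rules to the generator's own event structure,
#' enabling end-to-end verification of [consolidate()] + [voc_statistics()].
#'
#' @param n_birds,n_mics channel counts.
#' @param duration_s session duration.
#' @param rate_per_s cluster rate (events per second, roughly).
#' @param overlap_prob probability a cluster holds two overlapping events.
#' @param miss_tx_prob per-event transmitter miss probability.
#' @param miss_mic1_prob probability the first visible mic is not Mic1.
#' @param miss_allmic_prob per-cluster probability of missing on all mics.
#' @param crosstalk_prob per-event probability of a crosstalk segment on
#'   another bird's transmitter channel.
#' @param unsure_prob per-cluster probability of an extra Unsure segment.
#' @param seed integer seed; identical seeds give identical tables.
#' @return list `transmitter`, `mics` ([vocal_segments()] tables),
#'   `ground_truth` (intended consolidated data.frame), `params`.
#' @export
generate_annotations <- function(n_birds = 2, n_mics = 3, duration_s = 120,
                                 rate_per_s = 0.4, overlap_prob = 0,
                                 miss_tx_prob = 0, miss_mic1_prob = 0,
                                 miss_allmic_prob = 0, crosstalk_prob = 0,
                                 unsure_prob = 0, seed = 1) {
  stopifnot(n_birds >= 1, n_mics >= 1, duration_s > 0, rate_per_s > 0)
  set.seed(seed)
  birds <- sprintf("bird%02d", seq_len(n_birds))
  mics <- sprintf("Mic%d", seq_len(n_mics))
  tx <- list(); mc <- list(); gt <- list()
  t_cur <- 0.3
  gap_mean <- max(0.25, 1 / rate_per_s - 0.2)
  while (TRUE) {
    t_cur <- t_cur + 0.25 + rexp(1, 1 / gap_mean)
    two <- n_birds >= 2 && runif(1) < overlap_prob
    d1 <- runif(1, 0.08, 0.3)
    if (t_cur + d1 + 1 > duration_s) break
    ev_bird <- sample(birds, if (two) 2 else 1)
    ev_on <- t_cur
    ev_off <- t_cur + d1
    if (two) {
      d2 <- runif(1, 0.08, 0.3)
      on2 <- t_cur + runif(1, 0.3, 0.7) * d1
      ev_on <- c(ev_on, on2); ev_off <- c(ev_off, on2 + d2)
    }
    tx_seen <- runif(length(ev_on)) >= miss_tx_prob
    mic_missed <- runif(1) < miss_allmic_prob
    first_mic <- if (n_mics >= 2 && runif(1) < miss_mic1_prob)
      sample(mics[-1], 1) else mics[1]
    jit <- function(k) runif(k, -0.01, 0.01)
    for (e in seq_along(ev_on)) {
      if (tx_seen[e])
        tx[[length(tx) + 1L]] <- data.frame(
          source = ev_bird[e], onset = ev_on[e] + jit(1) / 2,
          offset = ev_off[e] + jit(1) / 2, crosstalk = "No", unsure = FALSE)
      if (tx_seen[e] && n_birds >= 2 && runif(1) < crosstalk_prob) {
        other <- sample(setdiff(birds, ev_bird[e]), 1)
        tx[[length(tx) + 1L]] <- data.frame(
          source = other, onset = ev_on[e], offset = ev_off[e],
          crosstalk = ev_bird[e], unsure = FALSE)
      }
    }
    mic_row <- NULL
    if (!mic_missed) {
      mic_row <- data.frame(
        source = first_mic, onset = min(ev_on) + jit(1),
        offset = max(ev_off) + jit(1), crosstalk = "No", unsure = FALSE)
      mc[[length(mc) + 1L]] <- mic_row
    }
    if (runif(1) < unsure_prob) {
      mc[[length(mc) + 1L]] <- data.frame(
        source = mics[1], onset = t_cur - 0.2, offset = t_cur - 0.15,
        crosstalk = "No", unsure = TRUE)
    }
    # intended consolidated outcome for this cluster
    seen <- which(tx_seen)
    tx_iv <- lapply(seq_along(ev_on), function(e) {
      if (!tx_seen[e]) return(NULL)
      last <- Filter(function(r) r$source == ev_bird[e] &&
                       r$crosstalk == "No", tx)
      last[[length(last)]]
    })
    if (is.null(mic_row)) {
      for (e in seen)
        gt[[length(gt) + 1L]] <- data.frame(
          onset = tx_iv[[e]]$onset, offset = tx_iv[[e]]$offset,
          bird_tag = ev_bird[e], transmitter_tag = ev_bird[e],
          firstmic_tag = "None")
    } else if (length(seen) == 0) {
      gt[[length(gt) + 1L]] <- data.frame(
        onset = mic_row$onset, offset = mic_row$offset,
        bird_tag = "None", transmitter_tag = "None",
        firstmic_tag = mic_row$source)
    } else if (length(seen) == 1) {
      e <- seen
      gt[[length(gt) + 1L]] <- data.frame(
        onset = min(mic_row$onset, tx_iv[[e]]$onset),
        offset = max(mic_row$offset, tx_iv[[e]]$offset),
        bird_tag = ev_bird[e], transmitter_tag = ev_bird[e],
        firstmic_tag = mic_row$source)
    } else {
      for (e in seen)
        gt[[length(gt) + 1L]] <- data.frame(
          onset = tx_iv[[e]]$onset, offset = tx_iv[[e]]$offset,
          bird_tag = ev_bird[e], transmitter_tag = ev_bird[e],
          firstmic_tag = mic_row$source)
    }
    t_cur <- max(ev_off) + 0.05
  }
  bindify <- function(l) {
    df <- if (length(l)) do.call(rbind, l) else
      data.frame(source = character(0), onset = numeric(0),
                 offset = numeric(0), crosstalk = character(0),
                 unsure = logical(0))
    class(df) <- c("vocal_segments", "data.frame")
    df[order(df$onset), , drop = FALSE]
  }
  gt_df <- if (length(gt)) do.call(rbind, gt) else
    data.frame(onset = numeric(0), offset = numeric(0),
               bird_tag = character(0), transmitter_tag = character(0),
               firstmic_tag = character(0))
  gt_df <- gt_df[order(gt_df$onset, gt_df$offset), , drop = FALSE]
  rownames(gt_df) <- NULL
  list(transmitter = bindify(tx), mics = bindify(mc), ground_truth = gt_df,
       params = list(n_birds = n_birds, n_mics = n_mics,
                     duration_s = duration_s, overlap_prob = overlap_prob,
                     miss_tx_prob = miss_tx_prob,
                     miss_mic1_prob = miss_mic1_prob,
                     miss_allmic_prob = miss_allmic_prob,
                     crosstalk_prob = crosstalk_prob, seed = seed))
}

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed STFT used for visual QC and to define the overlap quantum
#' (one spectrogram bin = `hop / rate_hz` seconds).
#'
#' @param x signal.
#' @param rate_hz sample rate.
#' @param window window length in samples (default 384).
#' @param hop hop size in samples (default 96).
#' @return list `mag` (freq x time magnitude), `freq` (Hz), `time` (s,
#'   window centers), `bin_s` (= hop / rate).
#' @export
spectrogram <- function(x, rate_hz, window = 384L, hop = 96L) {
  n <- length(x)
  stopifnot(n >= window, hop >= 1)
  n_frames <- (n - window) %/% hop + 1L
  w <- hann_window(window)
  nf <- window %/% 2L + 1L
  mag <- matrix(0, nf, n_frames)
  for (k in seq_len(n_frames)) {
    seg <- x[((k - 1L) * hop + 1L):((k - 1L) * hop + window)]
    mag[, k] <- Mod(fft(seg * w)[seq_len(nf)])
  }
  list(mag = mag, freq = (seq_len(nf) - 1L) * rate_hz / window,
       time = ((seq_len(n_frames) - 1L) * hop + window / 2) / rate_hz,
       bin_s = hop / rate_hz)
}

#' Read / write Raven-style selection tables
#'
#' Tab-separated tables with columns `Selection`, `Begin Time (s)`,
#' `End Time (s)`, `Channel`, `Crosstalk`, `Unsure`. Consolidated tables add
#' `Bird`, `Transmitter`, `FirstMic` columns instead of the tag columns.
#'
#' @param path file path.
#' @return [vocal_segments()] data.frame.
#' @export
read_selection_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  vocal_segments(source = df[["Channel"]], onset = df[["Begin Time (s)"]],
                 offset = df[["End Time (s)"]],
                 crosstalk = if ("Crosstalk" %in% names(df))
                   df[["Crosstalk"]] else "No",
                 unsure = if ("Unsure" %in% names(df))
                   df[["Unsure"]] else FALSE)
}

#' @rdname read_selection_table
#' @param segments a [vocal_segments()] table.
#' @export
write_selection_table <- function(segments, path) {
  df <- data.frame(Selection = seq_len(nrow(segments)),
                   check.names = FALSE)
  df[["Begin Time (s)"]] <- segments$onset
  df[["End Time (s)"]] <- segments$offset
  df[["Channel"]] <- segments$source
  df[["Crosstalk"]] <- segments$crosstalk
  df[["Unsure"]] <- segments$unsure
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
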