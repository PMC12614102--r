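---
title: "Multi-antenna FM telemetry: model, receiver, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-antenna FM telemetry: model, receiver, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtelem)
```

## The problem

Lightweight animal-borne FM transmitters encode an accelerometer signal
$a(t)$ (a contact microphone picking up body vibrations, in g) as the
instantaneous radio frequency

$$\omega_T(t) \simeq \omega_c(t) + c\,a(t),$$

with carrier $\omega_c$ near 300 MHz and sensitivity $c = 5$ kHz/g. A
moving bird re-orients its transmitter coil constantly, so any single
receiving antenna suffers deep fades when multipath components interfere
destructively. This package implements, in software, a four-antenna
diversity receiver that demodulates such signals robustly, together with
the analyses that sit on top of the demodulated frequency trace: radio
signal-to-noise (RSNR) and fading statistics, frequency-jump and wing-flap
detection, sub-frame video phase alignment, and multichannel vocal-segment
consolidation. Everything runs against a bundled transmitter/channel
simulator, so no recorded data is needed anywhere.

## Receiver model

Per antenna $a \in \{A,B,C,D\}$ the simulator renders an intermediate-band
complex signal

$$z^a(t) = g^a(t)\, e^{i[2\pi \int (\omega_T - \omega_{LO})\,dt +
\varphi^a(t)]} + n^a(t),$$

with smooth channel gains $g^a e^{i\varphi^a}$ and independent circularly
symmetric white Gaussian noise $n^a$ (variance $\sigma_a^2$). Four digital
down-converters sharing one tracking NCO produce baseband vectors $u^a$;
their compensated sum is the main vector $u^M = \sum_a u^a$. The phase
$\theta = \arg u^M$, unwrapped up to $\pm 128$ turns, drives a PID
controller that adjusts the tracking frequency $\omega(t)$, clipped to the
limiting range $[\Omega - \Delta\Omega, \Omega + \Delta\Omega]$ with
conditional-integration anti-windup. Every 512 baseband samples the angle
$\alpha^a$ of each antenna's mean vector relative to the main vector is fed
back into its compensation phase, $\Delta\varphi^a \mathrel{+}= \gamma
\alpha^a$ with $\gamma = 0.2$, so the four vectors sum constructively. The
high-pass filtered (200 Hz) tracking frequency is the demodulated
acceleration estimate.

### Presets and scaling

The published receiver samples the intermediate band at 100 MS/s and
decimates by 128 to a 781.25 kHz baseband. That is not desk-size, and the
algorithms are rate-invariant while all *thresholds* are physical, so the
default `"desk"` preset runs the identical chain at
$F_z = 781.25$ kS/s $= 100\,\mathrm{MS/s} / 128$ with decimation 8 and
log-decimation 4. This particular choice keeps two exact identities of the
full-scale system:

* the logged demodulated rate is the audio clock rate
  $200\,\mathrm{MHz}/2^{13} = 24{,}414.0625$ Hz, and
* one 21-ms radio frame is exactly 512 logged samples, i.e. one video
  frame at $24{,}414.0625/2^9 = 47.684$ Hz.

The `"fullscale"` preset records the full-scale parameters (decimation 128,
$\Delta\Omega = 1$ MHz, 100 kHz DDC passband) for rate arithmetic and for
short-signal runs.

### Numerical choices

* **In-loop decimator.** The DDC contract (flat passband, 60 dB stopband)
  is met by the standalone `ddc()` with a Kaiser windowed-sinc FIR. Inside
  the tracking loop that filter's group delay (~5 baseband samples) would
  consume the entire phase margin, so `run_demodulator()` decimates with a
  cascade of two length-$D$ moving averages (group delay under one baseband
  sample), the standard construction for hardware tracking loops. Adjacent
  channel selectivity is not needed in the single-transmitter simulations;
  multi-transmitter work should down-convert offline with `ddc()`.
* **PID gains.** The loop is proportional-dominant: `kp` = 3750 Hz/rad
  makes the design closed-loop bandwidth equal the scaled target
  30 kHz $\times F_{bb}/781.25$ kHz = 3.75 kHz (the measured $-3$ dB point
  is ~6 kHz because of mild delay peaking; the response at 600 Hz, where
  fidelity is asserted, is flat to 0.1%). A small integrator
  (`ki` = 3e5 Hz/(rad s), corner ~13 Hz) tracks carrier drift with
  asymptotically zero frequency error. Scaling `kp` by the baseband-rate
  ratio for the fullscale preset lands at 30 kHz, the published closed-loop
  bandwidth. Gains were chosen with `measure_closed_loop()`, which
  re-implements the white-noise probe measurement used to tune the
  original hardware.
* **Compensation sign.** The compensation phase is an offset *added* to
  the NCO phase accumulator (`u = e^{-i\Delta\varphi}\,\cdot` filtered
  mixer output), which makes the printed update
  $\Delta\varphi \mathrel{+}= \gamma\alpha$ negative feedback. The update
  applies from the next baseband sample onward; block boundaries are
  aligned to sample 0, and a one-block reporting delay is accepted.
* **Block-level rotation for RSNR statistics.** Rotating every sample by
  the instantaneous $\arg u^M$ would subtract the correlated phase noise
  of the sum, leaving only amplitude noise in the combined-signal variance
  (an apparent ~8.4 dB diversity gain). The block statistics are therefore
  rotated by the *block-mean* main-vector phase, which is uncorrelated
  with individual samples to order 1/512 and reproduces the clean theory:
  signal power $16\times$, noise variance $4\times$, RSNR gain 6 dB.
* **Degenerate inputs.** $\arg(0)$ is defined as 0 (total fade);
  `detect_tracking_loss()` compares with a relative tolerance of $10^{-9}$
  so that a clipped tracking frequency stored in absolute Hz still
  registers as exactly at-limit; ties in `best_single_antenna()` break to
  the lowest antenna label.

## RSNR and fading

Within non-overlapping 21-ms radio frames, $p^a = |\langle r^a\rangle|^2$
and $v^a_{frame} = \langle|r^a|^2\rangle - |\langle r^a\rangle|^2$; the
per-file noise $v^a$ is the median of the frame variances, and
$RSNR^a = 10\log_{10}(p^a/v^a)$ (with a $+\infty$ sentinel when $v = 0$,
excluded from summaries). Fading is RSNR < 13 dB. The published
best-single-antenna formula nests a max and a time average; following its
actual use, the antenna with the best file-averaged RSNR is selected and
its per-frame trace reported. The demodulated-noise figure $P_N$ integrates
a Hann/50%-overlap Welch PSD (segment length 1024, a free choice here) of the high-pass-filtered demodulated signal over 0-8 kHz during
non-vocal periods.

## Event detection and video alignment

Frequency jumps are deviations > 50 kHz from a centered running median
(0.2 s window, edge-truncated — edge behavior was unspecified), merged
across gaps < 50 ms. Wing flaps are dips whose derivative (first
difference × rate, on the trace down-sampled by 32 from the *logged* rate,
i.e. ~763 Hz) falls below $-60$ MHz/s and rises above $+60$ MHz/s within
2-12 ms; dips are validated by a 200-1000 kHz signal range in a ±10.5 ms
window. Whether the down-sampling factor applies to the baseband or the
logged rate was ambiguous; the logged-rate reading is implemented. Video
exposure onsets lie on the exact 47.684 Hz grid; each valid dip stamps its
nearest frame (plus the following one) with the exposure-onset-to-dip lag,
wrapped modulo the frame period into eight phase bins. Wrapping (rather
than signed binning) was chosen because the lag of the second event frame
exceeds one period in sign conventions otherwise.

## Vocal consolidation

Transmitter-based and microphone-based segments are merged by the pairing
rules (union interval for 1:1 pairs; per-transmitter split for 1:many;
miss tags for unpaired segments; error on many:1, never encountered in
practice). "Partially overlapping" is fixed at ≥ 1 spectrogram bin
(96/24,414.0625 s ≈ 3.9 ms). For mic segments paired with several
transmitter segments the consolidated intervals are the transmitter
intervals themselves — the original workflow chose onsets manually, which
cannot be replicated; this automated stand-in is the one documented
deviation. The bird guess for unpaired mic segments (repertoire-based and
manual in the original) is externalized to an optional argument, default
`"None"`. Both members of an overlapping pair count as overlapping, which
is what makes the overlap percentages comparable with published tables.

## What the synthetic world does and does not establish

The generator reproduces the *structure* of the recorded world: FM-encoded
harmonic vocal stacks (≤ 7 kHz), carrier-frequency excursions (wing-flap
dips, 2.5 MHz proximity bumps) injected into the carrier term because they
occur with a short-circuited accelerometer, smooth prescribed fading with
disjoint deep fades, independent Gaussian receiver noise, and
annotation-session artifacts (misses, crosstalk, unsure segments).
Defaults follow the published conditions: 5 kHz/g sensitivity, 15 Hz
transmitter high-pass, 28 Hz flap rate, 3 ms exposures, 13 dB fading
threshold. Where no value is stated the defaults are what a field
recording plausibly shows (0.68 g vocal amplitude giving the quoted
3.4 kHz deviation; fade floors at amplitude 0.005; ±10 ms annotation
jitter).

What it does **not** model: physical multipath geometry (fades are
prescribed trajectories, not Rayleigh draws — the receiver only ever sees
complex gains), transmitter temperature physics (drift is a linear
parameter), FPGA fixed-point arithmetic, acoustic propagation, and real
annotator behavior. A green test therefore establishes algorithmic
correctness and the printed theoretical relationships (6 dB diversity
gain, fading elimination on adversarial scenarios), not field performance
figures such as the published 6.5 dB-versus-best-antenna average, which
depend on real fading statistics.

## Known limitations

* Reacquisition after a tracking loss takes a few milliseconds (the
  integrator and the clamped phase unwrap must rewind); loss-interval
  offsets are therefore exact only when the excursion outlives the
  recording, and otherwise carry a reacquisition tail.
* With the limiting range set near the baseband rate (e.g. the desk
  default 100 kHz against a 97.66 kHz baseband), out-of-range beats alias
  across the decimator nulls and the pinned tracking frequency can
  chatter; tests pin with $\Delta\Omega$ well inside the baseband Nyquist.
* At 150 kHz dip depth the 60 MHz/s flap criterion is marginal at the
  763 Hz detection rate, so shallow-dip recall is incomplete — inherent to
  the published thresholds, not a tuning artifact.
* If the four antenna phases of a stationary on-center tone cancel
  *exactly* (zero main vector), the compensation loop sees a noise-driven
  reference phase and random-walks until the symmetry breaks; any
  asymmetry or tracking transient restores geometric convergence
  (contraction by $1-\gamma$ per block). Real channels never sit on this
  measure-zero configuration.
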