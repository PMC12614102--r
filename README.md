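# fmtelem

Multi-antenna FM telemetry in software: simulation, PLL demodulation, and
behavioral signal analysis.

## What this is for

Groups of songbirds can be recorded continuously with lightweight
animal-borne FM transmitters whose accelerometer acts as a contact
microphone: the acceleration signal $a(t)$ (units g) is encoded as the
instantaneous transmitter frequency

$$\omega_T(t) \simeq \omega_c(t) + c\,a(t), \qquad c = 5\ \text{kHz/g},$$

with $\omega_c$ near 300 MHz. Because a moving bird constantly re-orients
its transmitter coil, any single receiving antenna fades when multipath
components interfere destructively. This package re-implements a
four-antenna diversity receiver and its downstream analyses for people who
want to study, extend, or validate such systems without hardware:

* **`radio_sim`** — ground-truth accelerometer traces (vocal harmonic
  stacks, wing-flap dips, 2.5 MHz proximity excursions), FM encoding, and
  per-antenna intermediate-band rendering under configurable fading and
  noise (`synthesize_accel_trace`, `fm_encode`, `make_fading_scenario`,
  `render_antennas`).
* **`demod`** — the receiver core: four digital down-converters on a
  common tracking NCO; the phase $\theta = \arg u^M$ of the summed
  baseband vector $u^M = u^A + u^B + u^C + u^D$, unwrapped up to ±128
  turns, drives a PID-controlled PLL with a limiting range
  $[\Omega - \Delta\Omega, \Omega + \Delta\Omega]$; per-antenna
  compensation phases $\Delta\varphi^a$ are updated every 512 baseband
  samples by $\Delta\varphi^a \mathrel{+}= \gamma\,\alpha^a$
  ($\gamma = 0.2$) so the antennas sum constructively
  (`run_demodulator`, `ddc`, `detect_tracking_loss`,
  `demodulated_signal`, `measure_closed_loop`).
* **`rsnr`** — radio signal-to-noise per 21-ms radio frame,
  $RSNR = 10\log_{10}(p/v)$ with $p = |\langle r\rangle|^2$ and $v$ the
  per-file median frame variance; best-single-antenna comparison, fading
  fractions (< 13 dB), and the demodulated noise power $P_N$
  (`rsnr_frames`, `best_single_antenna`, `fading_stats`, `noise_power`).
* **`events`** — frequency-jump detection (> 50 kHz from a 0.2 s running
  median, merged across < 50 ms gaps) and wing-flap dips (derivative
  crossings of ∓60 MHz/s within 2–12 ms, 200–1000 kHz range validation)
  (`detect_jumps`, `detect_wing_flaps`).
* **`framesync`** — shared-clock timeline arithmetic
  (200 MHz / 2¹³ = 24.414 kHz audio, / 2⁹ = 47.684 Hz video) and
  sub-frame wing-flap phase binning of video exposures
  (`clock_plan`, `timestamp_frames`, `assign_phase_bins`).
* **`vocseg`** — transmitter- and microphone-based vocal segments,
  consolidation rules with Bird/Transmitter/FirstMic attribution,
  summary statistics, and a seeded synthetic annotation generator
  (`consolidate`, `voc_statistics`, `generate_annotations`,
  `spectrogram`).

## Worked example

One bird, a 0.68 g vocal tone at 600 Hz, an adversarial fading scenario in
which every antenna suffers one deep fade, and receiver noise:

```r
library(fmtelem)

trace <- synthesize_accel_trace(
  4, vocal = vocal_spec(onset = 1.2, duration = 0.6, f0_hz = 600,
                        amp_g = 0.68))
omega_t <- fm_encode(trace, transmitter_spec())      # 5 kHz/g FM encoding
channel <- make_fading_scenario(4, seed = 1)         # 4 disjoint deep fades
signals <- render_antennas(omega_t, channel, lo_hz = 300e6,
                           rate_hz = 100e6 / 128, seed = 1)
demod <- run_demodulator(signals, demod_config("desk"))
frames <- rsnr_frames(demod)
print(frames)
#> <rsnr_frames> 190 frames of 0.0210 s; mean RSNR (dB):
#>     A     B     C     D     M
#> 42.74 42.87 42.87 42.88 46.43

best <- best_single_antenna(frames)
cat(sprintf("time faded (<13 dB): best single %.2f%%, combined %.2f%%\n",
            100 * mean(best$rsnr < 13),
            fading_stats(frames)[["M"]]))
#> time faded (<13 dB): best single 1.05%, combined 0.00%

accel <- demodulated_signal(demod$omega, demod$rate_omega,
                            sensitivity_hz_per_g = 5000)
voc <- trace$annotations[trace$annotations$label == "vocal", ]
i <- floor(demod$rate_omega * (voc$onset + 0.1)):
     floor(demod$rate_omega * (voc$offset - 0.1))
cat(sprintf("recovered vocal amplitude: %.3f g (injected 0.68 g)\n",
            sqrt(2) * sd(accel[i])))
#> recovered vocal amplitude: 0.677 g (injected 0.68 g)
```

Reading the numbers: each single antenna averages ~43 dB RSNR but spends
~1% of the time below the 13 dB fading threshold (its deep fade); the
phase-compensated four-antenna sum gains the theoretical
$10\log_{10}(16/4) = 6$ dB where all antennas are live, never fades, and
the demodulated trace recovers the injected vocal amplitude to well within
5%.

A thin command-line interface wraps the same pipeline
(`inst/cli/fmtelem`): `simulate`, `demodulate`, `rsnr`, `detect`, `align`,
`vocstats`; containers are `.rds` files, tables are TSV.

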