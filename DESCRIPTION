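Package: fmtelem
Title: Multi-Antenna FM Telemetry: Simulation, Demodulation, and Behavioral Signal Analysis
Version: 0.1.0
Authors@R:
    person("BirdPark", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A software re-implementation of a multi-antenna FM telemetry
    receiver for animal-borne accelerometer transmitters, together with its
    downstream behavioral analyses. Includes a synthetic transmitter/channel
    simulator (FM-encoded accelerometer traces, per-antenna complex channel
    gains with deep fades, additive receiver noise), a phase-locked-loop FM
    demodulator driven by the phase of the summed baseband vector with
    per-antenna phase compensation, radio signal-to-noise and fading
    statistics, detectors for radio-frequency jumps and wing-flap dips,
    sub-frame video phase alignment from shared clock dividers, and a
    multichannel vocal-segment consolidation data model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
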