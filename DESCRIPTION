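Package: cororeg
Title: Coronary Flow Regulation Analysis from Pressure and Doppler Velocity Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to assess coronary blood flow regulation from intracoronary
    pressure and Doppler flow-velocity recordings. Implements beat detection on
    the pressure waveform, coronary flow reserve and hyperemic microvascular
    resistance from beat-level selection rules, and estimation of the lower
    autoregulatory breakpoint by 5-mmHg binning of beat pressure-flow
    coordinates followed by a paired two-segment regression whose intersection
    defines the breakpoint. Includes a seeded synthetic hemodynamics generator
    (pulsatile pressure, vasodilator-bolus hyperemia transients, balloon
    pressure ramps) so the full pipeline can be exercised and validated
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
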