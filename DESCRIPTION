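Package: wgmkinetics
Title: Single-Molecule Kinetics from Whispering-Gallery-Mode Sensor Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule optoplasmonic
    whispering-gallery-mode (WGM) sensing experiments on neurotransmitter to
    lipid-membrane interactions. Provides seeded generators for resonance-shift
    traces, sweep spectra, paired TE/TM channels, temperature series and
    Langmuir surface-pressure traces; centroid and Lorentzian resonance
    tracking; step/spike event detection; survivor-function construction with
    mono- and bi-exponential dwell-time and inter-event-interval fitting and
    AIC model selection; Eyring transition-state analysis of temperature
    dependent rates; TE/TM polarization-anisotropy metrics and first-order
    layer-thickness conversion; and injection-artifact-corrected surface
    pressure changes from Langmuir trough traces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
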