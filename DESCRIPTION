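Package: mesowide
Title: Processing of Interleaved Four-Wavelength Widefield Mesoscope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-camera widefield mesoscopic imaging with
    interleaved illumination at two fluorescence excitation wavelengths
    (470 and 565 nm) and two reflectance wavelengths (525 and 625 nm).
    Demultiplexes interleaved frame stacks into per-wavelength channels,
    estimates oxy- and deoxyhemoglobin concentration changes from two-
    wavelength reflectance by an explicit modified Beer-Lambert inversion,
    corrects green-channel fluorescence for hemodynamic absorption and for
    red-fluorophore spectral crosstalk, calibrates crosstalk ratios from
    in-vitro dilution series, computes stimulus-aligned trial averages and
    ratio maps, quantifies pupil diameter from behavioral video, and
    simulates rolling-shutter LED trigger schedules. A forward-model
    phantom generator produces synthetic acquisitions with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    rhdf5
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
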