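Package: erpspeller
Title: Offline Analysis of Audiovisual P300 Speller Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and offline decoding pipeline for event-related
    potential (ERP) based brain-computer interface spellers with audiovisual
    oddball stimulation. Provides a synthetic-EEG generator with configurable
    N2/P3/N4/P5 components and 1/f + alpha background noise, the standard
    preprocessing chain (mastoid re-referencing, 0.5-40 Hz band-pass,
    down-sampling to 200 Hz, stimulus-locked epoching with baseline removal),
    squared point-biserial (r-squared) classifiability maps and windowed
    feature extraction, stepwise linear discriminant analysis (SWLDA) and a
    linear maximum-margin classifier, repetition-aggregated character
    decoding with recognition-rate curves, and bootstrap t-tests with
    false-discovery-rate correction for spatio-temporal ERP comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
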