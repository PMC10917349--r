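Package: groovedyn
Title: Neurodynamic Modeling and Neural Decoding of Musical Groove
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the wanting-to-move (groove) experience of
    syncopated musical rhythms. Implements beat-gridded rhythm patterns and
    the Longuet-Higgins-Lee syncopation index; a three-layer gradient-frequency
    network of canonical Hopf oscillators with Hebbian connection plasticity
    and its run protocol yielding beat-rate (2 Hz) mean-field amplitudes;
    cochlear-envelope modulation spectra; Morlet time-frequency decomposition
    with 1/f rectification and spatial spectral-gradient fits; cross-validated
    ridge decoding (whole-sensor, searchlight, and ROI variants) with Fisher-z
    coding precision and Storey false discovery rate control; phase-amplitude
    coupling comodulograms; and a synthetic MEG-style data generator with
    planted ground truth so every analysis stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
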