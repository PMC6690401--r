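Package: stereodots
Title: Random-Dot Stereograms, Interocular Correlation, and the Binocular
    Energy Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing random-dot stereogram pairs (mixed- or
    same-polarity square dots, with or without dot overlap, and several
    disparity-noise models), measuring interocular correlation (Pearson
    coefficient, cross-correlation profiles, monocular autocorrelation,
    and provenance-based matched/unmatched pixel-pair statistics), and
    simulating populations of binocular energy-model V1 neurons with Gabor
    receptive fields. Includes a closed-form theory of the expected
    interocular correlation in terms of pixel-pair statistics, and a
    neuron/anti-neuron front/back discrimination task with percent-correct
    and statistical-efficiency readouts. The package demonstrates how
    forbidding dot overlap during stimulus construction lowers interocular
    correlation for same-polarity patterns, which is sufficient to produce
    a mixed-polarity advantage in standard correlation-based models of
    stereopsis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
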