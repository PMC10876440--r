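Package: ciliamech
Title: Kymograph, Antennal-Mechanics and Ciliary-Intensity Analysis for
    Chordotonal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of ciliary maintenance in Drosophila
    mechanosensory neurons, driven end-to-end by synthetic data with known
    ground truth. Implements kymograph construction and directional Fourier
    separation of intraflagellar transport (IFT) trains, train-track
    extraction with velocity, length, stall and encounter statistics;
    power-spectral-density analysis of antennal displacement with
    simple-harmonic-oscillator fitting, equipartition fluctuation energy and
    mechanical sensitivity gain; and marker-gated intensity quantification of
    ciliary proteins with group comparison. Ships generators for synthetic
    IFT time-lapse movies, Langevin oscillator traces, stimulus-response
    sweeps and two-channel image volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
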