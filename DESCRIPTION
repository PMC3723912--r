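Package: ck1clock
Title: Circadian Rhythm Quantification and CK1-Responsive Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the computational analyses of casein
    kinase 1 (CK1) circadian pharmacology and phosphoproteomics in a
    minimal eukaryotic model. Quantifies period, phase and amplitude of
    bioluminescence reporter traces by truncated-Fourier harmonic
    regression with a nonlinear period search; assembles dose-response
    curves (free-running period versus inhibitor dose) and phase-response
    curves (phase change versus pulse time, delays negative) from paired
    treated/control fits; collates label-free phospho-peptide
    quantifications to unique phospho-sites and calls significantly
    differential sites with an arcsinh-transformed t-test and raw
    fold-change gates; and tests enrichment of CK1 substrate motifs among
    differential sites with a Monte-Carlo permutation test backed by an
    exhaustive small-case oracle. A synthetic-data generator emulates the
    statistical structure of all inputs so the whole pipeline runs with
    known ground truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
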