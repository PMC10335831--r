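Package: mtkit
Title: Microtubule Transport, Ooplasmic Streaming, and Tubulin
    Glutamylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of microtubule-dependent processes in
    Drosophila tissues: run/pause segmentation and transport statistics
    for manually tracked organelle trajectories (run length, run
    velocity, transport velocity, pausing time ratio, pausing
    frequency), kymograph construction and flow-field classification of
    ooplasmic streaming patterns in stage 10B oocytes, tabulation of
    alpha-tubulin C-terminal glutamylation from peptide-spectrum-match
    tables, and quantification of cortical crescents and
    anterior-posterior intensity profiles in oocyte images.  Seeded
    synthetic-data generators for trajectories, streaming movies, PSM
    tables, and oocyte images provide ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
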