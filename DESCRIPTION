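Package: isgscore
Title: Interferon-Stimulated Gene Scores from NanoString nCounter Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and scoring of NanoString nCounter immune gene panels
    for monitoring type-I interferon pathway activity. Reads raw RCC files or
    count tables, applies the two-step positive-control and housekeeping-gene
    normalization (each factor the ratio of the cohort-mean control geometric
    mean to the sample's control geometric mean), and computes per-sample panel
    scores: the geometric-mean score over a 30-gene interferon-stimulated gene
    (ISG) panel and a healthy-reference Z-score, with analogous NF-kB and
    IFN-gamma panels. Includes healthy-donor reference bands, paired
    stimulated/unstimulated induction ratios for in-vitro IFN-beta
    responsiveness assays, longitudinal per-subject score trajectories with
    therapy annotations, and a seeded negative-binomial simulator of nCounter
    runs (lane effects, control ladder, disease elevation, stimulation
    induction) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
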