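Package: orthofixr
Title: Detecting and Correcting Gene-Prediction Errors Behind Domain
    Architecture Differences of Orthologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decide whether domain-architecture differences between
    orthologous proteins of two related species reflect gene-prediction errors
    rather than genuine proteome innovation. Provides reciprocal best-hit
    orthology with a configurable identity cutoff, consensus-based domain
    calling and linear domain-architecture comparison, misprediction rules
    (extracellular/intracellular domain co-occurrence without a transmembrane
    segment, drastic domain truncation), EST-based fusion-junction tests, a
    tiered correction protocol (transcript evidence, translated genome search,
    ortholog projection), translated six-frame recovery of missing genes, and a
    synthetic two-species proteome-pair generator with truth-labelled injected
    annotation errors (fusion, fission, cross-scaffold fragmentation,
    truncation, chimeric extension, omission) that makes every stage of the
    survey verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
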