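Package: regbind
Title: Mapping Protein-DNA Binding with ChIP Enrichment Tracks, SPR ReDCaT
    Footprinting, and Direct-Repeat Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising bacterial transcription-factor binding
    sites from complementary assays. Computes sliding-window ChIP-seq
    enrichment ratios from per-nucleotide depth tracks with control
    subtraction and region calling; designs reusable DNA capture (ReDCaT)
    duplexes for surface plasmon resonance, including tiling, truncation and
    repeat-substitution series, and normalises binding responses to the
    theoretical maximum (%Rmax) with footprint-boundary inference; scans
    short regulatory sequences for degenerate direct-repeat consensus motifs
    and discovers repeat families de novo; classifies differential-expression
    tables by volcano thresholds and performs qPCR standard-curve
    quantification with reference-gene normalisation. Seeded synthetic-data
    generators (genomes, depth tracks, binding cycles, count matrices)
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
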