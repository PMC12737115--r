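Package: panfam
Title: Pangenome Gene-Family Presence/Absence, Selection and Promoter
    Structural-Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for gene-family analysis across a panel of
    assembled genomes (a pangenome). Identifies family members from HMMER
    domain searches with E-value and profile-coverage filters, groups them
    into pan-genes, builds the gene-by-genome presence/absence (PAV) matrix
    and classifies occupancy (core, near-core, dispensable, private).
    Estimates pairwise Ka/Ks with from-scratch Nei-Gojobori (NG86) and
    approximate Yang-Nielsen (YN) codon estimators and summarizes per-gene
    positive-selection signal. Calls shared promoter insertion/deletion
    structural variants from reference-anchored multiple alignments,
    annotates them with FIMO-style position-weight-matrix scans using exact
    dynamic-programming p-values, and tests presence/absence association
    with expression by Student's t-test. A seeded synthetic-data generator
    produces pangenomes, codon pairs evolved at known omega and kappa,
    promoter alignments with planted indels, motif plants and expression
    tables, each with a machine-readable truth record.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
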