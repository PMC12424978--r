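Package: riboamp
Title: Ribosomal Operon Amplicon Design Comparison and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing 16S rRNA and full ribosomal-operon amplicon
    designs for microbiome profiling. Provides degenerate-primer in-silico PCR,
    in-silico trimming of long amplicon reads to nested sub-regions, rRNA
    operon census with theoretical amplicon sequence variant (ASV) prediction
    and contiguity screening, exact-dereplication ASV calling with
    lowest-common-ancestor taxonomic classification, rarefaction, four beta
    diversity metrics (Bray-Curtis, Jaccard, unweighted and weighted UniFrac),
    principal coordinates analysis, adonis-style PERMANOVA, mock-community
    expected-versus-observed bias evaluation, and a synthetic-data generator
    producing genomes with controlled operon architecture, two-cohort
    communities, and amplicon reads with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    withr,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
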