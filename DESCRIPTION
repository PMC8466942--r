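Package: chromdiv
Title: Chromosome-Level Genome Diversity Landscapes and Marker Localization
Version: 0.1.0
Authors@R:
    person("chromdiv", "developers", email = "chromdiv@example.org",
           role = c("aut", "cre"))
Description: Conservation-genomics toolkit for chromosome-level genome
    assemblies. Computes assembly contiguity and gap statistics (scaffold
    N50, N content) and draft-versus-chromosome comparisons; applies
    site-quality and coverage-band filters to single-sample VCFs; estimates
    windowed heterozygosity landscapes (heterozygous SNPs per kbp in
    stacking windows); identifies the X chromosome and its pseudoautosomal
    region from read-depth profiles of male samples; compares window subsets
    (autosomes, X, PAR) with one-sided Mann-Whitney tests; localizes STR
    marker panels by in silico PCR with mismatch scoring and an
    NA/declined/localized classification; and renders heatmap, boxplot,
    coverage-track and marker-map figures. Includes a seeded synthetic-data
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
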