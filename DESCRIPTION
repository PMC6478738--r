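Package: phasecall
Title: Read-Backed Phasing, Contamination-Aware SNV Calling and
    Filtering for Noisy Long Reads
Version: 0.1.0
Authors@R:
    person("phasecall", "developers", email = "phasecall@example.org",
           role = c("aut", "cre"))
Description: Single-sample, reference-panel-free haplotype phasing of
    noisy long sequencing reads using an EM-fitted two-haplotype
    emission model, with per-site phasing-quality metrics (phase
    entropy, per-haplotype strand bias) that separate true
    heterozygous variants from sequencing artefacts.  Includes a
    per-site frequency-based SNV caller with contamination-adjusted
    expected allele fractions for high-error reads, an annotation
    battery (homopolymers, coverage, in-read deletions, strand bias)
    with pre- and post-phasing filter policies, a diploid long-read
    simulator with configurable substitution/insertion/deletion error
    composition, and evaluation metrics: per-read alignment error
    rates, FDR/FNR/F1 with genotype-mismatch double counting, and
    switch error rate of phased calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    igraph,
    jsonlite,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
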