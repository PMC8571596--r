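Package: sweepscan
Title: Two-Population Selective-Sweep and CNV Differentiation Scans
Version: 0.9.0
Authors@R: person("sweepscan", "developers", role = c("aut", "cre"),
    email = "sweepscan@example.org")
Description: Genome-wide selection-scan toolkit for a two-population
    (case/control) resequencing cohort. Computes sliding-window nucleotide
    diversity (pi), pi-ratio and Hudson's F_ST from biallelic SNP genotypes,
    V_ST / F_ST / Welch t-test differentiation statistics for copy-number
    variant regions, selects candidates by top-percentile intersection,
    annotates them against gene models (overlap and flanking distance), and
    runs gene-set over-representation analysis with Benjamini-Hochberg FDR
    control. Includes a deterministic two-population simulator (Balding-
    Nichols allele frequencies with injected sweeps and differentiated CNVs)
    so the whole pipeline is testable without external data, and a
    command-line entry point orchestrating the full scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
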