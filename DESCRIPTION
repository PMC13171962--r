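Package: svadapt
Title: Structural Variant Validation from Nanopore Adaptive Sampling Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools to validate and characterize structural variants from
    Oxford Nanopore adaptive sampling experiments. Reads are partitioned
    into accepted (on-target) and ejected (off-target) classes from
    MinKNOW sequencing summaries, run statistics (N50, per-region depth,
    enrichment) are tabulated, copy number over targeted regions is
    inferred from binned log2 depth ratios normalized to the mean of all
    targets, the genome background is scanned for large copy-number
    variants using only ejected reads, breakpoint-spanning split reads
    are clustered into junctions, and rearrangement architectures are
    reconstructed by exhaustive walks over copy-number segment graphs.
    A synthetic run generator with planted structural variants provides
    a full truth-set-backed test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'genome.R'
    'regions.R'
    'summary-io.R'
    'alignments-io.R'
    'run-qc.R'
    'cnv-target.R'
    'cnv-background.R'
    'junctions.R'
    'architecture.R'
    'simulate.R'
    'fixtures.R'
    'tracks.R'
    'svadapt-package.R'
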