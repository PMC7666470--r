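Package: InsertionTracer
Title: Discovery, Sequence Resolution, and Genotyping of Non-Reference
    Insertion Structural Variants from Short Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects insertion structural variants (>50 bp) that are absent
    from a reference genome using paired-end short-read alignments. Discordant
    read pairs with one anchored end are clustered and assembled strand by
    strand into local contigs ("insertion tags") that carry flanking reference
    sequence, a breakpoint, and partial inserted sequence; left- and
    right-flank tags are paired into candidate insertion events. Full inserted
    sequences are then inferred by tracing the tag segments through additional
    target genomes, events are classified as retained ancestral sequence or
    novel insertion, breakpoint sequence features assign a mutational
    mechanism (VNTR, NAHR, TE, NH), and catalogued variants are genotyped in
    further samples by dual-allele realignment and the read-depth ratio of
    allele-supporting reads. A self-contained simulator (synthetic genomes,
    implanted insertions, paired-end reads) and evaluation routines reproduce
    the benchmark protocol, and population summaries (allele frequencies,
    per-individual inserted-sequence load, Nei pairwise F_ST) are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: bwa, samtools (read-mapping adapter for the simulation
    benchmark; the core caller only requires BAM input)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
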