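## Stage runners tying the modules together, and the simulation benchmark
## protocol (synthetic acceptor/donor, implants, reads, mapping, discovery,
## scoring).

#' Run discovery on a BAM file and optionally write its outputs
#'
#' Wraps [discoverInsertions()]; when `outDir` is given, writes the insertion
#' tags as a BED-like TSV (0-based half-open coordinates) plus a FASTA of the
#' partial inserted sequences, the paired events as TSV, and a run manifest
#' (configuration and input checksums). Outputs contain no timestamps, so
#' reruns with identical inputs are byte-identical.
#'
#' @param bamFile indexed BAM of the sample.
#' @param reference reference genome (FASTA path or `DNAStringSet`).
#' @param config a [svConfig()] object.
#' @param outDir output directory, or `NULL` to skip writing.
#' @return the [discoverInsertions()] result list.
#' @export
runDiscovery <- function(bamFile, reference, config = svConfig(),
                         outDir = NULL) {
    res <- discoverInsertions(bamFile, reference, config = config)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        m <- S4Vectors::mcols(res$tags)
        tagTsv <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(res$tags)),
            breakpoint = BiocGenerics::start(res$tags) - 1L,
            side = m$side,
            flank_len = nchar(as.character(m$flankSeq)),
            ins_part_len = nchar(as.character(m$insPartSeq)),
            seq = as.character(m$insPartSeq))
        utils::write.table(tagTsv, file.path(outDir, "insertion_tags.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (length(res$tags)) {
            fa <- m$insPartSeq
            names(fa) <- sprintf("tag_%d|%s|%s:%d", seq_along(res$tags),
                                 m$side, tagTsv$chrom, tagTsv$breakpoint)
            Biostrings::writeXStringSet(fa, file.path(outDir, "ins_parts.fa"))
        }
        pm <- S4Vectors::mcols(res$pairs)
        pairTsv <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(res$pairs)),
            left_bp = pm$leftBp, right_bp = pm$rightBp, gap = pm$gap,
            left_ins_part = as.character(pm$leftInsPart),
            right_ins_part = as.character(pm$rightInsPart))
        utils::write.table(pairTsv, file.path(outDir, "paired_tags.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeConfig(config, file.path(outDir, "config.txt"))
        manifest <- c(
            sprintf("bam\t%s\t%s", bamFile, tools::md5sum(bamFile)[[1]]),
            if (is.character(reference))
                sprintf("reference\t%s\t%s", reference,
                        tools::md5sum(reference)[[1]]),
            sprintf("counters\t%s",
                    paste(names(res$counters), res$counters, sep = "=",
                          collapse = ",")))
        writeLines(manifest, file.path(outDir, "manifest.tsv"))
    }
    res
}

#' Run tracing (and mechanism classification) into a catalogue VCF
#'
#' @param pairs a [PairedInsertionTags] object (from [runDiscovery()]).
#' @param reference reference genome (FASTA path or `DNAStringSet`).
#' @param targets list of [TargetGenome] objects (at least one).
#' @param config a [svConfig()] object.
#' @param outVcf output VCF path, or `NULL`.
#' @param classifyMech also classify mutational mechanisms (toy annotator
#'   unless `annotations` given).
#' @param annotations optional per-variant repeat annotations (see
#'   [classifyCatalogMechanisms()]).
#' @return an [InsertionCatalog].
#' @export
runTracing <- function(pairs, reference, targets, config = svConfig(),
                       outVcf = NULL, classifyMech = TRUE,
                       annotations = NULL) {
    if (length(targets) == 0L)
        stop("at least one target genome is required for tracing")
    catalog <- traceCatalog(pairs, reference, targets, config = config)
    if (classifyMech && length(catalog))
        catalog <- classifyCatalogMechanisms(catalog, reference,
                                             annotations = annotations,
                                             config = config)
    if (!is.null(outVcf)) writeCatalogVcf(catalog, reference, outVcf)
    catalog
}

#' Genotype a catalogue across samples into a multi-sample VCF
#'
#' @param catalog an [InsertionCatalog] (or a catalogue VCF path).
#' @param bamFiles named character vector of sample BAMs.
#' @param reference reference genome.
#' @param config a [svConfig()] object.
#' @param outVcf output VCF path, or `NULL`.
#' @return an [InsertionGenotypes].
#' @export
runGenotyping <- function(catalog, bamFiles, reference, config = svConfig(),
                          outVcf = NULL) {
    if (is.character(catalog)) catalog <- readCatalogVcf(catalog)
    if (is.null(names(bamFiles)))
        names(bamFiles) <- tools::file_path_sans_ext(basename(bamFiles))
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    res <- lapply(names(bamFiles), function(s)
        genotypeSample(catalog, bamFiles[[s]], reference, config = config,
                       sampleId = s))
    gt <- vapply(res, function(x) x$gt, character(length(catalog)))
    dosage <- vapply(res, function(x) x$dosage, integer(length(catalog)))
    nRef <- vapply(res, function(x) x$nRef, integer(length(catalog)))
    nAlt <- vapply(res, function(x) x$nAlt, integer(length(catalog)))
    dimn <- list(S4Vectors::mcols(catalog)$variantId, names(bamFiles))
    gt <- matrix(gt, ncol = length(bamFiles), dimnames = dimn)
    dosage <- matrix(dosage, ncol = length(bamFiles), dimnames = dimn)
    nRef <- matrix(nRef, ncol = length(bamFiles), dimnames = dimn)
    nAlt <- matrix(nAlt, ncol = length(bamFiles), dimnames = dimn)
    if (!is.null(outVcf))
        writeGenotypesVcf(catalog, reference, gt, nRef, nAlt, outVcf)
    makeInsertionGenotypes(dosage, population = rep("NA", ncol(dosage)),
                           svlen = S4Vectors::mcols(catalog)$svlen,
                           nRef = nRef, nAlt = nAlt)
}

#' Simulate the insertion-discovery benchmark and score it
#'
#' Full benchmark protocol: generate a synthetic acceptor and donor genome
#' (shared repeat library), implant `nIns` donor segments of log-uniform size
#' into the acceptor, simulate FR paired-end reads from the mutated acceptor,
#' map them with bwa against (i) the acceptor alone -- implanted segments
#' absent from the mapping reference ("unique" insertions) -- and optionally
#' (ii) acceptor plus donor ("non-unique": reads from implants can also map to
#' their donor locus), run discovery and tag pairing on each BAM, and score
#' the paired-tag calls against the implant truth (breakpoint gap < 100 bp,
#' >= 50% of the predicted insertion aligning).
#'
#' @param seed integer seed driving every random step.
#' @param acceptorLen,donorLen synthetic genome sizes (bp).
#' @param nIns number of implanted insertions.
#' @param sizeMin,sizeMax implant size range (bp), log-uniform.
#' @param coverage,readLen,insertMean,insertSd,err read simulation parameters.
#' @param modes subset of `c("unique", "nonunique")`.
#' @param workDir scratch directory for FASTA/FASTQ/BAM files.
#' @param config a [svConfig()] object.
#' @return list with one element per mode: the [evaluateCalls()] metrics plus
#'   `calls`, `truth` and the discovery counters.
#' @export
runBenchmark <- function(seed, acceptorLen = 5e6, donorLen = 5e6, nIns = 100L,
                         sizeMin = 100L, sizeMax = 20000L, coverage = 30,
                         readLen = 100L, insertMean = 350, insertSd = 50,
                         err = 0.002, modes = c("unique", "nonunique"),
                         workDir = tempfile("bench"), config = svConfig()) {
    modes <- match.arg(modes, several.ok = TRUE)
    dir.create(workDir, showWarnings = FALSE, recursive = TRUE)
    .log("benchmark: generating %.1f Mbp acceptor and donor genomes",
         acceptorLen / 1e6)
    acceptor <- generateSyntheticGenome(acceptorLen, seed = seed,
                                        name = "chrA")
    donor <- generateSyntheticGenome(donorLen, seed = seed + 1L,
                                     name = "chrD")
    imp <- implantInsertions(acceptor, donor, n = nIns, sizeMin = sizeMin,
                             sizeMax = sizeMax, seed = seed + 2L)
    .log("benchmark: simulating %gx 2x%d bp reads", coverage, readLen)
    fq1 <- file.path(workDir, "reads_1.fq")
    fq2 <- file.path(workDir, "reads_2.fq")
    simulatePers(imp$genome, coverage = coverage, readLen = readLen,
                 insertMean = insertMean, insertSd = insertSd, err = err,
                 seed = seed + 3L, fastq1 = fq1, fastq2 = fq2)
    refs <- list(
        unique = acceptor,
        nonunique = c(acceptor, donor))
    out <- list()
    for (mode in modes) {
        fa <- file.path(workDir, paste0("ref_", mode, ".fa"))
        writeReferenceFasta(refs[[mode]], fa)
        bam <- file.path(workDir, paste0(mode, ".bam"))
        .log("benchmark: mapping (%s reference)", mode)
        mapReads(fa, fq1, fq2, bam)
        disc <- discoverInsertions(bam, refs[[mode]], config = config)
        pm <- S4Vectors::mcols(disc$pairs)
        calls <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(disc$pairs)),
            leftBp = pm$leftBp, rightBp = pm$rightBp,
            predLeft = as.character(pm$leftInsPart),
            predRight = as.character(pm$rightInsPart),
            stringsAsFactors = FALSE)
        metrics <- evaluateCalls(calls, imp$truth, config = config)
        metrics$calls <- calls
        metrics$counters <- disc$counters
        .log("benchmark [%s]: sensitivity %.1f%%, FDR %.1f%% (%d calls)",
             mode, 100 * metrics$sensitivity, 100 * metrics$fdr,
             metrics$nCalled)
        out[[mode]] <- metrics
    }
    out$truth <- imp$truth
    out
}
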