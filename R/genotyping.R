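## Genotyping: dual-allele construction, read assignment by best-supported
## allele, and read-depth-ratio genotype calls.

#' Build the reference and insertion alleles of a variant
#'
#' The reference allele is the local reference spanning the breakpoint with
#' `flankExtension` bp on each side; the insertion allele is the same sequence
#' with the full inserted sequence placed at the breakpoint. Flanks must be at
#' least one read length so that reads can span the allele-distinguishing
#' junctions (`flank_extension_extra` bp are added on top of the read length).
#'
#' @param chrom,pos0 variant site: chromosome and 0-based insertion point.
#' @param insSeq full inserted sequence (character); must be non-empty.
#' @param reference reference genome (`DNAStringSet`).
#' @param readLen read length of the sample to be genotyped (bp).
#' @param config a [svConfig()] object (uses `flank_extension_extra`).
#' @param flankExtension override the computed flank extension (bp).
#' @return list with `refAllele`, `insAllele` (character), `bpOffset`
#'   (0-based breakpoint offset within both alleles), `insLen`; or `NULL`
#'   (with a logged reason) when the site is too close to a contig end.
#' @export
buildAlleles <- function(chrom, pos0, insSeq, reference, readLen = 100L,
                         config = svConfig(), flankExtension = NULL) {
    insSeq <- .dnaChar(insSeq)
    if (nchar(insSeq) == 0L)
        stop("insSeq must be non-empty: a zero-length insertion is not genotypable")
    if (is.null(flankExtension))
        flankExtension <- readLen + configValue(config, "flank_extension_extra")
    refSeq <- .chromSeq(reference, chrom)
    if (pos0 - flankExtension < 0L || pos0 + flankExtension > length(refSeq)) {
        .log("genotype: %s:%d skipped (within %d bp of a contig end)",
             chrom, pos0, flankExtension)
        return(NULL)
    }
    left <- as.character(.sub0(refSeq, pos0 - flankExtension, pos0))
    right <- as.character(.sub0(refSeq, pos0, pos0 + flankExtension))
    list(refAllele = paste0(left, right),
         insAllele = paste0(left, insSeq, right),
         bpOffset = flankExtension,
         insLen = nchar(insSeq))
}

#' Assign reads to the reference or insertion allele
#'
#' Each read is aligned locally (both orientations) to both alleles; it
#' supports an allele when its best score beats the other allele's by at least
#' `score_margin` and the winning alignment spans an allele-distinguishing
#' junction with `min_overlap` bp on each side: the breakpoint for the
#' reference allele, either phase-change point (flank/insertion boundary) for
#' the insertion allele. Reads entirely inside the insertion are not counted,
#' so the read-depth ratio does not grow with insertion length (the insertion
#' allele still has two junctions to the reference allele's one, a mild and
#' documented bias toward the insertion allele). All other reads are
#' ambiguous.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences.
#' @param alleles an allele pair from [buildAlleles()].
#' @param config a [svConfig()] object (uses `assign_k`, `score_margin`,
#'   `min_overlap`).
#' @return factor with levels `ref`, `alt`, `ambiguous`, plus attribute
#'   `scores` (matrix of best scores per allele).
#' @export
assignReads <- function(reads, alleles, config = svConfig()) {
    reads <- as.character(reads)
    if (length(reads) == 0L) {
        f <- factor(character(0), levels = c("ref", "alt", "ambiguous"))
        attr(f, "scores") <- matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("ref", "alt")))
        return(f)
    }
    res <- cpp_assign_reads(
        reads, alleles$refAllele, alleles$insAllele,
        k = configValue(config, "assign_k"),
        margin = configValue(config, "score_margin"),
        min_overlap = configValue(config, "min_overlap"),
        bp_ref = alleles$bpOffset,
        ins_start = alleles$bpOffset,
        ins_end = alleles$bpOffset + alleles$insLen)
    f <- factor(c("ambiguous", "ref", "alt")[res$call + 1L],
                levels = c("ref", "alt", "ambiguous"))
    attr(f, "scores") <- cbind(ref = res$score_ref, alt = res$score_alt)
    f
}

#' Call a biallelic genotype from allele-supporting read counts
#'
#' The alt-allele read-depth ratio `nAlt / (nRef + nAlt)` is thresholded:
#' `<= t_low` gives 0/0, `>= t_high` gives 1/1, in between 0/1. Sites with
#' fewer than `min_depth` informative reads are undetermined (`./.`).
#'
#' @param nRef,nAlt integer vectors of allele-supporting read counts.
#' @param config a [svConfig()] object (uses `t_low`, `t_high`, `min_depth`).
#' @return data.frame with columns `nRef`, `nAlt`, `altRatio`, `gt`
#'   (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`) and `dosage` (0/1/2, `NA` for
#'   `./.`).
#' @export
callGenotype <- function(nRef, nAlt, config = svConfig()) {
    stopifnot(length(nRef) == length(nAlt), all(nRef >= 0), all(nAlt >= 0))
    tLow <- configValue(config, "t_low")
    tHigh <- configValue(config, "t_high")
    minDepth <- configValue(config, "min_depth")
    depth <- nRef + nAlt
    ratio <- ifelse(depth > 0, nAlt / depth, NA_real_)
    gt <- rep("./.", length(depth))
    det <- depth >= minDepth
    gt[det & ratio <= tLow] <- "0/0"
    gt[det & ratio >= tHigh] <- "1/1"
    gt[det & ratio > tLow & ratio < tHigh] <- "0/1"
    dosage <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt]
    data.frame(nRef = nRef, nAlt = nAlt, altRatio = ratio, gt = gt,
               dosage = unname(dosage))
}

#' Genotype one variant from a set of reads
#'
#' Convenience wrapper chaining [assignReads()] and [callGenotype()].
#'
#' @inheritParams assignReads
#' @param config a [svConfig()] object.
#' @return one-row data.frame as in [callGenotype()].
#' @export
genotypeFromReads <- function(reads, alleles, config = svConfig()) {
    a <- assignReads(reads, alleles, config = config)
    callGenotype(sum(a == "ref"), sum(a == "alt"), config = config)
}

#' Genotype a catalogue of insertion variants in one sample
#'
#' For every sequence-resolved variant longer than both the read length and
#' `min_genotype_size` (shorter variants are skipped, since reads must span
#' the breakpoint unambiguously), reads are fetched from the breakpoint window
#' (including unmapped mates placed there by the aligner, which often carry
#' the insertion-supporting evidence), assigned to the two alleles and
#' counted into a genotype.
#'
#' @param catalog an [InsertionCatalog].
#' @param bamFile the sample's BAM file (indexed).
#' @param reference reference genome (`DNAStringSet` or FASTA path).
#' @param config a [svConfig()] object.
#' @param sampleId sample name recorded in the result.
#' @param lib optional [LibraryStats] of the sample.
#' @return data.frame with one row per variant: `variantId`, `sampleId`,
#'   `nRef`, `nAlt`, `altRatio`, `gt`, `dosage`, `skipped` (reason or `NA`).
#' @export
genotypeSample <- function(catalog, bamFile, reference, config = svConfig(),
                           sampleId = basename(bamFile), lib = NULL) {
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    if (is.null(lib)) lib <- estimateLibraryStats(bamFile)
    readLen <- readLength(lib)
    minSize <- max(readLen, configValue(config, "min_genotype_size"))
    flankExt <- readLen + configValue(config, "flank_extension_extra")
    m <- S4Vectors::mcols(catalog)
    out <- vector("list", length(catalog))
    for (i in seq_along(catalog)) {
        chrom <- as.character(GenomicRanges::seqnames(catalog))[i]
        pos0 <- BiocGenerics::start(catalog)[i]   # anchor base == 0-based point
        vid <- m$variantId[i]
        if (m$svlen[i] <= minSize) {
            out[[i]] <- data.frame(variantId = vid, sampleId = sampleId,
                                   nRef = NA_integer_, nAlt = NA_integer_,
                                   altRatio = NA_real_, gt = "./.",
                                   dosage = NA_integer_,
                                   skipped = sprintf("svlen <= %d", minSize))
            next
        }
        alleles <- buildAlleles(chrom, pos0, as.character(m$insSeq[i]),
                                reference, readLen = readLen, config = config)
        if (is.null(alleles)) {
            out[[i]] <- data.frame(variantId = vid, sampleId = sampleId,
                                   nRef = NA_integer_, nAlt = NA_integer_,
                                   altRatio = NA_real_, gt = "./.",
                                   dosage = NA_integer_,
                                   skipped = "near contig end")
            next
        }
        window <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(start = max(1L, pos0 - flankExt + 1L),
                                    end = pos0 + flankExt))
        param <- Rsamtools::ScanBamParam(
            what = c("seq"), which = window,
            flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                          isSupplementaryAlignment = FALSE,
                                          isDuplicate = FALSE))
        reads <- as.character(Rsamtools::scanBam(bamFile, param = param)[[1]]$seq)
        g <- genotypeFromReads(reads, alleles, config = config)
        out[[i]] <- cbind(data.frame(variantId = vid, sampleId = sampleId),
                          g, skipped = NA_character_)
    }
    do.call(rbind, out)
}
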