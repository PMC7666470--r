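## VCF serialization of the catalogue (sequence-resolved ALT alleles, not
## symbolic <INS>, so downstream genotyping is self-contained) and of
## multi-sample genotypes.

.catalogVcfHeader <- function(samples = character(0)) {
    info <- S4Vectors::DataFrame(
        Number = c("1", "1", "1", "1", "1"),
        Type = c("Integer", "String", "String", "Integer", "String"),
        Description = c(
            "Insertion length",
            "Accepted trace sources (genome:locus:identity, comma separated)",
            "Ancestral state: retention_of_ancestral, novel_insertion or untraced",
            "1 when multi-genome traces were concordant, else 0",
            "Inferred mutational mechanism: VNTR, NAHR, TE or NH"),
        row.names = c("SVLEN", "TRACESRC", "ANCSTATE", "CONCORD", "MECH"))
    geno <- S4Vectors::DataFrame(
        Number = c("1", "R"),
        Type = c("String", "Integer"),
        Description = c("Genotype",
                        "Allele-supporting read counts (ref, alt)"),
        row.names = c("GT", "AD"))
    hdr <- VariantAnnotation::VCFHeader(samples = samples)
    VariantAnnotation::info(hdr) <- info
    VariantAnnotation::geno(hdr) <- geno
    hdr
}

# htslib-style readers require '##fileformat' as the very first line; also
# drop the run-dependent fileDate line so identical runs give identical files
.fixVcfHeader <- function(file) {
    lines <- readLines(file)
    lines <- lines[!startsWith(lines, "##fileformat") &
                   !startsWith(lines, "##fileDate")]
    writeLines(c("##fileformat=VCFv4.2", lines), file)
    invisible(file)
}

.catalogToVcf <- function(catalog, reference, genotypes = NULL) {
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    m <- S4Vectors::mcols(catalog)
    n <- length(catalog)
    chrom <- as.character(GenomicRanges::seqnames(catalog))
    pos <- BiocGenerics::start(catalog)          # 1-based anchor base
    refBase <- vapply(seq_len(n), function(i)
        as.character(Biostrings::subseq(.chromSeq(reference, chrom[i]),
                                        pos[i], pos[i])), character(1))
    alt <- paste0(refBase, as.character(m$insSeq))
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    names(rr) <- m$variantId
    fixed <- S4Vectors::DataFrame(
        REF = Biostrings::DNAStringSet(refBase),
        ALT = Biostrings::DNAStringSetList(as.list(alt)),
        QUAL = rep(NA_real_, n),
        FILTER = rep("PASS", n))
    mech <- if (!is.null(m$mech)) m$mech else rep(NA_character_, n)
    info <- S4Vectors::DataFrame(
        SVLEN = as.integer(m$svlen),
        TRACESRC = vapply(m$traceSources, function(x)
            if (length(x)) paste(x, collapse = ",") else ".", character(1)),
        ANCSTATE = m$ancestralState,
        CONCORD = as.integer(m$concordant),
        MECH = ifelse(is.na(mech), ".", mech))
    samples <- if (is.null(genotypes)) character(0) else colnames(genotypes$gt)
    hdr <- .catalogVcfHeader(samples)
    if (is.null(genotypes)) {
        vcf <- VariantAnnotation::VCF(rowRanges = rr, fixed = fixed,
                                      info = info, collapsed = TRUE)
    } else {
        geno <- S4Vectors::SimpleList(GT = genotypes$gt, AD = genotypes$ad)
        vcf <- VariantAnnotation::VCF(
            rowRanges = rr, fixed = fixed, info = info, collapsed = TRUE,
            colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                           row.names = samples),
            geno = geno)
    }
    VariantAnnotation::header(vcf) <- hdr
    vcf
}

#' Write an insertion catalogue as VCF
#'
#' Emits VCF 4.2 with the full inserted sequence in ALT (anchor base plus
#' insertion) and INFO keys SVLEN, TRACESRC, ANCSTATE, CONCORD and MECH.
#'
#' @param catalog an [InsertionCatalog].
#' @param reference reference genome (`DNAStringSet` or FASTA path).
#' @param file output VCF path.
#' @return `file`, invisibly.
#' @export
writeCatalogVcf <- function(catalog, reference, file) {
    vcf <- .catalogToVcf(catalog, reference)
    VariantAnnotation::writeVcf(vcf, file)
    .fixVcfHeader(file)
    invisible(file)
}

#' Write a multi-sample genotype VCF for a catalogue
#'
#' @param catalog an [InsertionCatalog].
#' @param reference reference genome.
#' @param gt character matrix (variants x samples) of `0/0`-style genotypes.
#' @param nRef,nAlt integer matrices of allele-supporting read counts.
#' @param file output VCF path.
#' @return `file`, invisibly.
#' @export
writeGenotypesVcf <- function(catalog, reference, gt, nRef, nAlt, file) {
    stopifnot(nrow(gt) == length(catalog))
    ad <- array(NA_integer_, dim = c(nrow(gt), ncol(gt), 2L),
                dimnames = list(NULL, colnames(gt), NULL))
    ad[, , 1L] <- as.matrix(nRef)
    ad[, , 2L] <- as.matrix(nAlt)
    vcf <- .catalogToVcf(catalog, reference,
                         genotypes = list(gt = as.matrix(gt), ad = ad))
    VariantAnnotation::writeVcf(vcf, file)
    .fixVcfHeader(file)
    invisible(file)
}

#' Read a catalogue VCF back into an [InsertionCatalog]
#'
#' @param file VCF path (as written by [writeCatalogVcf()]).
#' @return an [InsertionCatalog].
#' @export
readCatalogVcf <- function(file) {
    vcf <- VariantAnnotation::readVcf(file)
    rr <- SummarizedExperiment::rowRanges(vcf)
    n <- length(rr)
    if (n == 0L) return(.emptyCatalog())
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- vapply(VariantAnnotation::alt(vcf), function(x)
        as.character(x)[1], character(1))
    insSeq <- substring(alt, nchar(ref) + 1L)
    info <- VariantAnnotation::info(vcf)
    src <- lapply(info$TRACESRC, function(x) {
        if (is.na(x) || x == ".") character(0) else strsplit(x, ",")[[1]]
    })
    gr <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(rr)),
        IRanges::IRanges(BiocGenerics::start(rr), width = 1L))
    mech <- if ("MECH" %in% colnames(info))
        ifelse(info$MECH == ".", NA_character_, info$MECH) else NULL
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        variantId = names(rr) %||% sprintf("I_%d", seq_len(n)),
        insSeq = Biostrings::DNAStringSet(insSeq),
        svlen = as.integer(info$SVLEN),
        leftBp = BiocGenerics::start(rr),
        rightBp = BiocGenerics::start(rr),
        traceSources = IRanges::CharacterList(src),
        concordant = as.logical(info$CONCORD),
        ancestralState = info$ANCSTATE)
    if (!is.null(mech)) S4Vectors::mcols(gr)$mech <- mech
    new("InsertionCatalog", gr)
}
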