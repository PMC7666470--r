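#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom BiocGenerics start end strand width
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#' @importFrom stats sd rnorm runif rbinom setNames
#' @importFrom utils head write.table
#' @useDynLib InsertionTracer, .registration = TRUE
NULL

#' Paired-end library statistics
#'
#' Summary of a sequencing library estimated from properly paired reads:
#' the mean and standard deviation of the outer insert length and the modal
#' read length. These numbers drive the clustering and tag-pairing windows
#' (mean plus two standard deviations) and the discordance cutoff (mean plus
#' three standard deviations).
#'
#' @slot meanInsert numeric(1), mean outer insert length in bp.
#' @slot sdInsert numeric(1), standard deviation of the insert length in bp.
#' @slot readLength integer(1), modal read length in bp.
#' @slot nPairs integer(1), number of proper pairs the estimate used.
#'
#' @seealso [estimateLibraryStats()]
#' @export
setClass("LibraryStats",
    representation(meanInsert = "numeric", sdInsert = "numeric",
                   readLength = "integer", nPairs = "integer"))

setValidity("LibraryStats", function(object) {
    msg <- NULL
    if (length(object@meanInsert) != 1 || object@meanInsert <= 0)
        msg <- c(msg, "meanInsert must be a single positive number")
    if (length(object@sdInsert) != 1 || object@sdInsert < 0)
        msg <- c(msg, "sdInsert must be a single non-negative number")
    if (length(object@readLength) != 1 || object@readLength <= 0)
        msg <- c(msg, "readLength must be a single positive integer")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn LibraryStats constructor.
#' @param meanInsert,sdInsert,readLength,nPairs see slots.
#' @export
LibraryStats <- function(meanInsert, sdInsert, readLength, nPairs = NA_integer_) {
    new("LibraryStats", meanInsert = as.numeric(meanInsert),
        sdInsert = as.numeric(sdInsert),
        readLength = as.integer(readLength), nPairs = as.integer(nPairs))
}

#' @describeIn LibraryStats mean insert length (bp).
#' @param x a `LibraryStats` object.
#' @export
meanInsert <- function(x) x@meanInsert

#' @describeIn LibraryStats insert length standard deviation (bp).
#' @export
sdInsert <- function(x) x@sdInsert

#' @describeIn LibraryStats modal read length (bp).
#' @export
readLength <- function(x) x@readLength

setMethod("show", "LibraryStats", function(object) {
    cat(sprintf("LibraryStats: insert %.1f +/- %.1f bp, read length %d bp (%s pairs)\n",
                object@meanInsert, object@sdInsert, object@readLength,
                ifelse(is.na(object@nPairs), "?", format(object@nPairs))))
})

#' Discordant paired-end reads
#'
#' A [GenomicRanges::GRanges] subclass holding one row per discordant read
#' pair: the anchored (mapped, high-MAPQ) end gives the range and strand, and
#' metadata columns carry the anchor CIGAR/MAPQ/sequence plus the mate
#' sequence and its status (`"unmapped"` or `"discordant"`). Coordinates are
#' the usual 1-based GRanges convention.
#'
#' Required metadata columns: `qname`, `mapq`, `cigar`, `anchorSeq`
#' (`DNAStringSet`), `mateSeq` (`DNAStringSet`), `mateReverse` (logical; was
#' the mate's stored sequence reverse-complemented by the aligner),
#' `mateStatus`.
#'
#' @seealso [extractDiscordantPers()]
#' @export
setClass("DiscordantPairs", contains = "GRanges")

setValidity("DiscordantPairs", function(object) {
    need <- c("qname", "mapq", "cigar", "anchorSeq", "mateSeq",
              "mateReverse", "mateStatus")
    miss <- setdiff(need, colnames(S4Vectors::mcols(object)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    bad <- !S4Vectors::mcols(object)$mateStatus %in% c("unmapped", "discordant")
    if (any(bad)) return("mateStatus must be 'unmapped' or 'discordant'")
    TRUE
})

#' Insertion tags
#'
#' A [GenomicRanges::GRanges] subclass with one row per insertion tag: a
#' locally assembled contig split at a breakpoint into a reference-matching
#' flank and a partial inserted sequence. The range is the zero-width
#' breakpoint position (start = 1-based base after the last left-flank base
#' for `side == "left_flank"`; start = first right-flank base for
#' `side == "right_flank"`).
#'
#' Metadata columns: `side`, `flankSeq`, `insPartSeq` (`DNAStringSet`),
#' `cluster` (integer id), `nReads`, `flankMismatches`.
#'
#' @seealso [refineBreakpoint()], [pairInsertionTags()]
#' @export
setClass("InsertionTags", contains = "GRanges")

setValidity("InsertionTags", function(object) {
    need <- c("side", "flankSeq", "insPartSeq", "cluster", "nReads",
              "flankMismatches")
    miss <- setdiff(need, colnames(S4Vectors::mcols(object)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    if (!all(S4Vectors::mcols(object)$side %in% c("left_flank", "right_flank")))
        return("side must be 'left_flank' or 'right_flank'")
    TRUE
})

#' Paired insertion tags
#'
#' A [GenomicRanges::GRanges] subclass with one row per candidate insertion
#' event: a left-flank tag and a right-flank tag whose breakpoints fall within
#' the insert-size window. The range spans the two breakpoints.
#'
#' Metadata columns: `leftBp`, `rightBp` (0-based breakpoint coordinates),
#' `gap` (`rightBp - leftBp`; small negative values indicate breakpoint
#' microhomology), `leftInsPart`, `rightInsPart` (`DNAStringSet`),
#' `leftCluster`, `rightCluster`, `nReads`.
#'
#' @seealso [pairInsertionTags()], [traceInsertion()]
#' @export
setClass("PairedInsertionTags", contains = "GRanges")

setValidity("PairedInsertionTags", function(object) {
    need <- c("leftBp", "rightBp", "gap", "leftInsPart", "rightInsPart")
    miss <- setdiff(need, colnames(S4Vectors::mcols(object)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    TRUE
})

#' Target genome for the tracing step
#'
#' A genome against which paired-tag segments are traced to recover the full
#' inserted sequence. Its `class` drives the ancestral-state call: any
#' accepted trace to a `"nonhuman_primate"` genome marks the event as
#' retention of ancestral sequence; traces only to `"human_assembly"` or
#' `"unmapped_contig_db"` genomes mark it as a novel insertion.
#'
#' @slot name character(1) display name.
#' @slot sequences `DNAStringSet` of the genome.
#' @slot genomeClass one of `"nonhuman_primate"`, `"human_assembly"`,
#'   `"unmapped_contig_db"`.
#' @export
setClass("TargetGenome",
    representation(name = "character", sequences = "DNAStringSet",
                   genomeClass = "character"))

setValidity("TargetGenome", function(object) {
    ok <- c("nonhuman_primate", "human_assembly", "unmapped_contig_db")
    if (!object@genomeClass %in% ok)
        return(paste("class must be one of:", paste(ok, collapse = ", ")))
    TRUE
})

#' @describeIn TargetGenome constructor; `sequences` may be a `DNAStringSet`
#'   or the path to a FASTA file.
#' @param name display name.
#' @param sequences genome sequences or FASTA path.
#' @param class target class (see slots).
#' @export
targetGenome <- function(name, sequences,
                         class = c("nonhuman_primate", "human_assembly",
                                   "unmapped_contig_db")) {
    class <- match.arg(class)
    if (is.character(sequences))
        sequences <- Biostrings::readDNAStringSet(sequences)
    if (is(sequences, "DNAString"))
        sequences <- Biostrings::DNAStringSet(sequences)
    new("TargetGenome", name = name, sequences = sequences, genomeClass = class)
}

setMethod("show", "TargetGenome", function(object) {
    cat(sprintf("TargetGenome '%s' (%s): %d sequence(s), %.2f Mbp\n",
                object@name, object@genomeClass, length(object@sequences),
                sum(as.numeric(Biostrings::width(object@sequences))) / 1e6))
})

#' Catalogue of sequence-resolved insertion variants
#'
#' A [GenomicRanges::GRanges] subclass with one row per traced insertion. The
#' range is the single anchor base before the insertion point (left-breakpoint
#' frame). Metadata columns: `variantId`, `insSeq` (`DNAStringSet`, full
#' inserted sequence; empty when untraced), `svlen`, `leftBp`, `rightBp`
#' (0-based discovery breakpoints), `traceSources` (`CharacterList` of
#' `genome:locus:identity` strings), `concordant`, `ancestralState`
#' (`"retention_of_ancestral"`, `"novel_insertion"` or `"untraced"`), and
#' optionally `mech`/`mechEvidence` after mechanism classification.
#'
#' @seealso [traceInsertion()], [classifyMechanism()], [writeCatalogVcf()]
#' @export
setClass("InsertionCatalog", contains = "GRanges")

setValidity("InsertionCatalog", function(object) {
    need <- c("variantId", "insSeq", "svlen", "ancestralState")
    miss <- setdiff(need, colnames(S4Vectors::mcols(object)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    ok <- c("retention_of_ancestral", "novel_insertion", "untraced")
    if (!all(S4Vectors::mcols(object)$ancestralState %in% ok))
        return("invalid ancestralState value")
    TRUE
})

#' Genotyped insertion variants
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding biallelic
#' genotypes of catalogued insertions across samples. Assays: `dosage`
#' (alt-allele dosage 0/1/2, `NA` for `./.`), and optionally `nRef`/`nAlt`
#' (allele-supporting read counts). `colData` must contain a `population`
#' column; `rowData` carries `svlen`.
#'
#' @seealso [makeInsertionGenotypes()], [alleleFrequencies()], [pairwiseFst()]
#' @export
setClass("InsertionGenotypes", contains = "SummarizedExperiment")

setValidity("InsertionGenotypes", function(object) {
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
        return("dosage values must be 0, 1, 2 or NA")
    if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must have a 'population' column")
    if (!"svlen" %in% colnames(SummarizedExperiment::rowData(object)))
        return("rowData must have an 'svlen' column")
    TRUE
})

#' @describeIn InsertionGenotypes construct from a dosage matrix
#'   (variants x samples), a population label per sample and a variant length
#'   (bp) per variant.
#' @param dosage integer matrix, variants x samples, values 0/1/2/NA.
#' @param population character/factor of length `ncol(dosage)`.
#' @param svlen integer vector of length `nrow(dosage)`.
#' @param nRef,nAlt optional matrices of allele-supporting read counts.
#' @export
makeInsertionGenotypes <- function(dosage, population, svlen,
                                   nRef = NULL, nAlt = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    assays <- list(dosage = dosage)
    if (!is.null(nRef)) assays$nRef <- as.matrix(nRef)
    if (!is.null(nAlt)) assays$nAlt <- as.matrix(nAlt)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(
            population = as.character(population),
            row.names = colnames(dosage)),
        rowData = S4Vectors::DataFrame(svlen = as.integer(svlen)))
    new("InsertionGenotypes", se)
}
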