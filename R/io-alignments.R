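## Alignment input: library statistics and discordant pair selection.

.scanAll <- function(bamFile, what, flag = Rsamtools::scanBamFlag()) {
    param <- Rsamtools::ScanBamParam(what = what, flag = flag)
    res <- Rsamtools::scanBam(bamFile, param = param)[[1]]
    res
}

#' Estimate paired-end library statistics from a BAM file
#'
#' Computes the mean and standard deviation of the outer insert length and the
#' modal read length over properly paired, primary, non-duplicate alignments
#' (one record per pair, via positive TLEN). These statistics parameterize the
#' clustering and pairing windows downstream.
#'
#' @param bamFile path to a BAM file.
#' @param sampleSize maximum number of proper pairs to use; `Inf` (default)
#'   uses all. When finite, a deterministic evenly spaced subsample of the
#'   insert sizes (after sorting) is used, so the estimate does not depend on
#'   record order.
#' @param minProperPairs hard error if fewer proper pairs than this are found.
#' @return a [LibraryStats] object.
#' @examples
#' \dontrun{estimateLibraryStats("sample.bam")}
#' @export
estimateLibraryStats <- function(bamFile, sampleSize = Inf,
                                 minProperPairs = 100L) {
    flag <- Rsamtools::scanBamFlag(
        isPaired = TRUE, isProperPair = TRUE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
        isUnmappedQuery = FALSE)
    res <- .scanAll(bamFile, what = c("isize", "qwidth"), flag = flag)
    keep <- !is.na(res$isize) & res$isize > 0L
    isize <- res$isize[keep]
    qw <- res$qwidth[keep]
    n <- length(isize)
    if (n < minProperPairs)
        stop(sprintf("only %d proper pairs found (minimum %d required)",
                     n, minProperPairs))
    if (is.finite(sampleSize) && n > sampleSize) {
        o <- order(isize)
        idx <- o[round(seq(1L, n, length.out = sampleSize))]
        isize <- isize[idx]
        qw <- qw[idx]
        n <- length(isize)
    }
    tab <- table(qw)
    LibraryStats(meanInsert = mean(isize), sdInsert = stats::sd(isize),
                 readLength = as.integer(names(tab)[which.max(tab)]),
                 nPairs = n)
}

#' Select discordant paired-end reads
#'
#' Emits one record per read pair in which one end is anchored (mapped with
#' MAPQ at or above `minMapq`) while the other end is unmapped or discordantly
#' placed. Discordant placement means: the mate maps to a different
#' chromosome, the pair is not in FR orientation, or the outer insert exceeds
#' `mean + insert_sd_discordant * sd` of the library, judged directly from
#' TLEN rather than via the aligner's proper-pair flag (whose acceptance
#' window is usually wider). Secondary, supplementary and duplicate
#' records are ignored. When both ends of a discordantly mapped pair pass the
#' MAPQ filter, both are emitted as anchors (each locus sees the evidence).
#'
#' @param bamFile path to a BAM file (the whole file is scanned).
#' @param lib a [LibraryStats]; estimated from `bamFile` when `NULL`.
#' @param config a [svConfig()] object (uses `min_mapq`,
#'   `insert_sd_discordant`).
#' @return a [DiscordantPairs] object. Pairs whose unmapped mate record is
#'   missing from the file are skipped with a warning.
#' @export
extractDiscordantPers <- function(bamFile, lib = NULL, config = svConfig()) {
    minMapq <- configValue(config, "min_mapq")
    if (is.null(lib)) lib <- estimateLibraryStats(bamFile)
    maxInsert <- meanInsert(lib) +
        configValue(config, "insert_sd_discordant") * sdInsert(lib)

    flag <- Rsamtools::scanBamFlag(
        isPaired = TRUE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE, isDuplicate = FALSE)
    res <- .scanAll(bamFile, what = c("qname", "flag", "rname", "strand",
                                      "pos", "mapq", "cigar", "isize",
                                      "mrnm", "mpos", "seq"), flag = flag)
    n <- length(res$qname)
    if (n == 0L)
        return(.emptyDiscordantPairs())

    fl <- res$flag
    unmapped <- bitwAnd(fl, 4L) > 0L
    mateUnmapped <- bitwAnd(fl, 8L) > 0L
    reverse <- bitwAnd(fl, 16L) > 0L
    mateReverse <- bitwAnd(fl, 32L) > 0L
    proper <- bitwAnd(fl, 2L) > 0L
    first <- bitwAnd(fl, 64L) > 0L

    rname <- as.character(res$rname)
    mrnm <- as.character(res$mrnm)
    mapq <- res$mapq
    mapq[is.na(mapq)] <- 0L

    ## discordance of a mapped-mapped pair, judged from the anchor record
    sameChrom <- !is.na(mrnm) & !is.na(rname) & mrnm == rname
    ## FR orientation: leftmost read forward, rightmost reverse
    leftmost <- !is.na(res$pos) & !is.na(res$mpos) & res$pos <= res$mpos
    frOk <- sameChrom & ((leftmost & !reverse & mateReverse) |
                         (!leftmost & reverse & !mateReverse))
    ## the insert-size rule is applied directly (not via the aligner's
    ## proper-pair flag, whose window is typically wider than mean + k*sd)
    insBad <- is.na(res$isize) | abs(res$isize) > maxInsert
    pairDiscordant <- !unmapped & !mateUnmapped &
        (!sameChrom | !frOk | insBad)

    anchorUnmappedMate <- !unmapped & mateUnmapped & mapq >= minMapq
    anchorDiscordant <- pairDiscordant & mapq >= minMapq

    anchorIdx <- which(anchorUnmappedMate | anchorDiscordant)
    if (length(anchorIdx) == 0L)
        return(.emptyDiscordantPairs())

    ## locate the mate record of each anchor: same qname, opposite first flag
    key <- paste0(res$qname, "/", ifelse(first, 2L, 1L))  # key of the MATE
    recKey <- paste0(res$qname, "/", ifelse(first, 1L, 2L))
    mateRow <- match(key[anchorIdx], recKey)

    missing <- is.na(mateRow)
    if (any(missing)) {
        warning(sum(missing), " discordant pair(s) skipped: mate record ",
                "(and its sequence) not present in the file")
        anchorIdx <- anchorIdx[!missing]
        mateRow <- mateRow[!missing]
    }
    if (length(anchorIdx) == 0L)
        return(.emptyDiscordantPairs())

    gr <- GenomicRanges::GRanges(
        seqnames = rname[anchorIdx],
        ranges = IRanges::IRanges(start = res$pos[anchorIdx],
                                  width = Biostrings::width(res$seq)[anchorIdx]),
        strand = ifelse(reverse[anchorIdx], "-", "+"))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        qname = res$qname[anchorIdx],
        mapq = mapq[anchorIdx],
        cigar = res$cigar[anchorIdx],
        anchorSeq = res$seq[anchorIdx],
        mateSeq = res$seq[mateRow],
        mateReverse = reverse[mateRow],
        mateStatus = ifelse(mateUnmapped[anchorIdx], "unmapped", "discordant"))
    new("DiscordantPairs", gr)
}

.emptyDiscordantPairs <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        qname = character(0), mapq = integer(0), cigar = character(0),
        anchorSeq = Biostrings::DNAStringSet(), mateSeq = Biostrings::DNAStringSet(),
        mateReverse = logical(0), mateStatus = character(0))
    new("DiscordantPairs", gr)
}
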