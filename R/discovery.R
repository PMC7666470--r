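## Discovery: cluster discordant pairs, assemble strand-specific contigs,
## refine breakpoints into insertion tags, and pair tags into events.

#' Cluster discordant pairs by strand and anchor location
#'
#' Single-linkage clustering of anchor start positions, partitioned by
#' (chromosome, anchor strand), with link distance
#' `meanInsert + cluster_sd_window * sdInsert`. Clusters with fewer than
#' `min_support` members are dropped.
#'
#' @param pers a [DiscordantPairs] object.
#' @param lib a [LibraryStats] object.
#' @param config a [svConfig()] object (uses `cluster_sd_window`,
#'   `min_support`).
#' @return a `GRanges` with one row per cluster (span of anchor starts) and
#'   metadata columns `members` (an `IntegerList` of row indices into `pers`)
#'   and `n`.
#' @export
clusterPers <- function(pers, lib, config = svConfig()) {
    link <- meanInsert(lib) + configValue(config, "cluster_sd_window") * sdInsert(lib)
    minSupport <- configValue(config, "min_support")
    if (length(pers) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            members = IRanges::IntegerList(), n = integer(0))
        return(gr)
    }
    o <- order(as.character(GenomicRanges::seqnames(pers)),
               as.character(BiocGenerics::strand(pers)),
               BiocGenerics::start(pers))
    key <- paste0(as.character(GenomicRanges::seqnames(pers))[o], "/",
                  as.character(BiocGenerics::strand(pers))[o])
    pos <- BiocGenerics::start(pers)[o]
    newGroup <- c(TRUE, key[-1] != key[-length(key)] |
                        diff(pos) > link)
    cid <- cumsum(newGroup)
    membersByCluster <- split(o, cid)
    n <- lengths(membersByCluster)
    keep <- n >= minSupport
    membersByCluster <- membersByCluster[keep]
    if (length(membersByCluster) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            members = IRanges::IntegerList(), n = integer(0))
        return(gr)
    }
    first <- vapply(membersByCluster, function(i) i[[1]], integer(1))
    spanStart <- vapply(membersByCluster, function(i)
        min(BiocGenerics::start(pers)[i]), integer(1))
    spanEnd <- vapply(membersByCluster, function(i)
        max(BiocGenerics::end(pers)[i]), integer(1))
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(pers))[first],
        ranges = IRanges::IRanges(start = spanStart, end = spanEnd),
        strand = as.character(BiocGenerics::strand(pers))[first])
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        members = IRanges::IntegerList(unname(membersByCluster)),
        n = unname(lengths(membersByCluster)))
    gr
}

#' Orient the reads of one cluster for strand-specific assembly
#'
#' Returns all member reads of a cluster in reference-forward orientation:
#' anchored sequences are stored reference-oriented by the aligner; the mate
#' of a plus-strand anchor was sequenced from the opposite strand (FR
#' library), so its sequencing-orientation sequence is reverse-complemented,
#' while the mate of a minus-strand anchor is used as sequenced.
#'
#' @param pers a [DiscordantPairs] object.
#' @param members integer indices of the cluster members in `pers`.
#' @return character vector of 2x`length(members)` oriented read sequences.
#' @export
clusterReadSet <- function(pers, members) {
    m <- S4Vectors::mcols(pers)[members, , drop = FALSE]
    anchorStrand <- as.character(BiocGenerics::strand(pers))[members]
    anchor <- as.character(m$anchorSeq)
    mateStored <- as.character(m$mateSeq)
    ## back to sequencing orientation, then into the anchor's reference frame
    mateSeqd <- ifelse(m$mateReverse, revComp(mateStored), mateStored)
    mateRef <- ifelse(anchorStrand == "+", revComp(mateSeqd), mateSeqd)
    c(anchor, mateRef)
}

#' Local De Bruijn assembly of a read cluster
#'
#' Builds a De Bruijn graph (k-mers kept at coverage >= `min_kmer_cov`) from
#' the oriented anchored and mate reads of one cluster, emits maximal
#' unbranched paths as contigs, and places every read back onto the contigs by
#' exact k-mer seeding with a mismatch-tolerant check.
#'
#' @param reads character vector of reads, all in one orientation
#'   (see [clusterReadSet()]).
#' @param config a [svConfig()] object (uses `k`, `min_kmer_cov`,
#'   `placement_mm_frac`, `max_contig_len`).
#' @param k override of the configured k-mer size (used by the retry ladder
#'   `k_fallback` when the primary k yields no refinable contig).
#' @return list with elements `contigs` (character), `coverage` (mean k-mer
#'   coverage per contig) and `placements` (data.frame: read, contig, offset,
#'   mismatches, overlap). Empty contig set when no read could be placed.
#' @export
assembleCluster <- function(reads, config = svConfig(),
                            k = configValue(config, "k")) {
    res <- cpp_assemble(as.character(reads), k,
                        configValue(config, "min_kmer_cov"),
                        configValue(config, "placement_mm_frac"),
                        configValue(config, "max_contig_len"))
    placed <- table(factor(res$placements$contig,
                           levels = seq_along(res$contigs)))
    keep <- which(placed >= configValue(config, "min_placed_reads"))
    if (length(keep) == 0L)
        return(list(contigs = character(0), coverage = numeric(0),
                    placements = res$placements[0, , drop = FALSE]))
    res$contigs <- res$contigs[keep]
    res$coverage <- res$coverage[keep]
    res$placements <- res$placements[res$placements$contig %in% keep, ,
                                     drop = FALSE]
    res$placements$contig <- match(res$placements$contig, keep)
    res
}

#' Validate a contig against its read placements
#'
#' A contig is accepted when its placed reads are mutually consistent: all in
#' the cluster orientation (reads placing in the opposite orientation never
#' seed, so placement itself enforces strand consistency) and tiling the
#' contig in a single chain with no unsupported internal gap larger than the
#' read length. Chimeric joins leave such gaps and are rejected.
#'
#' @param contig contig sequence (character).
#' @param placements data.frame with columns `read`, `offset` and `overlap`
#'   for this contig (see [assembleCluster()]).
#' @param readLength read length in bp.
#' @return `TRUE` or `FALSE` with attribute `reason`.
#' @export
validateContig <- function(contig, placements, readLength) {
    if (nrow(placements) == 0L)
        return(structure(FALSE, reason = "no reads placed"))
    start <- pmax(0L, placements$offset)
    end <- start + placements$overlap
    o <- order(start)
    start <- start[o]; end <- end[o]
    hi <- cummax(end)
    gaps <- start[-1] - hi[-length(hi)]
    if (length(gaps) && max(gaps) > readLength)
        return(structure(FALSE,
                         reason = sprintf("unsupported gap of %d bp", max(gaps))))
    TRUE
}

#' Refine a contig into an insertion tag
#'
#' Anchors the contig in the local reference by exact k-mer seeding and runs a
#' banded affine-gap prefix (left side) or suffix (right side) alignment to
#' find the split point that maximizes the reference-matching flank: the
#' maximal flank becomes `flankSeq`, its terminal reference coordinate the
#' breakpoint, and the clipped remainder the partial inserted sequence. Ties
#' favor the longer flank, so under breakpoint microhomology left tags shift
#' right and right tags shift left.
#'
#' @param contig contig sequence (character).
#' @param localRef local reference sequence (character or `DNAString`).
#' @param origin 0-based coordinate of `localRef[1]` on the chromosome.
#' @param side `"left_flank"` (plus-strand cluster: flank is the contig
#'   prefix) or `"right_flank"` (minus-strand cluster: flank is the suffix).
#' @param chrom chromosome name for the resulting tag.
#' @param cluster integer cluster id recorded in the tag.
#' @param nReads read support recorded in the tag.
#' @param config a [svConfig()] object (uses `min_flank`, `min_ins_part`,
#'   `flank_mm_tol`, `refine_seed_k`, `refine_band`).
#' @return an [InsertionTags] object of length 1, or `NULL` when the contig
#'   has no reference-matching segment of at least `min_flank` bp, no clipped
#'   remainder of at least `min_ins_part` bp, or too many flank mismatches.
#' @export
refineBreakpoint <- function(contig, localRef, origin, side, chrom = "ref",
                             cluster = NA_integer_, nReads = NA_integer_,
                             config = svConfig()) {
    side <- match.arg(side, c("left_flank", "right_flank"))
    contig <- .dnaChar(contig)
    localRef <- .dnaChar(localRef)
    sk <- configValue(config, "refine_seed_k")
    band <- configValue(config, "refine_band")
    n <- nchar(contig)
    m <- nchar(localRef)
    if (n < configValue(config, "min_flank") + configValue(config, "min_ins_part"))
        return(NULL)

    rev1 <- function(x) as.character(Biostrings::reverse(Biostrings::DNAString(x)))
    if (side == "left_flank") { q <- contig; t <- localRef } else {
        q <- rev1(contig); t <- rev1(localRef)
    }
    hits <- cpp_kmer_hits(q, t, k = sk)
    if (nrow(hits) == 0L) return(NULL)
    ## anchor candidates from seeds near the flank end of the contig
    hits <- hits[order(hits$qpos), , drop = FALSE]
    hits <- hits[hits$qpos <= max(60L, min(hits$qpos)), , drop = FALSE]
    diags <- unique(hits$tpos - hits$qpos)
    diags <- diags[diags >= 0 & diags < m]
    if (length(diags) == 0L) return(NULL)
    diags <- utils::head(diags, 8L)

    best <- NULL
    for (a0 in diags) {
        sp <- cpp_prefix_split(q, t, t0 = a0, band = band)
        if (is.null(best) || sp$score > best$score) { best <- sp; best$a0 <- a0 }
    }
    split <- best$split
    insLen <- n - split
    if (split < configValue(config, "min_flank")) return(NULL)
    if (insLen < configValue(config, "min_ins_part")) return(NULL)
    if (best$mismatches > configValue(config, "flank_mm_tol") * split)
        return(NULL)

    if (side == "left_flank") {
        flankSeq <- substr(contig, 1L, split)
        insPart <- substr(contig, split + 1L, n)
        bp0 <- origin + best$t_end           # 0-based point after last flank base
    } else {
        flankSeq <- substr(contig, n - split + 1L, n)
        insPart <- substr(contig, 1L, n - split)
        bp0 <- origin + (m - best$t_end)     # 0-based first flank base
    }
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = bp0 + 1L, width = 0L),
        strand = "*")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        side = side,
        flankSeq = Biostrings::DNAStringSet(flankSeq),
        insPartSeq = Biostrings::DNAStringSet(insPart),
        cluster = as.integer(cluster),
        nReads = as.integer(nReads),
        flankMismatches = as.integer(best$mismatches))
    new("InsertionTags", gr)
}

.emptyTags <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        side = character(0), flankSeq = Biostrings::DNAStringSet(),
        insPartSeq = Biostrings::DNAStringSet(), cluster = integer(0),
        nReads = integer(0), flankMismatches = integer(0))
    new("InsertionTags", gr)
}

#' Pair left- and right-flank insertion tags into candidate events
#'
#' Greedy one-to-one matching: all eligible (left, right) tag pairs on the
#' same chromosome whose breakpoint gap `rightBp - leftBp` lies within
#' `[-max_microhomology, meanInsert + pair_sd_window * sdInsert]` are sorted
#' by absolute gap (ties by position) and taken while both tags are unused.
#' Small negative gaps arise from breakpoint microhomology, where the maximal
#' flanks of the two tags overlap.
#'
#' @param tags an [InsertionTags] object.
#' @param lib a [LibraryStats] object.
#' @param config a [svConfig()] object (uses `pair_sd_window`,
#'   `max_microhomology`).
#' @return a [PairedInsertionTags] object.
#' @export
pairInsertionTags <- function(tags, lib, config = svConfig()) {
    window <- meanInsert(lib) + configValue(config, "pair_sd_window") * sdInsert(lib)
    minGap <- -configValue(config, "max_microhomology")
    m <- S4Vectors::mcols(tags)
    bp0 <- BiocGenerics::start(tags) - 1L
    chrom <- as.character(GenomicRanges::seqnames(tags))
    li <- which(m$side == "left_flank")
    ri <- which(m$side == "right_flank")
    cand <- NULL
    if (length(li) && length(ri)) {
        cand <- expand.grid(l = li, r = ri)
        cand <- cand[chrom[cand$l] == chrom[cand$r], , drop = FALSE]
        cand$gap <- bp0[cand$r] - bp0[cand$l]
        cand <- cand[cand$gap >= minGap & cand$gap <= window, , drop = FALSE]
    }
    if (is.null(cand) || nrow(cand) == 0L) return(.emptyPairs())
    cand <- cand[order(abs(cand$gap), bp0[cand$l], bp0[cand$r]), , drop = FALSE]
    usedL <- usedR <- integer(0)
    takeL <- takeR <- integer(0)
    for (i in seq_len(nrow(cand))) {
        l <- cand$l[i]; r <- cand$r[i]
        if (l %in% usedL || r %in% usedR) next
        usedL <- c(usedL, l); usedR <- c(usedR, r)
        takeL <- c(takeL, l); takeR <- c(takeR, r)
    }
    lbp <- bp0[takeL]; rbp <- bp0[takeR]
    gr <- GenomicRanges::GRanges(
        seqnames = chrom[takeL],
        ranges = IRanges::IRanges(start = pmin(lbp, rbp) + 1L,
                                  end = pmax(lbp, rbp)),
        strand = "*")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        leftBp = lbp, rightBp = rbp, gap = rbp - lbp,
        leftInsPart = m$insPartSeq[takeL],
        rightInsPart = m$insPartSeq[takeR],
        leftCluster = m$cluster[takeL], rightCluster = m$cluster[takeR],
        nReads = m$nReads[takeL] + m$nReads[takeR])
    new("PairedInsertionTags", gr)
}

.emptyPairs <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        leftBp = integer(0), rightBp = integer(0), gap = integer(0),
        leftInsPart = Biostrings::DNAStringSet(),
        rightInsPart = Biostrings::DNAStringSet(),
        leftCluster = integer(0), rightCluster = integer(0),
        nReads = integer(0))
    new("PairedInsertionTags", gr)
}

#' Run the full discovery stage on a BAM file
#'
#' Selects discordant pairs, clusters them by strand and location, assembles
#' each cluster into local contigs, keeps the best-supported validated contig
#' per cluster, refines it into an insertion tag, and pairs left/right tags
#' into candidate insertion events. Per-stage counters are logged to stderr
#' and returned, so the funnel from read pairs to events is reproducible.
#'
#' @param bamFile coordinate-sorted, indexed BAM (or name-collated; the whole
#'   file is scanned).
#' @param reference reference genome: `DNAStringSet` or FASTA path.
#' @param config a [svConfig()] object.
#' @param lib optional [LibraryStats]; estimated from the BAM when `NULL`.
#' @return list with `tags` ([InsertionTags]), `pairs`
#'   ([PairedInsertionTags]), `lib`, `clusters` and `counters` (named integer
#'   vector: pers, clusters, contigsAccepted, contigsRejected, tags, pairs).
#' @export
discoverInsertions <- function(bamFile, reference, config = svConfig(),
                               lib = NULL) {
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    if (is.null(lib)) lib <- estimateLibraryStats(bamFile)
    pers <- extractDiscordantPers(bamFile, lib = lib, config = config)
    clusters <- clusterPers(pers, lib, config = config)
    .log("discovery: %d discordant pairs, %d clusters", length(pers),
         length(clusters))

    pad <- as.integer(meanInsert(lib) +
                      configValue(config, "cluster_sd_window") * sdInsert(lib) +
                      readLength(lib) + 200L)
    tagList <- list()
    nAccept <- 0L; nReject <- 0L
    for (ci in seq_along(clusters)) {
        members <- clusters$members[[ci]]
        strandC <- as.character(BiocGenerics::strand(clusters))[ci]
        chrom <- as.character(GenomicRanges::seqnames(clusters))[ci]
        reads <- clusterReadSet(pers, members)
        refSeq <- .chromSeq(reference, chrom)
        origin <- max(0L, BiocGenerics::start(clusters)[ci] - 1L - pad)
        localRef <- .sub0(refSeq, origin, BiocGenerics::end(clusters)[ci] + pad)
        side <- if (strandC == "+") "left_flank" else "right_flank"
        ## assemble at the primary k; if no refinable contig emerges, retry
        ## at smaller k (better junction connectivity in sparse clusters);
        ## within one assembly, contigs are tried in decreasing read support
        ## and the first validated contig yielding a tag wins (at most one
        ## tag per cluster)
        anyValid <- FALSE
        tag <- NULL
        for (kk in c(configValue(config, "k"),
                     configValue(config, "k_fallback"))) {
            asm <- assembleCluster(reads, config = config, k = kk)
            if (length(asm$contigs) == 0L) next
            placed <- table(factor(asm$placements$contig,
                                   levels = seq_along(asm$contigs)))
            for (cand in order(-as.integer(placed))) {
                if (placed[cand] == 0L) break
                pl <- asm$placements[asm$placements$contig == cand, ,
                                     drop = FALSE]
                if (!isTRUE(validateContig(asm$contigs[[cand]], pl,
                                           readLength(lib)))) next
                anyValid <- TRUE
                tag <- refineBreakpoint(asm$contigs[[cand]], localRef, origin,
                                        side, chrom = chrom, cluster = ci,
                                        nReads = as.integer(placed[cand]),
                                        config = config)
                if (!is.null(tag)) break
            }
            if (!is.null(tag)) break
        }
        if (anyValid) nAccept <- nAccept + 1L else nReject <- nReject + 1L
        if (!is.null(tag)) tagList[[length(tagList) + 1L]] <- tag
    }
    tags <- if (length(tagList)) {
        suppressWarnings(do.call(c, tagList))
    } else .emptyTags()
    pairs <- pairInsertionTags(tags, lib, config = config)
    counters <- c(pers = length(pers), clusters = length(clusters),
                  contigsAccepted = nAccept, contigsRejected = nReject,
                  tags = length(tags), pairs = length(pairs))
    .log("discovery: %d contigs accepted, %d rejected, %d tags, %d pairs",
         nAccept, nReject, length(tags), length(pairs))
    list(tags = tags, pairs = pairs, lib = lib, clusters = clusters,
         counters = counters)
}
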