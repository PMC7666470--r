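## Tracing: locate syntenic loci in target genomes via the reference flanks,
## pull the candidate full insertion sequence, validate it with the partial
## inserted sequences, and classify the ancestral state.

## Locate one flank in one target sequence by exact k-mer seeding plus a
## diagonal identity check. Returns data.frame of candidate loci
## (tpos = 0-based start of the flank on the target, identity) or NULL.
.locateFlank <- function(flank, targetChar, config) {
    k <- configValue(config, "trace_seed_k")
    step <- configValue(config, "trace_seed_step")
    hits <- cpp_kmer_hits(.dnaChar(flank), targetChar, k = k, step = step,
                          max_per = 64L)
    if (nrow(hits) == 0L) return(NULL)
    diag <- hits$tpos - hits$qpos
    tab <- sort(table(diag), decreasing = TRUE)
    cand <- as.integer(names(tab))[seq_len(min(8L, length(tab)))]
    cand <- cand[cand >= 0]
    if (!length(cand)) return(NULL)
    fl <- nchar(.dnaChar(flank))
    res <- lapply(cand, function(d) {
        mm <- cpp_diag_matches(.dnaChar(flank), targetChar, 0L, d, fl)
        data.frame(tpos = d, identity = mm[[1]] / fl, score = mm[[1]])
    })
    out <- do.call(rbind, res)
    out[order(-out$score), , drop = FALSE]
}

#' Locate the syntenic region of a paired-tag site in a target genome
#'
#' Extracts `trace_flank_len` bp of reference sequence on each side of the
#' event, anchors both flanks in the target genome (exact k-mer seeding plus
#' identity verification, forward then reverse-complement strand), and returns
#' the interval between the inner flank ends. A flank must map uniquely:
#' its best locus score must exceed `unique_ratio` times the second best.
#'
#' @param chrom,leftBp,rightBp event site: chromosome and 0-based left/right
#'   breakpoints (see [PairedInsertionTags]).
#' @param reference reference genome (`DNAStringSet`).
#' @param target a [TargetGenome].
#' @param config a [svConfig()] object.
#' @return `NULL` when either flank cannot be placed uniquely and
#'   consistently; otherwise a list with `targetSeqname`, `strand`,
#'   `insStart`/`insEnd` (0-based half-open candidate interval on the target,
#'   already in the left-breakpoint frame, i.e. including `leftBp - rightBp`
#'   microhomology bases), `identity` (mean flank identity).
#' @export
locateSyntenicRegion <- function(chrom, leftBp, rightBp, reference, target,
                                 config = svConfig()) {
    flankLen <- configValue(config, "trace_flank_len")
    refSeq <- .chromSeq(reference, chrom)
    lFlank <- .sub0(refSeq, leftBp - flankLen, leftBp)
    rFlank <- .sub0(refSeq, rightBp, rightBp + flankLen)
    if (length(lFlank) < flankLen || length(rFlank) < flankLen) {
        .log("trace: flank extraction out of bounds at %s:%d", chrom, leftBp)
        return(NULL)
    }
    overlap <- max(0L, leftBp - rightBp)   # breakpoint microhomology
    uniqueRatio <- configValue(config, "unique_ratio")
    maxSize <- configValue(config, "max_trace_size")

    for (ti in seq_along(target@sequences)) {
        tname <- names(target@sequences)[ti]
        tFwd <- as.character(target@sequences[[ti]])
        for (strand in c("+", "-")) {
            tChar <- if (strand == "+") tFwd else revComp(tFwd)
            lc <- .locateFlank(lFlank, tChar, config)
            rc <- .locateFlank(rFlank, tChar, config)
            if (is.null(lc) || is.null(rc)) next
            lOk <- lc$identity[1] >= 0.8 &&
                (nrow(lc) < 2 || lc$score[1] >= uniqueRatio * lc$score[2])
            rOk <- rc$identity[1] >= 0.8 &&
                (nrow(rc) < 2 || rc$score[1] >= uniqueRatio * rc$score[2])
            if (!lOk || !rOk) next
            insStart <- lc$tpos[1] + length(lFlank)
            insEnd <- rc$tpos[1] + overlap
            len <- insEnd - insStart
            if (len < 0 || len > maxSize) next
            return(list(targetSeqname = tname, strand = strand,
                        insStart = insStart, insEnd = insEnd,
                        identity = mean(c(lc$identity[1], rc$identity[1]))))
        }
    }
    NULL
}

## identity of an insertion part against the corresponding end of a candidate
## sequence (local alignment; fraction of part bases matched)
.partIdentity <- function(part, candidate, end = c("left", "right")) {
    end <- match.arg(end)
    pl <- nchar(part)
    if (pl == 0L) return(NA_real_)
    cl <- nchar(candidate)
    win <- min(cl, pl + 100L)
    sub <- if (end == "left") substr(candidate, 1L, win)
           else substr(candidate, cl - win + 1L, cl)
    sw <- cpp_sw_affine(part, sub)
    sw$matches / pl
}

#' Check concordance of traced candidates from multiple genomes
#'
#' All-pairs global alignment of the candidate sequences; the set is
#' concordant when every pair reaches `concord_identity` identity over the
#' shorter sequence. The consensus is the candidate with the highest mean
#' pairwise identity (ties: longer sequence, then lexicographically smaller
#' genome name).
#'
#' @param candidates named character vector (names = genome names) of
#'   candidate full insertion sequences; length >= 2.
#' @param config a [svConfig()] object.
#' @return list with `concordant` (logical) and `consensus` (name of the
#'   chosen candidate).
#' @export
checkConcordance <- function(candidates, config = svConfig()) {
    stopifnot(length(candidates) >= 2L)
    n <- length(candidates)
    idm <- matrix(1, n, n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(candidates[[i]]),
            Biostrings::DNAString(candidates[[j]]), type = "global")
        idm[i, j] <- idm[j, i] <- Biostrings::nmatch(aln) /
            min(nchar(candidates[[i]]), nchar(candidates[[j]]))
    }
    thr <- configValue(config, "concord_identity")
    concordant <- all(idm[upper.tri(idm)] >= thr)
    meanId <- rowMeans(idm)
    o <- order(-meanId, -nchar(candidates), names(candidates))
    list(concordant = concordant, consensus = names(candidates)[o[1]],
         identities = idm)
}

#' Classify the ancestral state of a traced insertion
#'
#' Any accepted trace to a non-human-primate genome implies the inserted
#' sequence predates the human lineage (the reference carries a deletion of
#' ancestral sequence); traces only to other human assemblies or unmapped
#' contig databases imply a novel insertion; no trace leaves the event
#' untraced.
#'
#' @param sourceClasses character vector of target classes with accepted
#'   traces (subset of `"nonhuman_primate"`, `"human_assembly"`,
#'   `"unmapped_contig_db"`).
#' @return one of `"retention_of_ancestral"`, `"novel_insertion"`,
#'   `"untraced"`.
#' @export
classifyAncestralState <- function(sourceClasses) {
    if ("nonhuman_primate" %in% sourceClasses) "retention_of_ancestral"
    else if (any(c("human_assembly", "unmapped_contig_db") %in% sourceClasses))
        "novel_insertion"
    else "untraced"
}

#' Trace the full inserted sequence of one paired-tag event
#'
#' For each target genome with a syntenic locus, the candidate full insertion
#' is the target sequence between the flank-anchored breakpoints; it is
#' accepted when both partial inserted sequences align to its corresponding
#' ends at `trace_identity` identity or better. Accepted candidates from
#' several genomes are checked for concordance and the consensus becomes the
#' full inserted sequence.
#'
#' @param chrom,leftBp,rightBp event site (0-based breakpoints).
#' @param leftInsPart,rightInsPart partial inserted sequences (character; one
#'   may be empty, not both).
#' @param reference reference genome (`DNAStringSet`).
#' @param targets list of [TargetGenome] objects.
#' @param config a [svConfig()] object.
#' @return list with `insSeq` (character; `""` when untraced), `sources`
#'   (character vector `genome:locus:identity`), `sourceClasses`,
#'   `concordant`, `ancestralState`.
#' @export
traceInsertion <- function(chrom, leftBp, rightBp, leftInsPart, rightInsPart,
                           reference, targets, config = svConfig()) {
    if (nchar(leftInsPart) == 0L && nchar(rightInsPart) == 0L)
        stop("at least one partial inserted sequence is required")
    thr <- configValue(config, "trace_identity")
    cand <- character(0); srcs <- character(0); classes <- character(0)
    for (tg in targets) {
        loc <- locateSyntenicRegion(chrom, leftBp, rightBp, reference, tg,
                                    config = config)
        if (is.null(loc)) next
        tseq <- tg@sequences[[loc$targetSeqname]]
        tChar <- if (loc$strand == "+") as.character(tseq)
                 else revComp(as.character(tseq))
        candidate <- substr(tChar, loc$insStart + 1L, loc$insEnd)
        if (nchar(candidate) == 0L) next
        idL <- .partIdentity(.dnaChar(leftInsPart), candidate, "left")
        idR <- .partIdentity(.dnaChar(rightInsPart), candidate, "right")
        ids <- c(idL, idR)
        ids <- ids[!is.na(ids)]
        if (!length(ids) || any(ids < thr)) next
        cand[tg@name] <- candidate
        srcs <- c(srcs, sprintf("%s:%s:%d-%d:%.3f", tg@name, loc$targetSeqname,
                                loc$insStart, loc$insEnd, mean(ids)))
        classes <- c(classes, tg@genomeClass)
    }
    if (length(cand) == 0L)
        return(list(insSeq = "", sources = character(0),
                    sourceClasses = character(0), concordant = NA,
                    ancestralState = "untraced"))
    concordant <- TRUE
    chosen <- names(cand)[1]
    if (length(cand) >= 2L) {
        cc <- checkConcordance(cand, config = config)
        concordant <- cc$concordant
        chosen <- cc$consensus
    }
    list(insSeq = unname(cand[[chosen]]), sources = srcs,
         sourceClasses = classes, concordant = concordant,
         ancestralState = classifyAncestralState(classes))
}

#' Trace all paired-tag events into a sequence-resolved catalogue
#'
#' Runs [traceInsertion()] on every event and assembles an
#' [InsertionCatalog]. Variant ids are `I_<n>` in position order.
#'
#' @param pairs a [PairedInsertionTags] object.
#' @param reference reference genome (`DNAStringSet` or FASTA path).
#' @param targets list of [TargetGenome] objects.
#' @param config a [svConfig()] object.
#' @param keepUntraced keep events with no accepted trace (default `FALSE`,
#'   matching the pipeline's use of tracing as a confirmation filter).
#' @return an [InsertionCatalog].
#' @export
traceCatalog <- function(pairs, reference, targets, config = svConfig(),
                         keepUntraced = FALSE) {
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    m <- S4Vectors::mcols(pairs)
    rows <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
        chrom <- as.character(GenomicRanges::seqnames(pairs))[i]
        tr <- traceInsertion(chrom, m$leftBp[i], m$rightBp[i],
                             as.character(m$leftInsPart[i]),
                             as.character(m$rightInsPart[i]),
                             reference, targets, config = config)
        rows[[i]] <- tr
    }
    traced <- vapply(rows, function(x) nzchar(x$insSeq), logical(1))
    keep <- if (keepUntraced) seq_along(rows) else which(traced)
    .log("tracing: %d/%d events traced", sum(traced), length(pairs))
    if (!length(keep)) return(.emptyCatalog())

    ## left-breakpoint frame, then canonical left-normalized representation
    chroms <- as.character(GenomicRanges::seqnames(pairs))[keep]
    pos0 <- m$leftBp[keep]
    seqs <- vapply(rows[keep], function(x) x$insSeq, character(1))
    for (j in seq_along(keep)) {
        if (!nzchar(seqs[j])) next
        nrm <- normalizeInsertion(pos0[j], seqs[j], .chromSeq(reference, chroms[j]))
        pos0[j] <- nrm$pos
        seqs[j] <- nrm$seq
    }
    o <- order(chroms, pos0)
    keep <- keep[o]; chroms <- chroms[o]; pos0 <- pos0[o]; seqs <- seqs[o]
    gr <- GenomicRanges::GRanges(
        seqnames = chroms,
        ranges = IRanges::IRanges(start = pos0, width = 1L),  # anchor base
        strand = "*")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        variantId = sprintf("I_%d", seq_along(keep)),
        insSeq = Biostrings::DNAStringSet(seqs),
        svlen = nchar(seqs),
        leftBp = m$leftBp[keep], rightBp = m$rightBp[keep],
        traceSources = IRanges::CharacterList(
            lapply(rows[keep], function(x) x$sources)),
        concordant = vapply(rows[keep], function(x) isTRUE(x$concordant),
                            logical(1)),
        ancestralState = vapply(rows[keep], function(x) x$ancestralState,
                                character(1)))
    new("InsertionCatalog", gr)
}

.emptyCatalog <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        variantId = character(0), insSeq = Biostrings::DNAStringSet(),
        svlen = integer(0), leftBp = integer(0), rightBp = integer(0),
        traceSources = IRanges::CharacterList(),
        concordant = logical(0), ancestralState = character(0))
    new("InsertionCatalog", gr)
}
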