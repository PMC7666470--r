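## Simulation: synthetic genomes with interspersed repeats, insertion
## implanting, paired-end read simulation and benchmark scoring.

#' Built-in synthetic repeat consensus library
#'
#' A small fixed library of synthetic repeat elements (an Alu-sized SINE-like
#' 300-mer, a LINE-like 2-kbp element, an SVA-like 1.2-kbp composite and a
#' 171-bp satellite monomer) generated once from a hard-coded RNG stream, so
#' it is identical across sessions. Genomes built with
#' [generateSyntheticGenome()] share this library, which makes donor-derived
#' insertions "non-unique" with respect to an acceptor genome, mimicking
#' repeat sharing between real chromosomes.
#'
#' @return named character vector of consensus sequences.
#' @export
repeatLibrary <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        cache <<- .withSeed(20111L, {
            rb <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
            sat <- rb(171L)
            c(aluSyn = rb(300L), lineSyn = rb(2000L), svaSyn = rb(1200L),
              satSyn = sat)
        })
        cache
    }
})

## substitute a fraction of bases in one sequence (uses ambient RNG)
.mutateSeq <- function(seq, rate) {
    n <- nchar(seq)
    nm <- stats::rbinom(1L, n, rate)
    if (nm == 0L) return(seq)
    pos <- sample.int(n, nm)
    shift <- sample.int(3L, nm, replace = TRUE)
    as.character(cpp_apply_subs(seq, rep(1L, nm), pos, shift))
}

#' Generate a synthetic genome with interspersed repeats
#'
#' An i.i.d. background sequence at the requested GC content, with diverged
#' copies of the built-in repeat library placed at non-overlapping positions
#' until they cover approximately `repeatDensity` of the sequence.
#' Deterministic for a fixed `seed`.
#'
#' @param length genome length in bp (>= 10 kbp).
#' @param gc GC fraction of the background (default 0.41, human-like).
#' @param repeatDensity target fraction covered by repeat copies (must be
#'   < 1); 0 disables repeat placement.
#' @param divergence per-copy substitution rate applied to each repeat copy
#'   (default 0.05).
#' @param seed integer seed; `NULL` uses the ambient RNG state.
#' @param name sequence name.
#' @return `DNAStringSet` of length 1; `metadata()$repeats` holds a `GRanges`
#'   of the placed copies (family in `mcols`).
#' @export
generateSyntheticGenome <- function(length, gc = 0.41, repeatDensity = 0.2,
                                    divergence = 0.05, seed = NULL,
                                    name = "chrS") {
    if (length < 10000L) stop("genome length must be at least 10 kbp")
    if (repeatDensity >= 1) stop("repeatDensity must be < 1")
    .withSeed(seed, {
        p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
        bg <- paste(sample(names(p), length, replace = TRUE, prob = p),
                    collapse = "")
        placed <- IRanges::IRanges()
        fams <- character(0)
        if (repeatDensity > 0) {
            lib <- repeatLibrary()
            target <- repeatDensity * length
            widths <- nchar(lib)
            ## draw candidate placements in bulk, drop overlaps greedily in
            ## position order, keep the prefix reaching the target coverage
            nCand <- ceiling(1.8 * target / mean(widths))
            famIdx <- sample.int(length(lib), nCand, replace = TRUE)
            starts <- sapply(widths[famIdx], function(w)
                sample.int(max(1L, length - w), 1L))
            o <- order(starts)
            famIdx <- famIdx[o]; starts <- starts[o]
            keep <- logical(nCand)
            lastEnd <- 0
            for (i in seq_len(nCand)) {
                if (starts[i] > lastEnd) {
                    keep[i] <- TRUE
                    lastEnd <- starts[i] + widths[famIdx[i]] - 1L
                }
            }
            famIdx <- famIdx[keep]; starts <- starts[keep]
            cum <- cumsum(widths[famIdx])
            take <- seq_len(min(length(starts), sum(cum < target) + 1L))
            famIdx <- famIdx[take]; starts <- starts[take]
            copies <- vapply(famIdx, function(fi)
                .mutateSeq(lib[[fi]], divergence), character(1))
            ## rebuild the sequence in one pass: background gaps + copies
            ends <- starts + widths[famIdx] - 1L
            gapStart <- c(1L, ends + 1L)
            gapEnd <- c(starts - 1L, length)
            pieces <- character(2L * length(starts) + 1L)
            pieces[seq(1L, by = 2L, length.out = length(gapStart))] <-
                substring(bg, gapStart, gapEnd)
            pieces[seq(2L, by = 2L, length.out = length(copies))] <- copies
            bg <- paste(pieces, collapse = "")
            placed <- IRanges::IRanges(start = starts,
                                       width = widths[famIdx])
            fams <- names(lib)[famIdx]
        }
        genome <- Biostrings::DNAStringSet(bg)
        names(genome) <- name
        reps <- GenomicRanges::GRanges(rep(name, length(placed)), placed)
        S4Vectors::mcols(reps)$family <- fams
        S4Vectors::metadata(genome)$repeats <- reps
        genome
    })
}

#' Implant insertions from a donor genome into an acceptor genome
#'
#' Draws `n` donor segments with log-uniform sizes in `[sizeMin, sizeMax]`
#' and inserts them at uniform, non-overlapping acceptor positions (at least
#' `minGap` apart and `edgeMargin` from the ends). Truth coordinates are on
#' the original acceptor frame (0-based insertion points).
#'
#' @param acceptor,donor `DNAStringSet` genomes (first sequence used).
#' @param n number of insertions.
#' @param sizeMin,sizeMax insertion size range in bp.
#' @param seed integer seed; `NULL` uses the ambient RNG state.
#' @param minGap minimum distance between implant positions (bp).
#' @param edgeMargin keep-out zone at the acceptor ends (bp).
#' @return list with `genome` (mutated acceptor, `DNAStringSet`) and `truth`
#'   (data.frame: `chrom`, `pos` 0-based, `size`, `donorStart`, `donorEnd`
#'   0-based half-open, `seq`).
#' @export
implantInsertions <- function(acceptor, donor, n, sizeMin = 100L,
                              sizeMax = 100000L, seed = NULL, minGap = 2000L,
                              edgeMargin = 2000L) {
    accChar <- as.character(acceptor[[1]])
    donChar <- as.character(donor[[1]])
    accLen <- nchar(accChar)
    donLen <- nchar(donChar)
    if (n * sizeMax > 0.5 * accLen * 10)
        stop("total implant size is too large for the acceptor")
    .withSeed(seed, {
        sizes <- as.integer(round(exp(stats::runif(n, log(sizeMin),
                                                   log(sizeMax)))))
        sizes <- pmin(pmax(sizes, as.integer(sizeMin)),
                      as.integer(min(sizeMax, donLen)))
        ## uniform positions subject to pairwise spacing >= minGap: draw
        ## sorted uniforms in the gap-reduced interval and re-expand
        span <- (accLen - edgeMargin) - edgeMargin - (n - 1L) * minGap
        if (span <= n)
            stop("could not place ", n, " insertions at least ", minGap,
                 " bp apart in a ", accLen, " bp acceptor")
        u <- sort(sample.int(span, n))
        pos <- edgeMargin + u + (seq_len(n) - 1L) * minGap
        dstart <- vapply(sizes, function(s)
            sample.int(donLen - s + 1L, 1L), integer(1))
        seqs <- substring(donChar, dstart, dstart + sizes - 1L)
        ## interleave acceptor pieces and implants
        pieces <- character(2L * n + 1L)
        prev <- 0L
        for (i in seq_len(n)) {
            pieces[2L * i - 1L] <- substr(accChar, prev + 1L, pos[i])
            pieces[2L * i] <- seqs[i]
            prev <- pos[i]
        }
        pieces[2L * n + 1L] <- substr(accChar, prev + 1L, accLen)
        mutated <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
        names(mutated) <- names(acceptor)[1]
        ## breakpoint microhomology makes the insertion point ambiguous: the
        ## same mutated sequence arises from a run of equivalent (pos, seq)
        ## representations. Record the two canonical ends of that run; the
        ## right (left) discovery breakpoint lands on posLeft (posRight).
        posLeft <- pos; posRight <- pos
        for (i in seq_len(n)) {
            p <- pos[i]; s <- seqs[i]; L <- sizes[i]
            h <- 0L
            while (h < L && substr(s, L - h, L - h) ==
                   substr(accChar, p - h, p - h)) h <- h + 1L
            posLeft[i] <- p - h
            h <- 0L
            while (h < L && substr(s, h + 1L, h + 1L) ==
                   substr(accChar, p + h + 1L, p + h + 1L)) h <- h + 1L
            posRight[i] <- p + h
        }
        truth <- data.frame(chrom = names(acceptor)[1], pos = pos,
                            posLeft = posLeft, posRight = posRight,
                            size = sizes, donorStart = dstart - 1L,
                            donorEnd = dstart - 1L + sizes, seq = seqs,
                            stringsAsFactors = FALSE)
        list(genome = mutated, truth = truth)
    })
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are placed uniformly to the target coverage with insert sizes
#' drawn from a normal distribution, read 1 taken from the fragment start
#' (forward) and read 2 from the fragment end (reverse complement; FR
#' orientation). Substitution errors are injected at the given per-base rate.
#' Deterministic for a fixed `seed`; base qualities are constant `I`.
#'
#' @param genome `DNAStringSet` (first sequence used).
#' @param coverage target sequence coverage (x).
#' @param readLen read length (bp).
#' @param insertMean,insertSd outer insert length distribution (bp);
#'   `insertMean` must exceed `2 * readLen`.
#' @param err per-base substitution error rate.
#' @param seed integer seed; `NULL` uses the ambient RNG state.
#' @param fastq1,fastq2 output FASTQ paths.
#' @param prefix read-name prefix.
#' @return invisibly, c(fastq1, fastq2); attribute `nPairs`.
#' @export
simulatePers <- function(genome, coverage = 30, readLen = 100L,
                         insertMean = 350, insertSd = 50, err = 0.002,
                         seed = NULL, fastq1 = tempfile(fileext = "_1.fq"),
                         fastq2 = tempfile(fileext = "_2.fq"),
                         prefix = "sim") {
    if (insertMean <= 2 * readLen)
        stop("insertMean must exceed 2 * readLen")
    gChar <- as.character(genome[[1]])
    L <- nchar(gChar)
    nPairs <- round(coverage * L / (2 * readLen))
    .withSeed(seed, {
        ins <- round(stats::rnorm(nPairs, insertMean, insertSd))
        ins <- pmin(pmax(ins, 2L * readLen), L)
        start <- floor(stats::runif(nPairs) * (L - ins + 1)) + 1L
        r1 <- substring(gChar, start, start + readLen - 1L)
        r2 <- revComp(substring(gChar, start + ins - readLen, start + ins - 1L))
        total <- 2L * nPairs * readLen
        nerr <- stats::rbinom(1L, total, err)
        if (nerr > 0L) {
            idx <- sample.int(total, nerr)
            readIdx <- (idx - 1L) %/% readLen + 1L
            posIdx <- (idx - 1L) %% readLen + 1L
            shift <- sample.int(3L, nerr, replace = TRUE)
            both <- cpp_apply_subs(c(r1, r2), readIdx, posIdx, shift)
            r1 <- both[seq_len(nPairs)]
            r2 <- both[nPairs + seq_len(nPairs)]
        }
        nm <- sprintf("%s_%d", prefix, seq_len(nPairs))
        cpp_write_fastq(paste0(nm, "/1"), r1, fastq1)
        cpp_write_fastq(paste0(nm, "/2"), r2, fastq2)
    })
    out <- c(fastq1, fastq2)
    attr(out, "nPairs") <- nPairs
    invisible(out)
}

#' Score insertion calls against a simulated truth set
#'
#' A call matches a truth record when (i) its breakpoint gap is below
#' `eval_max_gap` (100 bp) and (ii) at least
#' `eval_min_align_frac` (50%) of the predicted inserted sequence aligns to
#' the implanted segment (each predicted part is aligned locally and its
#' matched bases summed). The gap is the smaller of the distances between the
#' call's left breakpoint and the right-normalized truth position, and the
#' call's right breakpoint and the left-normalized truth position
#' (`posRight`/`posLeft` columns when present, else `pos`): under breakpoint
#' microhomology the insertion point is a run of equivalent representations,
#' and the maximal-flank rule places each tag at the corresponding end of
#' that run. Matching is one-to-one, greedy by smallest gap.
#' Sensitivity is matched truth records over all truth records; FDR is
#' unmatched calls over all calls.
#'
#' @param calls data.frame with columns `chrom`, `leftBp`, `rightBp` (0-based)
#'   and `predLeft`, `predRight` (predicted inserted sequence parts; either
#'   may be an empty string, e.g. a fully traced call uses only `predLeft`).
#' @param truth truth data.frame from [implantInsertions()].
#' @param config a [svConfig()] object.
#' @return list with `sensitivity`, `fdr`, `breakpointGaps` (matched calls),
#'   `nTrue`, `nCalled`, `nMatched`.
#' @export
evaluateCalls <- function(calls, truth, config = svConfig()) {
    maxGap <- configValue(config, "eval_max_gap")
    minFrac <- configValue(config, "eval_min_align_frac")
    nTrue <- nrow(truth)
    nCalled <- nrow(calls)
    if (nCalled == 0L)
        return(list(sensitivity = 0, fdr = NA_real_,
                    breakpointGaps = integer(0), nTrue = nTrue, nCalled = 0L,
                    nMatched = 0L))
    ## under breakpoint microhomology the truth point is ambiguous; compare
    ## each reported breakpoint against the matching canonical truth frame
    ## (left tags shift right, right tags shift left)
    posL <- if ("posLeft" %in% colnames(truth)) truth$posLeft else truth$pos
    posR <- if ("posRight" %in% colnames(truth)) truth$posRight else truth$pos
    cand <- list()
    for (ci in seq_len(nCalled)) {
        ti <- which(truth$chrom == calls$chrom[ci])
        if (!length(ti)) next
        gap <- pmin(abs(calls$leftBp[ci] - posR[ti]),
                    abs(calls$rightBp[ci] - posL[ti]))
        ok <- gap < maxGap
        if (any(ok))
            cand[[length(cand) + 1L]] <- data.frame(
                call = ci, truthRow = ti[ok], gap = gap[ok])
    }
    matchedCalls <- integer(0)
    matchedTruth <- integer(0)
    gaps <- integer(0)
    if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(cand$gap, cand$call), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
            ci <- cand$call[i]; ti <- cand$truthRow[i]
            if (ci %in% matchedCalls || ti %in% matchedTruth) next
            pl <- calls$predLeft[ci]; pr <- calls$predRight[ci]
            totalLen <- nchar(pl) + nchar(pr)
            if (totalLen == 0L) next
            aligned <- 0
            if (nchar(pl) > 0L)
                aligned <- aligned + cpp_sw_affine(pl, truth$seq[ti])$matches
            if (nchar(pr) > 0L)
                aligned <- aligned + cpp_sw_affine(pr, truth$seq[ti])$matches
            if (aligned / totalLen < minFrac) next
            matchedCalls <- c(matchedCalls, ci)
            matchedTruth <- c(matchedTruth, ti)
            gaps <- c(gaps, cand$gap[i])
        }
    }
    list(sensitivity = length(matchedTruth) / nTrue,
         fdr = (nCalled - length(matchedCalls)) / nCalled,
         breakpointGaps = gaps, nTrue = nTrue, nCalled = nCalled,
         nMatched = length(matchedCalls))
}
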