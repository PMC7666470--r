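# Clustering, assembly, contig validation, breakpoint refinement, pairing.

# Minimal DiscordantPairs with given anchor positions/strands.
make_pers <- function(pos, strand = "+", chrom = "chrT", width = 100L) {
    n <- length(pos)
    gr <- GenomicRanges::GRanges(
        rep(chrom, length.out = n),
        IRanges::IRanges(start = pos, width = width),
        strand = rep(strand, length.out = n))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        qname = sprintf("r%d", seq_len(n)), mapq = rep(60L, n),
        cigar = rep("100M", n),
        anchorSeq = Biostrings::DNAStringSet(rep(strrep("A", width), n)),
        mateSeq = Biostrings::DNAStringSet(rep(strrep("C", width), n)),
        mateReverse = rep(FALSE, n),
        mateStatus = rep("unmapped", n))
    new("DiscordantPairs", gr)
}

test_that("clustering equals brute-force transitive closure and is order-invariant", {
    lib <- LibraryStats(200, 50, 100L)  # link distance 300
    cfg <- svConfig(min_support = 1L)

    cl <- clusterPers(make_pers(c(100L, 150L, 200L)), lib, cfg)
    expect_length(cl, 1L)
    expect_equal(cl$n, 3L)

    cl <- clusterPers(make_pers(c(100L, 5000L)), lib, cfg)
    expect_length(cl, 2L)

    # randomized positions vs brute-force single-linkage closure
    set.seed(7)
    for (rep in 1:5) {
        pos <- sort(sample.int(20000L, 50L))
        pers <- make_pers(pos)
        cl <- clusterPers(pers, lib, cfg)
        # oracle: transitive closure of the pairwise <= 300 relation in 1D
        breaks <- which(diff(pos) > 300)
        oracleSizes <- diff(c(0L, breaks, length(pos)))
        got <- sort(cl$n)
        expect_identical(sort(as.integer(oracleSizes)), as.integer(got))

        # input order must not matter
        perm <- sample(length(pers))
        cl2 <- clusterPers(pers[perm], lib, cfg)
        expect_identical(sort(cl2$n), sort(cl$n))
        expect_setequal(BiocGenerics::start(cl2), BiocGenerics::start(cl))
    }

    # min_support drops small clusters
    cl <- clusterPers(make_pers(c(100L, 150L, 5000L)), lib,
                      svConfig(min_support = 2L))
    expect_length(cl, 1L)
    expect_equal(cl$n, 2L)

    # empty input -> empty output
    expect_length(clusterPers(make_pers(integer(0)), lib, cfg), 0L)
})

test_that("De Bruijn assembly reconstructs a tiled sequence and drops outliers", {
    set.seed(11)
    truthSeq <- rand_dna(300)
    reads <- tiling_reads(truthSeq, 50L, step = 1L)
    # error-free reads: no coverage floor, so reconstruction is exact
    cfg <- svConfig(k = 21L, min_kmer_cov = 1L)
    asm <- assembleCluster(reads, cfg)
    expect_identical(asm$contigs, truthSeq)
    expect_equal(nrow(asm$placements), length(reads))

    # with the default coverage floor of 2, terminal k-mers (seen in a single
    # read) are trimmed by one base at each contig end
    asmCov <- assembleCluster(reads, svConfig(k = 21L))
    expect_identical(asmCov$contigs, substr(truthSeq, 2, nchar(truthSeq) - 1))

    # one unrelated read sharing no k-mer: disconnected singleton contig is
    # dropped by the min-placed-reads rule
    asm2 <- assembleCluster(c(reads, rand_dna(50)), cfg)
    expect_true(truthSeq %in% asm2$contigs)
    expect_length(asm2$contigs, 1L)

    # a repeated 25-mer: resolved by k=31, fragmented at k=21
    rep25 <- rand_dna(25)
    seqRep <- paste0(rand_dna(80), rep25, rand_dna(70), rep25, rand_dna(80))
    readsRep <- tiling_reads(seqRep, 60L, step = 1L)
    asm31 <- assembleCluster(readsRep, svConfig(k = 31L, min_kmer_cov = 1L))
    expect_identical(asm31$contigs[which.max(nchar(asm31$contigs))], seqRep)

    # disable the min-placed-reads contig filter: short inter-branch unitigs
    # legitimately lose all their reads to longer-overlap neighbours
    asm21 <- assembleCluster(readsRep, svConfig(k = 21L, min_kmer_cov = 1L,
                                                min_placed_reads = 0L))
    # oracle: an independent R implementation of unbranched-path extraction
    k <- 21L
    kmers <- unique(unlist(lapply(readsRep, function(r)
        substring(r, 1:(nchar(r) - k + 1), k:nchar(r)))))
    succ <- function(x) kmers[kmers %in% paste0(substr(x, 2, k),
                                                c("A", "C", "G", "T"))]
    pred <- function(x) kmers[kmers %in% paste0(c("A", "C", "G", "T"),
                                                substr(x, 1, k - 1))]
    starts <- kmers[vapply(kmers, function(x) {
        p <- pred(x)
        length(p) != 1 || length(succ(p)) > 1
    }, logical(1))]
    oracle <- vapply(starts, function(x) {
        path <- x
        repeat {
            s <- succ(path[length(path)])
            if (length(s) != 1 || length(pred(s)) != 1 || s %in% path) break
            path <- c(path, s)
        }
        paste0(path[1], paste(substring(path[-1], k, k), collapse = ""))
    }, character(1))
    expect_setequal(asm21$contigs, unname(oracle))
})

test_that("contig validation rejects placement chains with unsupported gaps", {
    ok <- validateContig("x", data.frame(read = 1:3,
                                         offset = c(0L, 40L, 80L),
                                         overlap = c(100L, 100L, 100L)), 100L)
    expect_true(ok)
    bad <- validateContig("x", data.frame(read = 1:2,
                                          offset = c(0L, 700L),
                                          overlap = c(100L, 100L)), 100L)
    expect_false(bad)
    expect_match(attr(bad, "reason"), "gap")
    none <- validateContig("x", data.frame(read = integer(0),
                                           offset = integer(0),
                                           overlap = integer(0)), 100L)
    expect_false(none)

    # randomized placement sets vs direct re-check of the chain condition
    set.seed(13)
    for (rep in 1:20) {
        off <- sort(sample.int(1000L, 8L))
        pl <- data.frame(read = 1:8, offset = off, overlap = 100L)
        got <- isTRUE(validateContig("x", pl, 100L))
        ends <- cummax(off + 100L)
        oracle <- all(off[-1] - ends[-8] <= 100L)
        expect_identical(got, oracle)
    }
})

test_that("breakpoint refinement finds the split maximizing the flank", {
    set.seed(17)
    ref <- rand_dna(3000)
    cfg <- svConfig()

    # left tag: ref[1001..1100] + novel insertion part whose first base
    # differs from ref[1101] (no breakpoint microhomology by construction)
    ins <- strrep("GATTACA", 5)
    stopifnot(substr(ins, 1, 1) != substr(ref, 1101, 1101))
    contig <- paste0(substr(ref, 1001, 1100), ins)
    tag <- refineBreakpoint(contig, ref, origin = 0L, side = "left_flank",
                            config = cfg)
    expect_s4_class(tag, "InsertionTags")
    expect_equal(BiocGenerics::start(tag) - 1L, 1100L)  # 0-based breakpoint
    expect_equal(as.character(tag$insPartSeq), ins)
    expect_equal(tag$side, "left_flank")

    # right tag: novel 40-mer + ref[2001..2120]; last insertion base chosen
    # to differ from ref[2000] (again no microhomology)
    ins2 <- rand_dna(40)
    substr(ins2, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                    substr(ref, 2000, 2000))[1]
    contig2 <- paste0(ins2, substr(ref, 2001, 2120))
    tag2 <- refineBreakpoint(contig2, ref, origin = 0L, side = "right_flank",
                             config = cfg)
    expect_equal(BiocGenerics::start(tag2) - 1L, 2000L)
    expect_equal(as.character(tag2$insPartSeq), ins2)

    # fully reference contig -> no insertion evidence
    expect_null(refineBreakpoint(substr(ref, 501, 800), ref, 0L,
                                 "left_flank", config = cfg))

    # two flank mismatches within tolerance: same breakpoint as clean case;
    # oracle = exhaustive scan over all split points maximizing matches
    flank <- substr(ref, 1001, 1200)
    substr(flank, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                     substr(flank, 50, 50))[1]
    substr(flank, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                       substr(flank, 120, 120))[1]
    contig3 <- paste0(flank, ins2)
    tag3 <- refineBreakpoint(contig3, ref, 0L, "left_flank", config = cfg)
    refChars <- strsplit(substr(ref, 1001, 1000 + nchar(contig3)), "")[[1]]
    ctgChars <- strsplit(contig3, "")[[1]]
    sc <- cumsum(ifelse(ctgChars == refChars[seq_along(ctgChars)], 1, -4))
    oracleSplit <- which.max(sc)
    expect_equal(BiocGenerics::start(tag3) - 1L, 1000L + oracleSplit)
    expect_equal(tag3$flankMismatches, 2L)
})

test_that("flank of every tag realigns to the reference at its breakpoint", {
    set.seed(19)
    ref <- rand_dna(5000)
    for (rep in 1:10) {
        at <- sample(1500:3500, 1)
        ins <- rand_dna(sample(60:400, 1))
        contig <- paste0(substr(ref, at - 149, at), ins)
        tag <- refineBreakpoint(contig, ref, 0L, "left_flank")
        if (is.null(tag)) next
        bp <- BiocGenerics::start(tag) - 1L
        fl <- as.character(tag$flankSeq)
        refFl <- substr(ref, bp - nchar(fl) + 1L, bp)
        mm <- sum(strsplit(fl, "")[[1]] != strsplit(refFl, "")[[1]])
        expect_lte(mm / nchar(fl), 0.02)
    }
})

test_that("tag pairing equals exhaustive minimum-gap matching", {
    lib <- LibraryStats(350, 75, 100L)  # window 500
    mk_tags <- function(bp, side) {
        gr <- GenomicRanges::GRanges(
            "chrT", IRanges::IRanges(start = bp + 1L, width = 0L))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            side = side,
            flankSeq = Biostrings::DNAStringSet(rep("ACGT", length(bp))),
            insPartSeq = Biostrings::DNAStringSet(rep("TTTT", length(bp))),
            cluster = seq_along(bp), nReads = rep(5L, length(bp)),
            flankMismatches = rep(0L, length(bp)))
        new("InsertionTags", gr)
    }
    t1 <- suppressWarnings(c(mk_tags(1100L, "left_flank"),
                             mk_tags(1105L, "right_flank")))
    expect_length(pairInsertionTags(t1, lib), 1L)
    t2 <- suppressWarnings(c(mk_tags(1100L, "left_flank"),
                             mk_tags(9000L, "right_flank")))
    expect_length(pairInsertionTags(t2, lib), 0L)

    # 20 random tags: compare to brute-force greedy matching oracle
    set.seed(23)
    for (rep in 1:5) {
        lb <- sort(sample.int(10000L, 10L))
        rb <- sort(sample.int(10000L, 10L))
        tags <- suppressWarnings(c(mk_tags(lb, "left_flank"),
                                   mk_tags(rb, "right_flank")))
        got <- pairInsertionTags(tags, lib)
        # oracle: enumerate eligible pairs, sort by |gap|, take greedily
        el <- expand.grid(l = seq_along(lb), r = seq_along(rb))
        el$gap <- rb[el$r] - lb[el$l]
        el <- el[el$gap >= -100 & el$gap <= 500, ]
        el <- el[order(abs(el$gap), lb[el$l], rb[el$r]), ]
        ul <- ur <- integer(0); n <- 0L
        pairsOracle <- list()
        for (i in seq_len(nrow(el))) {
            if (el$l[i] %in% ul || el$r[i] %in% ur) next
            ul <- c(ul, el$l[i]); ur <- c(ur, el$r[i])
            pairsOracle[[length(pairsOracle) + 1L]] <-
                c(lb[el$l[i]], rb[el$r[i]])
        }
        expect_equal(length(got), length(pairsOracle))
        if (length(got)) {
            gotMat <- cbind(got$leftBp, got$rightBp)
            oraMat <- do.call(rbind, pairsOracle)
            expect_setequal(paste(gotMat[, 1], gotMat[, 2]),
                            paste(oraMat[, 1], oraMat[, 2]))
        }
    }
})
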