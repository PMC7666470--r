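# Mechanism classification: VNTR, NAHR, TE, NH cascade.

test_that("breakpoint context extraction is exact and flags truncation", {
    g <- Biostrings::DNAStringSet(strrep("ACGT", 500))
    names(g) <- "chrT"
    ctx <- extractBreakpointContext("chrT", 1000L, g, w = 100L)
    expect_identical(nchar(ctx$left), 100L)
    expect_identical(nchar(ctx$right), 100L)
    expect_false(ctx$truncated)
    # concatenation reconstructs the local reference
    expect_identical(paste0(ctx$left, ctx$right),
                     as.character(Biostrings::subseq(g[[1]], 901, 1100)))

    ctx2 <- extractBreakpointContext("chrT", 50L, g, w = 100L)
    expect_identical(nchar(ctx2$left), 50L)
    expect_true(ctx2$truncated)
})

test_that("VNTR detection finds the tandem period and requires a flank motif", {
    set.seed(141)
    motif <- "ACGTT"
    ins <- strrep(motif, 40)
    flanksWith <- list(left = paste0(rand_dna(90), motif), right = rand_dna(100))
    flanksWithout <- list(left = rand_dna(100), right = rand_dna(100))

    v <- detectVntr(ins, flanksWith)
    expect_false(is.null(v))
    expect_identical(v$period, 5L)
    expect_identical(v$copies, 40)

    # no motif at the insertion-site flank: not a local tandem expansion
    expect_null(detectVntr(ins, flanksWithout))
    # random sequence has no period
    expect_null(detectVntr(rand_dna(400), flanksWith))

    # mutated tandem: the detection decision must match a brute-force scan
    # over all periods computing maximal tandem coverage
    insMut <- ins
    nmut <- 20L
    # keep the leading motif intact so the flank-motif condition is unchanged
    pos <- sample(6:nchar(ins), nmut)
    for (p in pos) {
        substr(insMut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(insMut, p, p)), 1)
    }
    cov_oracle <- function(s, p) {
        x <- strsplit(s, "")[[1]]
        (sum(x[-seq_len(p)] == x[seq_len(length(x) - p)]) + p) / length(x)
    }
    motif_in_flank <- function(motif, flank) {
        # brute-force scan over every offset, counting mismatches
        p <- nchar(motif); fn <- nchar(flank)
        if (fn < p) return(FALSE)
        m <- strsplit(motif, "")[[1]]
        any(vapply(0:(fn - p), function(o) {
            sum(strsplit(substr(flank, o + 1, o + p), "")[[1]] != m) <=
                floor(0.1 * p)
        }, logical(1)))
    }
    n <- nchar(insMut)
    covs <- vapply(1:(n %/% 2), function(p) cov_oracle(insMut, p), numeric(1))
    flankSeq <- paste0(flanksWith$left, flanksWith$right)
    okP <- which(covs >= 0.85)
    okP <- okP[okP >= 2]
    okP <- okP[vapply(okP, function(p)
        motif_in_flank(substr(insMut, 1, p), flankSeq), logical(1))]
    v2 <- detectVntr(insMut, flanksWith)
    if (length(okP)) {
        expect_false(is.null(v2))
        expect_identical(v2$period, min(okP))
        expect_identical(v2$coverage, covs[v2$period])
    } else expect_null(v2)
})

test_that("NAHR detection reports homologous flank blocks", {
    set.seed(143)
    block <- rand_dna(80)
    left <- paste0(rand_dna(20), block)
    right <- paste0(block, rand_dna(20))
    h <- detectNahr(left, right)
    expect_false(is.null(h))
    expect_gte(h$homologyLength, 80L)
    expect_gte(h$identity, 0.99)

    expect_null(detectNahr(rand_dna(100), rand_dna(100)))

    # 85%-identity block of 60 bp: below the 90% identity bar; the decision
    # must agree with an independent Biostrings local alignment
    b2 <- block
    mutAt <- sample.int(60, 9)
    for (p in mutAt)
        substr(b2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(b2, p, p)), 1)
    l2 <- paste0(rand_dna(40), substr(b2, 1, 60))
    r2 <- paste0(substr(block, 1, 60), rand_dna(40))
    got <- detectNahr(l2, r2)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(l2), Biostrings::DNAString(r2), type = "local",
        substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
    oracleLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    oracleId <- Biostrings::nmatch(aln) / oracleLen
    expect_identical(is.null(got), oracleLen < 50 || oracleId < 0.9)
})

test_that("TE fraction uses the interval union and the strict 80% rule", {
    ann <- data.frame(start = c(11L, 281L), end = c(290L, 300L),
                      family = "aluSyn")
    te <- classifyTe(300L, ann)
    expect_false(is.null(te))
    expect_equal(te$fraction, 290 / 300)
    expect_identical(te$family, "aluSyn")

    expect_null(classifyTe(300L, data.frame(start = 1L, end = 150L,
                                            family = "aluSyn")))
    # fraction exactly 0.80 is NOT "more than 80%"
    expect_null(classifyTe(300L, data.frame(start = 1L, end = 240L,
                                            family = "aluSyn")))
    expect_null(classifyTe(300L, NULL))

    # invariance under interval splitting; equality with per-base counting
    set.seed(145)
    for (rep in 1:10) {
        iv <- sort(sample.int(500L, 8L))
        ann1 <- data.frame(start = iv[c(1, 3, 5, 7)], end = iv[c(2, 4, 6, 8)],
                           family = "lineSyn")
        # split every interval at its midpoint
        mid <- with(ann1, pmax(start, floor((start + end) / 2)))
        ann2 <- rbind(data.frame(start = ann1$start, end = mid,
                                 family = "lineSyn"),
                      data.frame(start = pmin(mid + 1L, ann1$end),
                                 end = ann1$end, family = "lineSyn"))
        f1 <- classifyTe(500L, ann1, config = svConfig(te_fraction = 0))
        f2 <- classifyTe(500L, ann2, config = svConfig(te_fraction = 0))
        covered <- logical(500L)
        for (i in seq_len(nrow(ann1)))
            covered[ann1$start[i]:ann1$end[i]] <- TRUE
        expect_equal(f1$fraction, sum(covered) / 500)
        expect_equal(f2$fraction, f1$fraction)
    }
})

test_that("the cascade applies VNTR > NAHR > TE > NH priority", {
    set.seed(147)
    motif <- "ACGTT"
    flanks <- list(left = paste0(rand_dna(90), motif), right = rand_dna(100))

    # tandem insertion that is ALSO fully TE-annotated: VNTR wins by priority
    ins <- strrep(motif, 60)
    ann <- data.frame(start = 1L, end = nchar(ins), family = "svaSyn")
    cl <- classifyMechanism(ins, flanks, ann)
    expect_identical(cl$mech, "VNTR")

    # homologous flanks, non-tandem insertion: NAHR
    block <- rand_dna(70)
    flanksH <- list(left = paste0(rand_dna(30), block),
                    right = paste0(block, rand_dna(30)))
    expect_identical(classifyMechanism(rand_dna(300), flanksH, NULL)$mech,
                     "NAHR")

    # >80% TE-annotated, no tandem or homology: TE
    insTE <- rand_dna(300)
    annTE <- data.frame(start = 1L, end = 290L, family = "aluSyn")
    expect_identical(
        classifyMechanism(insTE, list(left = rand_dna(100),
                                      right = rand_dna(100)), annTE)$mech,
        "TE")

    # no recognizable features: NH
    expect_identical(
        classifyMechanism(rand_dna(300), list(left = rand_dna(100),
                                              right = rand_dna(100)),
                          NULL)$mech, "NH")

    # random constructed panel: cascade equals independent detector order
    for (rep in 1:10) {
        insR <- rand_dna(sample(200:500, 1))
        fl <- list(left = rand_dna(100), right = rand_dna(100))
        annR <- if (runif(1) < 0.5)
            data.frame(start = 1L, end = round(nchar(insR) * runif(1)),
                       family = "aluSyn") else NULL
        got <- classifyMechanism(insR, fl, annR)$mech
        want <- if (!is.null(detectVntr(insR, fl))) "VNTR"
            else if (!is.null(detectNahr(fl$left, fl$right))) "NAHR"
            else if (!is.null(classifyTe(nchar(insR), annR))) "TE"
            else "NH"
        expect_identical(got, want)
    }
})

test_that("the toy k-mer annotator recovers repeat intervals on insertions", {
    lib <- repeatLibrary()
    ins <- paste0(lib[["aluSyn"]], strrep("A", 30), lib[["aluSyn"]])
    ann <- annotateRepeats(ins)
    expect_true(all(ann$family == "aluSyn"))
    te <- classifyTe(nchar(ins), ann)
    expect_false(is.null(te))
    expect_gt(te$fraction, 0.85)
})
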