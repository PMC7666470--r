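# Syntenic localization, full-sequence tracing, concordance, ancestral state.

test_that("syntenic localization recovers the implant interval", {
    set.seed(101)
    acc <- generateSyntheticGenome(5e4, repeatDensity = 0, seed = 101,
                                   name = "chrA")
    don <- generateSyntheticGenome(2e4, repeatDensity = 0, seed = 102,
                                   name = "chrD")
    imp <- implantInsertions(acc, don, n = 1, sizeMin = 700, sizeMax = 700,
                             seed = 103)
    t <- imp$truth
    tgt <- targetGenome("carrier", imp$genome, "human_assembly")

    loc <- locateSyntenicRegion("chrA", t$pos, t$pos, acc, tgt)
    expect_false(is.null(loc))
    expect_identical(loc$insEnd - loc$insStart, t$size)
    expect_identical(substr(as.character(imp$genome[[1]]),
                            loc$insStart + 1L, loc$insEnd), t$seq)

    # a target lacking the locus entirely
    other <- generateSyntheticGenome(3e4, repeatDensity = 0, seed = 104,
                                     name = "chrX")
    expect_null(locateSyntenicRegion("chrA", t$pos, t$pos, acc,
                                     targetGenome("alien", other,
                                                  "human_assembly")))

    # locus present on the reverse strand of the target
    rcTarget <- Biostrings::DNAStringSet(
        Biostrings::reverseComplement(imp$genome[[1]]))
    names(rcTarget) <- "chrRC"
    locRC <- locateSyntenicRegion("chrA", t$pos, t$pos, acc,
                                  targetGenome("rc", rcTarget,
                                               "human_assembly"))
    expect_false(is.null(locRC))
    expect_identical(locRC$strand, "-")
    expect_identical(locRC$insEnd - locRC$insStart, t$size)
})

test_that("diverged target flanks still localize the interval closely", {
    set.seed(107)
    acc <- generateSyntheticGenome(5e4, repeatDensity = 0, seed = 107,
                                   name = "chrA")
    don <- generateSyntheticGenome(2e4, repeatDensity = 0, seed = 108,
                                   name = "chrD")
    imp <- implantInsertions(acc, don, n = 1, sizeMin = 2000, sizeMax = 2000,
                             seed = 109)
    t <- imp$truth
    # substitute ~1% of target bases (substitution-only divergence)
    tchar <- as.character(imp$genome[[1]])
    nmut <- round(0.01 * nchar(tchar))
    pos <- sample.int(nchar(tchar), nmut)
    shift <- sample.int(3L, nmut, replace = TRUE)
    tdiv <- as.character(InsertionTracer:::cpp_apply_subs(
        tchar, rep(1L, nmut), pos, shift))
    tgt <- targetGenome("diverged",
                        {x <- Biostrings::DNAStringSet(tdiv)
                         names(x) <- "chrA"; x},
                        "nonhuman_primate")
    loc <- locateSyntenicRegion("chrA", t$pos, t$pos, acc, tgt)
    expect_false(is.null(loc))
    expect_lte(abs((loc$insEnd - loc$insStart) - t$size), 5L)
})

test_that("tracing recovers the exact insertion and applies the identity threshold", {
    set.seed(111)
    acc <- generateSyntheticGenome(5e4, repeatDensity = 0, seed = 111,
                                   name = "chrA")
    don <- generateSyntheticGenome(2e4, repeatDensity = 0, seed = 112,
                                   name = "chrD")
    imp <- implantInsertions(acc, don, n = 1, sizeMin = 900, sizeMax = 900,
                             seed = 113)
    t <- imp$truth
    tgt <- targetGenome("carrier", imp$genome, "nonhuman_primate")

    tr <- traceInsertion("chrA", t$pos, t$pos,
                         substr(t$seq, 1, 150),
                         substr(t$seq, t$size - 149, t$size),
                         acc, list(tgt))
    expect_identical(tr$insSeq, t$seq)
    expect_identical(tr$ancestralState, "retention_of_ancestral")

    # partial inserted sequences unrelated to the carrier: below the identity
    # threshold, the candidate is rejected and the event stays untraced
    tr2 <- traceInsertion("chrA", t$pos, t$pos,
                          rand_dna(150), rand_dna(150), acc, list(tgt))
    expect_identical(tr2$ancestralState, "untraced")
    expect_identical(tr2$insSeq, "")
})

test_that("round-trip tracing is exact across sizes (canonical form)", {
    # property: implant, trace against the carrier, compare canonical
    # left-normalized representations
    set.seed(115)
    acc <- generateSyntheticGenome(2e5, repeatDensity = 0, seed = 115,
                                   name = "chrA")
    don <- generateSyntheticGenome(1e5, repeatDensity = 0, seed = 116,
                                   name = "chrD")
    imp <- implantInsertions(acc, don, n = 12, sizeMin = 60, sizeMax = 10000,
                             seed = 117)
    pairs <- pairs_from_truth(imp$truth)
    tgt <- targetGenome("carrier", imp$genome, "nonhuman_primate")
    ctl <- traceCatalog(pairs, acc, list(tgt))
    expect_identical(length(ctl), nrow(imp$truth))
    m <- S4Vectors::mcols(ctl)
    truthNorm <- lapply(seq_len(nrow(imp$truth)), function(i)
        normalizeInsertion(imp$truth$pos[i], imp$truth$seq[i], acc[["chrA"]]))
    expect_setequal(as.character(m$insSeq),
                    vapply(truthNorm, `[[`, character(1), "seq"))
    expect_setequal(BiocGenerics::start(ctl),
                    vapply(truthNorm, `[[`, integer(1), "pos"))
    expect_true(all(m$ancestralState == "retention_of_ancestral"))
})

test_that("concordance detects outliers and picks a deterministic consensus", {
    set.seed(119)
    base <- rand_dna(500)
    snv <- base
    substr(snv, 250, 250) <- setdiff(c("A", "C", "G", "T"),
                                     substr(base, 250, 250))[1]

    cc <- checkConcordance(c(g1 = base, g2 = base, g3 = base))
    expect_true(cc$concordant)

    cc2 <- checkConcordance(c(g1 = base, g2 = snv))
    expect_true(cc2$concordant)  # 1 SNV in 500 bp >> 90% identity

    # unrelated random sequences: expected identity ~ 25-50% after alignment
    cc3 <- checkConcordance(c(g1 = rand_dna(500), g2 = rand_dna(500)))
    expect_false(cc3$concordant)

    # an outlier flags discordance, the consensus is still reported
    mut <- paste0(substr(base, 1, 200), rand_dna(300))
    cc4 <- checkConcordance(c(g1 = base, g2 = base, g9 = mut))
    expect_false(cc4$concordant)
    expect_identical(cc4$consensus, "g1")  # tie with g2 broken by name

    # oracle: pairwise identity from an independent hand-rolled NW aligner
    # on substitution-diverged sequences (no gaps, so scoring schemes agree)
    a <- rand_dna(120)
    b <- a
    for (p in sample.int(120, 12))
        substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(b, p, p)), 1)
    cc5 <- checkConcordance(c(x = a, y = b))
    expect_equal(cc5$identities[1, 2], nw_matches(a, b) / 120,
                 tolerance = 0.02)
})

test_that("ancestral-state classification is exhaustively correct", {
    classes <- c("nonhuman_primate", "human_assembly", "unmapped_contig_db")
    # all 8 subsets of the three target classes
    for (mask in 0:7) {
        present <- classes[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
        got <- classifyAncestralState(present)
        want <- if ("nonhuman_primate" %in% present) "retention_of_ancestral"
                else if (length(present)) "novel_insertion" else "untraced"
        expect_identical(got, want)
    }
})
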