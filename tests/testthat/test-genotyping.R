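# Dual-allele construction, read assignment, read-depth-ratio genotypes.

test_that("allele construction concatenates flanks and insertion", {
    ref <- Biostrings::DNAStringSet("AAAATTTT")
    names(ref) <- "chrT"
    al <- buildAlleles("chrT", 4L, "GG", ref, flankExtension = 4L)
    expect_identical(al$refAllele, "AAAATTTT")
    expect_identical(al$insAllele, "AAAAGGTTTT")
    expect_identical(al$bpOffset, 4L)

    expect_error(buildAlleles("chrT", 4L, "", ref, flankExtension = 4L),
                 "non-empty")

    # near a contig end: skipped with NULL
    expect_null(buildAlleles("chrT", 1L, "GG", ref, flankExtension = 4L))

    # length arithmetic holds for random variants
    set.seed(121)
    g <- Biostrings::DNAStringSet(rand_dna(20000))
    names(g) <- "chrT"
    for (i in 1:20) {
        pos <- sample(2000:18000, 1)
        ins <- rand_dna(sample(100:800, 1))
        al <- buildAlleles("chrT", pos, ins, g, readLen = 100L)
        expect_identical(nchar(al$insAllele),
                         nchar(al$refAllele) + nchar(ins))
    }
})

test_that("read assignment matches a Smith-Waterman oracle on simulated reads", {
    set.seed(123)
    g <- Biostrings::DNAStringSet(rand_dna(5000))
    names(g) <- "chrT"
    ins <- rand_dna(400)
    al <- buildAlleles("chrT", 2500L, ins, g, readLen = 100L)

    # junction-crossing read supports alt; flank-only read is ambiguous
    junctionRead <- substr(al$insAllele, al$bpOffset - 49L, al$bpOffset + 50L)
    flankRead <- substr(al$refAllele, 1L, 100L)
    a <- assignReads(c(junctionRead, flankRead), al)
    expect_identical(as.character(a), c("alt", "ambiguous"))

    # 600 error-bearing reads from a known diploid vs a Biostrings
    # local-alignment oracle on the score comparison
    reads <- c(hap_reads(al$refAllele, 40), hap_reads(al$insAllele, 40))
    calls <- assignReads(reads, al)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4)
    oracle <- vapply(reads, function(r) {
        sc <- function(allele) {
            max(Biostrings::score(Biostrings::pairwiseAlignment(
                    Biostrings::DNAString(r), Biostrings::DNAString(allele),
                    type = "local", substitutionMatrix = mat,
                    gapOpening = 6, gapExtension = 1)),
                Biostrings::score(Biostrings::pairwiseAlignment(
                    Biostrings::reverseComplement(Biostrings::DNAString(r)),
                    Biostrings::DNAString(allele),
                    type = "local", substitutionMatrix = mat,
                    gapOpening = 6, gapExtension = 1)))
        }
        d <- sc(al$insAllele) - sc(al$refAllele)
        if (d >= 5) "alt" else if (d <= -5) "ref" else "ambiguous"
    }, character(1))
    determined <- calls != "ambiguous"
    agree <- as.character(calls)[determined] == oracle[determined]
    expect_gte(mean(agree), 0.99)
})

test_that("ratio thresholds and depth floor drive the genotype", {
    g <- callGenotype(c(20L, 10L, 1L, 0L), c(0L, 10L, 1L, 30L))
    expect_identical(g$gt, c("0/0", "0/1", "./.", "1/1"))
    expect_identical(g$dosage, c(0L, 1L, NA_integer_, 2L))

    # monotonicity: raising nAlt at fixed nRef never moves toward 0/0
    ord <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
    for (nRef in c(0L, 3L, 10L)) {
        gts <- callGenotype(rep(nRef, 61L), 0:60)$gt
        lv <- ord[gts]
        lv[is.na(lv)] <- -1  # ./. only at the low-depth start
        expect_true(all(diff(lv) >= 0))
    }

    # symmetry: swapping the counts swaps 0/0 and 1/1
    set.seed(127)
    nr <- sample(0:30, 50, replace = TRUE)
    na <- sample(0:30, 50, replace = TRUE)
    g1 <- callGenotype(nr, na)$gt
    g2 <- callGenotype(na, nr)$gt
    swap <- c("0/0" = "1/1", "1/1" = "0/0", "0/1" = "0/1", "./." = "./.")
    expect_identical(unname(swap[g1]), g2)
})

test_that("simulated diploids are genotyped concordantly and AF is recovered", {
    set.seed(129)
    g <- Biostrings::DNAStringSet(rand_dna(100000))
    names(g) <- "chrT"
    afGrid <- seq(0.1, 0.9, by = 0.2)
    nVar <- 20L; nSamp <- 12L
    err <- 0
    concord <- 0L; total <- 0L
    afHat <- numeric(nVar); afTrue <- numeric(nVar)
    for (v in seq_len(nVar)) {
        pos <- 2000L + v * 4000L
        ins <- rand_dna(sample(150:500, 1))
        al <- buildAlleles("chrT", pos, ins, g, readLen = 100L)
        af <- afGrid[(v - 1L) %% length(afGrid) + 1L]
        dosages <- stats::rbinom(nSamp, 2L, af)
        called <- integer(nSamp)
        for (s in seq_len(nSamp)) {
            haps <- c(al$refAllele, al$insAllele)[
                c(rep(1L, 2L - dosages[s]), rep(2L, dosages[s]))]
            reads <- unlist(lapply(haps, hap_reads, coverage = 15,
                                   err = 0.002))
            gt <- genotypeFromReads(reads, al)
            called[s] <- gt$dosage
            if (!is.na(gt$dosage)) {
                total <- total + 1L
                concord <- concord + (gt$dosage == dosages[s])
            }
        }
        afHat[v] <- mean(called, na.rm = TRUE) / 2
        afTrue[v] <- mean(dosages) / 2   # realized panel frequency
    }
    expect_gte(concord / total, 0.95)
    # AF recovered within binomial sampling error of the realized frequency
    se <- sqrt(afTrue * (1 - afTrue) / (2 * nSamp)) + 1e-9
    expect_gte(mean(abs(afHat - afTrue) <= 3 * se + 0.02), 0.95)
})

test_that("low coverage yields undetermined genotypes", {
    set.seed(131)
    g <- Biostrings::DNAStringSet(rand_dna(20000))
    names(g) <- "chrT"
    al <- buildAlleles("chrT", 10000L, rand_dna(300), g, readLen = 100L)
    undet <- 0L
    for (rep in 1:60) {
        # ~2x total coverage: one haploid coverage unit per haplotype
        reads <- c(hap_reads(al$refAllele, 1), hap_reads(al$insAllele, 1))
        gt <- genotypeFromReads(reads, al)
        undet <- undet + (gt$gt == "./.")
    }
    expect_gte(undet / 60, 0.4)
})

test_that("genotyping a catalogue from a BAM applies the size filter", {
    set.seed(133)
    genome <- rand_dna(30000)
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "chrT"
    ins <- rand_dna(400)
    pos0 <- 15000L

    # homozygous-alt sample: reads from the insertion haplotype around the
    # breakpoint; plus background proper pairs for library stats
    hap <- paste0(substr(genome, 1, pos0), ins,
                  substr(genome, pos0 + 1, nchar(genome)))
    lines <- unlist(lapply(1:200, function(i)
        proper_pair(paste0("bg", i), "chrT", 10L + i * 60L, 350L, 100L,
                    genome)))
    # insertion-supporting pairs: anchored flank read + unmapped mate from
    # inside/around the insertion on the alternate haplotype
    for (i in 1:25) {
        aStart <- pos0 - 250L + i * 7L
        mStart <- pos0 - 60L + i * 9L
        lines <- c(lines,
                   anchored_unmapped_pair(paste0("insL", i), "chrT", aStart,
                                          100L, genome,
                                          substr(hap, mStart + 160L,
                                                 mStart + 259L)))
    }
    bam <- sam_to_bam(lines, c(chrT = nchar(genome)))

    mk_catalog <- function(pos, seq) {
        gr <- GenomicRanges::GRanges("chrT",
                                     IRanges::IRanges(pos, width = 1L))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            variantId = sprintf("I_%d", seq_along(pos)),
            insSeq = Biostrings::DNAStringSet(seq),
            svlen = nchar(seq), leftBp = pos, rightBp = pos,
            traceSources = IRanges::CharacterList(
                rep(list("t:chr:0-1:1.0"), length(pos))),
            concordant = rep(TRUE, length(pos)),
            ancestralState = rep("retention_of_ancestral", length(pos)))
        new("InsertionCatalog", gr)
    }
    catalog <- mk_catalog(c(pos0, 5000L), c(ins, rand_dna(80)))
    res <- genotypeSample(catalog, bam, g, sampleId = "s1")
    expect_identical(nrow(res), 2L)
    # the 80 bp variant is below the size filter (reads cannot span it
    # unambiguously), mirroring the restriction to variants > read length
    expect_match(res$skipped[2], "svlen")
    expect_identical(res$gt[2], "./.")
    expect_false(is.na(res$nAlt[1]))
    expect_gt(res$nAlt[1], 0)
})
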