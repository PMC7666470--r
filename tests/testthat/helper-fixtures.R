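# Fixture builders shared across tests. All data is generated in code; the
# only external tools used are samtools/bwa (on PATH), needed for BAM
# fixtures and the mapping-based integration tests.

rand_dna <- function(n, gc = 0.5) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Write SAM text records to a BAM file (sorted + indexed).
sam_to_bam <- function(samLines, seqLengths,
                       dir = tempfile(pattern = "samfix")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths), seqLengths))
    sam <- file.path(dir, "records.sam")
    writeLines(c(hdr, samLines), sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, "records"),
                            overwrite = TRUE, indexDestination = TRUE)
    bam
}

# One SAM line; pos/mpos are 1-based, 0 for unmapped-style placeholders.
sam_line <- function(qname, flag, rname, pos, mapq, cigar, mrnm, mpos, tlen,
                     seq) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            qname, flag, rname, pos, mapq, cigar, mrnm, mpos, tlen, seq,
            strrep("I", nchar(seq)))
}

# A proper FR pair: read1 forward at pos, read2 reverse so that the outer
# insert is `insert`. Returns two SAM lines.
proper_pair <- function(qname, rname, pos, insert, readLen, genome) {
    r1 <- substr(genome, pos, pos + readLen - 1)
    p2 <- pos + insert - readLen
    r2 <- substr(genome, p2, p2 + readLen - 1)
    c(sam_line(qname, 99L, rname, pos, 60L, paste0(readLen, "M"), "=", p2,
               insert, r1),
      sam_line(qname, 147L, rname, p2, 60L, paste0(readLen, "M"), "=", pos,
               -insert, r2))
}

# Anchored read (forward) + unmapped mate placed at the anchor.
anchored_unmapped_pair <- function(qname, rname, pos, readLen, genome,
                                   mateSeq, mapq = 60L) {
    r1 <- substr(genome, pos, pos + readLen - 1)
    c(sam_line(qname, 105L, rname, pos, mapq, paste0(readLen, "M"), "=", pos,
               0L, r1),       # paired, mate unmapped, mate "reverse"
      sam_line(qname, 181L, rname, pos, 0L, "*", "=", pos, 0L, mateSeq))
}

# Error-free reads tiling seq[from..to] at the given step (1-based, forward).
tiling_reads <- function(seq, readLen, step = 1L, from = 1L,
                         to = nchar(seq) - readLen + 1L) {
    starts <- seq.int(from, to, by = step)
    substring(seq, starts, starts + readLen - 1L)
}

# Truth-derived paired insertion tags (partials of length partLen).
pairs_from_truth <- function(truth, partLen = 150L) {
    n <- nrow(truth)
    lparts <- substr(truth$seq, 1L, pmin(partLen, truth$size))
    rparts <- substr(truth$seq, pmax(1L, truth$size - partLen + 1L),
                     truth$size)
    gr <- GenomicRanges::GRanges(
        truth$chrom, IRanges::IRanges(start = truth$pos + 1L,
                                      end = truth$pos))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        leftBp = truth$pos, rightBp = truth$pos, gap = 0L,
        leftInsPart = Biostrings::DNAStringSet(lparts),
        rightInsPart = Biostrings::DNAStringSet(rparts),
        leftCluster = seq_len(n), rightCluster = seq_len(n) + n,
        nReads = rep(10L, n))
    new("PairedInsertionTags", gr)
}

# Independent Needleman-Wunsch global aligner (match +1, mismatch/gap -1),
# returning the number of matched bases -- a small oracle, deliberately
# separate from both Biostrings and the package's own aligners.
nw_matches <- function(a, b) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    S <- matrix(0, n + 1, m + 1)
    M <- matrix(0L, n + 1, m + 1)
    S[, 1] <- -(0:n); S[1, ] <- -(0:m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        dg <- S[i, j] + ifelse(a[i] == b[j], 1, -1)
        up <- S[i, j + 1] - 1
        lf <- S[i + 1, j] - 1
        best <- max(dg, up, lf)
        S[i + 1, j + 1] <- best
        M[i + 1, j + 1] <- if (best == dg) M[i, j] + (a[i] == b[j])
                           else if (best == up) M[i, j + 1] else M[i + 1, j]
    }
    M[n + 1, m + 1]
}

# Simulate substitution-error reads from a haplotype (both orientations).
hap_reads <- function(hap, coverage, readLen = 100L, err = 0.002) {
    n <- max(0L, round(coverage * nchar(hap) / readLen))
    if (n == 0L) return(character(0))
    s <- sample.int(max(1L, nchar(hap) - readLen + 1L), n, replace = TRUE)
    r <- substring(hap, s, s + readLen - 1L)
    nerr <- stats::rbinom(1L, sum(nchar(r)), err)
    if (nerr > 0L) {
        idx <- sample.int(sum(nchar(r)), nerr)
        ri <- (idx - 1L) %/% readLen + 1L
        pos <- (idx - 1L) %% readLen + 1L
        for (k in seq_len(nerr)) {
            base <- substr(r[ri[k]], pos[k], pos[k])
            alt <- setdiff(c("A", "C", "G", "T"), base)
            substr(r[ri[k]], pos[k], pos[k]) <- sample(alt, 1L)
        }
    }
    flip <- stats::runif(n) < 0.5
    r[flip] <- revComp(r[flip])
    r
}
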