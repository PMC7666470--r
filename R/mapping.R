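## Thin adapter around a standard short-read aligner (bwa) and samtools, used
## by the simulation benchmark. The caller itself only needs BAM input; any
## aligner producing sorted indexed BAM can be substituted.

.checkTool <- function(tool) {
    path <- Sys.which(tool)
    if (!nzchar(path))
        stop("required external tool not found on PATH: ", tool)
    path
}

#' Write sequences to FASTA and build aligner indexes
#'
#' @param sequences `DNAStringSet`.
#' @param fasta output FASTA path.
#' @return `fasta`, invisibly.
#' @export
writeReferenceFasta <- function(sequences, fasta) {
    Biostrings::writeXStringSet(sequences, fasta)
    .checkTool("samtools")
    system2("samtools", c("faidx", shQuote(fasta)))
    invisible(fasta)
}

#' Map paired-end reads with bwa and produce a sorted, indexed BAM
#'
#' @param fasta reference FASTA (indexed on first use).
#' @param fastq1,fastq2 paired FASTQ files.
#' @param outBam output BAM path.
#' @param threads bwa threads.
#' @return `outBam`, invisibly.
#' @export
mapReads <- function(fasta, fastq1, fastq2, outBam, threads = 1L) {
    .checkTool("bwa")
    .checkTool("samtools")
    if (!file.exists(paste0(fasta, ".bwt"))) {
        status <- system2("bwa", c("index", shQuote(fasta)),
                          stdout = FALSE, stderr = FALSE)
        if (status != 0L) stop("bwa index failed for ", fasta)
    }
    cmd <- sprintf("bwa mem -t %d %s %s %s 2>/dev/null | samtools sort -o %s - 2>/dev/null",
                   as.integer(threads), shQuote(fasta), shQuote(fastq1),
                   shQuote(fastq2), shQuote(outBam))
    status <- system(cmd)
    if (status != 0L) stop("bwa mem | samtools sort failed")
    status <- system2("samtools", c("index", shQuote(outBam)))
    if (status != 0L) stop("samtools index failed for ", outBam)
    invisible(outBam)
}
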