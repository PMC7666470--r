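## internal helpers

.log <- function(fmt, ...) {
    message(sprintf(paste0("[InsertionTracer] ", fmt), ...))
}

## evaluate `code` under a temporary RNG seed, restoring global RNG state
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## coerce to a single plain character string of DNA
.dnaChar <- function(x) {
    if (is(x, "DNAString") || is(x, "DNAStringSet"))
        return(as.character(x)[[1]])
    as.character(x)[[1]]
}

## fetch one chromosome (DNAString) from a DNAStringSet by name
.chromSeq <- function(ref, chrom) {
    if (is(ref, "DNAString")) return(ref)
    if (!chrom %in% names(ref))
        stop("sequence '", chrom, "' not found in the reference")
    ref[[chrom]]
}

## 0-based half-open substring of a DNAString-like, clipped to bounds
.sub0 <- function(seq, start0, end0) {
    n <- length(seq)
    s <- max(0L, as.integer(start0))
    e <- min(n, as.integer(end0))
    if (e <= s) return(Biostrings::DNAString(""))
    Biostrings::subseq(seq, start = s + 1L, end = e)
}

#' Left-normalize an insertion representation
#'
#' An insertion of sequence `seq` at 0-based point `pos` (between `ref[pos-1]`
#' and `ref[pos]`, 0-based) is ambiguous when the inserted sequence shares
#' bases with the reference around the point (breakpoint microhomology): the
#' same mutated sequence has several `(pos, seq)` representations. This shifts
#' the representation to the smallest possible `pos`, rotating `seq`
#' accordingly -- the same canonical form VCF uses for indels -- so that
#' call/truth and multi-genome comparisons are exact.
#'
#' @param pos integer(1), 0-based insertion point on `ref`.
#' @param seq inserted sequence (character or `DNAString`).
#' @param ref the reference sequence (`DNAString` or character).
#' @return list with canonical `pos` and `seq` (character).
#' @export
normalizeInsertion <- function(pos, seq, ref) {
    refc <- .dnaChar(ref)
    s <- .dnaChar(seq)
    pos <- as.integer(pos)
    n <- nchar(s)
    if (n == 0L) return(list(pos = pos, seq = s))
    while (pos > 0L && substr(s, n, n) == substr(refc, pos, pos)) {
        s <- paste0(substr(refc, pos, pos), substr(s, 1L, n - 1L))
        pos <- pos - 1L
    }
    list(pos = pos, seq = s)
}

#' Reverse-complement character sequences
#'
#' Thin vectorized wrapper used throughout the package; `N` and other
#' ambiguity codes map to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revComp <- function(x) as.character(cpp_revcomp(as.character(x)))
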