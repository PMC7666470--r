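## Mutational-mechanism classification from breakpoint sequence features:
## VNTR -> NAHR -> TE -> NH priority cascade.

#' Extract breakpoint flanking context
#'
#' Returns `w` bp of reference sequence on each side of the insertion point
#' (truncated and flagged near contig ends).
#'
#' @param chrom,pos0 site: chromosome and 0-based insertion point.
#' @param reference reference genome (`DNAStringSet`).
#' @param w flank width in bp (default 100).
#' @return list with `left`, `right` (character) and `truncated` (logical).
#' @export
extractBreakpointContext <- function(chrom, pos0, reference, w = 100L) {
    refSeq <- .chromSeq(reference, chrom)
    left <- as.character(.sub0(refSeq, pos0 - w, pos0))
    right <- as.character(.sub0(refSeq, pos0, pos0 + w))
    list(left = left, right = right,
         truncated = nchar(left) < w || nchar(right) < w)
}

#' Detect a variable-number tandem repeat insertion
#'
#' Scans all periods `p` in `[vntr_min_period, len/2]` for tandemness: the
#' fraction of positions consistent with period `p` must reach
#' `vntr_coverage`, and the motif (the first `p` bases) must also occur at the
#' insertion-site flank (within 10% mismatches), the signature of an expanded
#' local tandem array. The smallest qualifying period is reported.
#'
#' @param insSeq inserted sequence (character).
#' @param flanks list with `left`/`right` flank sequences (see
#'   [extractBreakpointContext()]).
#' @param config a [svConfig()] object.
#' @return `NULL`, or list with `period`, `copies`, `coverage`, `motif`.
#' @export
detectVntr <- function(insSeq, flanks, config = svConfig()) {
    insSeq <- .dnaChar(insSeq)
    n <- nchar(insSeq)
    pmin <- configValue(config, "vntr_min_period")
    pmax <- n %/% 2L
    if (pmax < pmin) return(NULL)
    cov <- cpp_tandem_scan(insSeq, pmax)
    thr <- configValue(config, "vntr_coverage")
    ok <- which(cov >= thr)
    ok <- ok[ok >= pmin]
    if (!length(ok)) return(NULL)
    for (p in ok) {
        motif <- substr(insSeq, 1L, p)
        flankSeq <- paste0(flanks$left, flanks$right)
        if (nchar(flankSeq) < p) next
        hit <- Biostrings::matchPattern(
            Biostrings::DNAString(motif), Biostrings::DNAString(flankSeq),
            max.mismatch = floor(0.1 * p))
        if (length(hit) > 0L)
            return(list(period = p, copies = round(n / p),
                        coverage = cov[[p]], motif = motif))
    }
    NULL
}

#' Detect non-allelic homologous recombination signature
#'
#' Reports the best local alignment between the two breakpoint-adjacent
#' flanks; an NAHR call requires a homologous block of at least
#' `nahr_min_homology` bp at `nahr_identity` identity or better.
#'
#' @param leftFlank,rightFlank flank sequences (character).
#' @param config a [svConfig()] object.
#' @return `NULL`, or list with `homologyLength` and `identity`.
#' @export
detectNahr <- function(leftFlank, rightFlank, config = svConfig()) {
    if (nchar(leftFlank) == 0L || nchar(rightFlank) == 0L) return(NULL)
    sw <- cpp_sw_affine(.dnaChar(leftFlank), .dnaChar(rightFlank))
    if (sw$length < configValue(config, "nahr_min_homology")) return(NULL)
    identity <- sw$matches / sw$length
    if (identity < configValue(config, "nahr_identity")) return(NULL)
    list(homologyLength = sw$length, identity = identity)
}

#' Classify a transposable-element insertion from a repeat annotation
#'
#' The repeat-masked fraction is the union of the annotated intervals divided
#' by the insertion length; a TE call requires strictly more than
#' `te_fraction` (default 0.80) of the sequence to be retroelement-derived.
#' The family is the class covering the most bases.
#'
#' @param insLen insertion length (bp).
#' @param annotation repeat intervals on the inserted sequence: a data.frame
#'   with 1-based `start`, `end`, `family` columns, or a `GRanges` with a
#'   `family` metadata column. `NULL`/empty means no annotation (no TE call).
#' @param config a [svConfig()] object.
#' @return `NULL`, or list with `fraction` and `family`.
#' @export
classifyTe <- function(insLen, annotation, config = svConfig()) {
    if (is.null(annotation)) return(NULL)
    if (is(annotation, "GRanges")) {
        ir <- IRanges::ranges(annotation)
        fam <- S4Vectors::mcols(annotation)$family
    } else {
        if (nrow(annotation) == 0L) return(NULL)
        ir <- IRanges::IRanges(start = annotation$start, end = annotation$end)
        fam <- annotation$family
    }
    if (length(ir) == 0L) return(NULL)
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(insLen))
    fraction <- sum(IRanges::width(IRanges::reduce(ir))) / insLen
    if (fraction <= configValue(config, "te_fraction")) return(NULL)
    byFam <- vapply(split(ir, fam), function(x)
        sum(IRanges::width(IRanges::reduce(x))), numeric(1))
    list(fraction = fraction, family = names(byFam)[which.max(byFam)])
}

#' Classify the mutational mechanism of one insertion variant
#'
#' Fixed priority cascade: VNTR, then NAHR, then TE, then NH (no recognizable
#' feature). Exactly one mechanism is assigned; the first positive detector
#' wins even when later ones would also fire.
#'
#' @param insSeq inserted sequence (character).
#' @param flanks list with `left`/`right` breakpoint flanks.
#' @param annotation repeat annotation on the inserted sequence (see
#'   [classifyTe()]), or `NULL`.
#' @param config a [svConfig()] object.
#' @return list with `mech` (`"VNTR"`, `"NAHR"`, `"TE"`, `"NH"`) and
#'   `evidence` (character description).
#' @export
classifyMechanism <- function(insSeq, flanks, annotation = NULL,
                              config = svConfig()) {
    v <- detectVntr(insSeq, flanks, config = config)
    if (!is.null(v))
        return(list(mech = "VNTR",
                    evidence = sprintf("period=%d,copies=%d,coverage=%.2f",
                                       v$period, v$copies, v$coverage)))
    h <- detectNahr(flanks$left, flanks$right, config = config)
    if (!is.null(h))
        return(list(mech = "NAHR",
                    evidence = sprintf("homology=%dbp,identity=%.2f",
                                       h$homologyLength, h$identity)))
    te <- classifyTe(nchar(.dnaChar(insSeq)), annotation, config = config)
    if (!is.null(te))
        return(list(mech = "TE",
                    evidence = sprintf("fraction=%.3f,family=%s",
                                       te$fraction, te$family)))
    list(mech = "NH", evidence = "none")
}

#' Annotate repeats on inserted sequences with the built-in toy library
#'
#' A lightweight stand-in for a full repeat annotator, intended for tests and
#' simulated data: intervals of the inserted sequence sharing exact k-mers
#' with an element of the library (see [repeatLibrary()]) are collected per
#' family, merged when closer than `mergeGap`, and returned as annotation
#' intervals. Diverged copies are detected through their conserved k-mer
#' stretches. For real data, supply RepeatMasker-style intervals instead.
#'
#' @param insSeq inserted sequence (character).
#' @param library named character vector / `DNAStringSet` of repeat consensus
#'   sequences; default [repeatLibrary()].
#' @param k seed k-mer length.
#' @param mergeGap merge hits separated by at most this many bp.
#' @return data.frame with `start`, `end`, `family` (1-based, closed), or an
#'   empty data.frame.
#' @export
annotateRepeats <- function(insSeq, library = repeatLibrary(), k = 21L,
                            mergeGap = 40L) {
    insSeq <- .dnaChar(insSeq)
    out <- list()
    libChar <- setNames(as.character(library), names(library))
    for (fam in names(libChar)) {
        hits <- cpp_kmer_hits(libChar[[fam]], insSeq, k = k, max_per = 1000L)
        if (nrow(hits) == 0L) next
        ir <- IRanges::reduce(IRanges::IRanges(start = hits$tpos + 1L,
                                               width = k),
                              min.gapwidth = mergeGap)
        out[[fam]] <- data.frame(start = IRanges::start(ir),
                                 end = IRanges::end(ir), family = fam)
    }
    if (!length(out))
        return(data.frame(start = integer(0), end = integer(0),
                          family = character(0)))
    do.call(rbind, unname(out))
}

#' Add mechanism calls to an insertion catalogue
#'
#' @param catalog an [InsertionCatalog].
#' @param reference reference genome (`DNAStringSet`).
#' @param annotations optional named list (by `variantId`) of repeat
#'   annotations; when `NULL` the toy k-mer annotator ([annotateRepeats()])
#'   is used.
#' @param config a [svConfig()] object (uses `mech_flank`).
#' @return the catalogue with `mech` and `mechEvidence` metadata columns.
#' @export
classifyCatalogMechanisms <- function(catalog, reference, annotations = NULL,
                                      config = svConfig()) {
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    w <- configValue(config, "mech_flank")
    m <- S4Vectors::mcols(catalog)
    mech <- character(length(catalog))
    ev <- character(length(catalog))
    for (i in seq_along(catalog)) {
        chrom <- as.character(GenomicRanges::seqnames(catalog))[i]
        pos0 <- BiocGenerics::start(catalog)[i]
        ctx <- extractBreakpointContext(chrom, pos0, reference, w = w)
        ins <- as.character(m$insSeq[i])
        ann <- if (!is.null(annotations)) annotations[[m$variantId[i]]]
               else annotateRepeats(ins)
        cl <- classifyMechanism(ins, ctx, ann, config = config)
        mech[i] <- cl$mech
        ev[i] <- cl$evidence
    }
    S4Vectors::mcols(catalog)$mech <- mech
    S4Vectors::mcols(catalog)$mechEvidence <- ev
    catalog
}
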