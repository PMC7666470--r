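## Population summaries over genotyped insertion variants: allele frequencies,
## per-individual inserted-sequence load, Nei pairwise F_ST.

.dosageOf <- function(gm) {
    if (is(gm, "InsertionGenotypes"))
        SummarizedExperiment::assay(gm, "dosage")
    else as.matrix(gm)
}

.popsOf <- function(gm, populations) {
    if (is(gm, "InsertionGenotypes"))
        as.character(SummarizedExperiment::colData(gm)$population)
    else as.character(populations)
}

#' Allele frequencies of insertion variants
#'
#' AF per variant is the alt-dosage sum over twice the number of non-missing
#' samples; with `byGroup = TRUE` a variants x populations matrix is returned.
#' All-missing variants get `NA` (with a warning).
#'
#' @param gm an [InsertionGenotypes] or a dosage matrix (variants x samples,
#'   values 0/1/2/NA).
#' @param byGroup compute per-population frequencies.
#' @param populations population label per sample (ignored for
#'   `InsertionGenotypes`).
#' @return numeric vector, or matrix when `byGroup`.
#' @export
alleleFrequencies <- function(gm, byGroup = FALSE, populations = NULL) {
    d <- .dosageOf(gm)
    af1 <- function(mat) {
        nm <- rowSums(!is.na(mat))
        af <- rowSums(mat, na.rm = TRUE) / (2 * nm)
        af[nm == 0] <- NA_real_
        af
    }
    if (!byGroup) {
        af <- af1(d)
        if (anyNA(af)) warning(sum(is.na(af)), " variant(s) with no called ",
                               "genotype: AF undefined")
        return(af)
    }
    pops <- .popsOf(gm, populations)
    stopifnot(length(pops) == ncol(d))
    groups <- sort(unique(pops))
    out <- vapply(groups, function(g) af1(d[, pops == g, drop = FALSE]),
                  numeric(nrow(d)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(d),
                                         dimnames = list(rownames(d), groups))
    out
}

#' Per-individual non-reference sequence load
#'
#' For each sample, the number of variants carried (dosage >= 1) and the total
#' inserted sequence in bp. The default presence-based mode counts each
#' carried variant's full length once; `mode = "dosage"` weights by dosage
#' (half for heterozygotes, on the diploid scale).
#'
#' @param gm an [InsertionGenotypes] or dosage matrix.
#' @param svlen variant lengths in bp (ignored for `InsertionGenotypes`).
#' @param mode `"presence"` (default) or `"dosage"`.
#' @return data.frame with `sample`, `nVariants`, `loadBp`.
#' @export
perIndividualLoad <- function(gm, svlen = NULL, mode = c("presence", "dosage")) {
    mode <- match.arg(mode)
    d <- .dosageOf(gm)
    if (is(gm, "InsertionGenotypes"))
        svlen <- SummarizedExperiment::rowData(gm)$svlen
    stopifnot(length(svlen) == nrow(d))
    carried <- !is.na(d) & d >= 1L
    nVar <- colSums(carried)
    load <- if (mode == "presence") colSums(carried * svlen)
            else colSums(ifelse(is.na(d), 0, d) / 2 * svlen)
    data.frame(sample = colnames(d) %||% as.character(seq_len(ncol(d))),
               nVariants = unname(nVar), loadBp = unname(load))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nei F_ST for two allele frequencies
#'
#' Closed form `(H_T - H_S) / H_T` with `H_S = (2 p1 (1-p1) + 2 p2 (1-p2))/2`
#' and `H_T = 2 p (1-p)` at the unweighted mean frequency
#' `p = (p1 + p2)/2`. Monomorphic pooled frequencies give 0.
#'
#' @param p1,p2 allele frequencies in the two groups (vectors recycle).
#' @return numeric vector of F_ST values in `[0, 1]`.
#' @export
neiFst <- function(p1, p2) {
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
    pmin(pmax(fst, 0), 1)
}

#' Pairwise Nei F_ST of one population against all others
#'
#' Per variant, the focal group's allele frequency is compared to the pooled
#' remainder's. Variants where either side has fewer than two non-missing
#' samples get `NA`.
#'
#' @param gm an [InsertionGenotypes] or dosage matrix.
#' @param group focal population label.
#' @param populations population labels (ignored for `InsertionGenotypes`).
#' @return numeric vector of per-variant F_ST.
#' @export
pairwiseFst <- function(gm, group, populations = NULL) {
    d <- .dosageOf(gm)
    pops <- .popsOf(gm, populations)
    stopifnot(length(pops) == ncol(d))
    if (!group %in% pops)
        stop("population '", group, "' not present in the sample labels")
    inG <- pops == group
    dG <- d[, inG, drop = FALSE]
    dR <- d[, !inG, drop = FALSE]
    nG <- rowSums(!is.na(dG))
    nR <- rowSums(!is.na(dR))
    pG <- rowSums(dG, na.rm = TRUE) / (2 * nG)
    pR <- rowSums(dR, na.rm = TRUE) / (2 * nR)
    fst <- neiFst(pG, pR)
    fst[nG < 2 | nR < 2] <- NA_real_
    fst
}

#' Top-k F_ST report per population group
#'
#' @param fstTable matrix or data.frame of per-variant F_ST values, one column
#'   per group; row names (or a `variantId` column) identify variants.
#' @param k number of top hits per group (default 10).
#' @return data.frame with `group`, `variantId`, `fst`, `rank`, sorted by
#'   descending F_ST within group; ties broken by variant id.
#' @export
topFstReport <- function(fstTable, k = 10L) {
    if (is.data.frame(fstTable) && "variantId" %in% colnames(fstTable)) {
        ids <- fstTable$variantId
        fstTable <- as.matrix(fstTable[, setdiff(colnames(fstTable),
                                                 "variantId"), drop = FALSE])
        rownames(fstTable) <- ids
    } else fstTable <- as.matrix(fstTable)
    ids <- rownames(fstTable) %||% as.character(seq_len(nrow(fstTable)))
    out <- lapply(colnames(fstTable), function(g) {
        v <- fstTable[, g]
        o <- order(-v, ids, na.last = TRUE)
        o <- o[!is.na(v[o])]
        o <- utils::head(o, k)
        if (!length(o)) return(NULL)
        data.frame(group = g, variantId = ids[o], fst = v[o],
                   rank = seq_along(o))
    })
    do.call(rbind, out)
}
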