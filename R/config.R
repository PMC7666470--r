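#' Pipeline configuration
#'
#' All tunables of the caller with their defaults and a provenance flag
#' (`"default"` vs `"user"`) per value. Every stage takes a config object so a
#' run is reproducible from the serialized configuration plus the inputs and
#' seed.
#'
#' @slot values named list of parameter values.
#' @slot provenance named character vector, `"default"` or `"user"`.
#' @export
setClass("SvPipelineConfig",
    representation(values = "list", provenance = "character"))

.CONFIG_DEFAULTS <- list(
    ## alignment selection
    min_mapq = 20L,              # minimum anchor MAPQ
    insert_sd_discordant = 3,    # |insert| > mean + k*sd counts as discordant
    lib_sample_size = Inf,       # max proper pairs used for library stats
    min_proper_pairs = 100L,     # hard error below this
    ## clustering / pairing
    min_support = 3L,            # min discordant pairs per cluster
    cluster_sd_window = 2,       # link distance = mean + k*sd
    pair_sd_window = 2,          # pairing window = mean + k*sd
    max_microhomology = 100L,    # allowed negative right-left breakpoint gap
    ## assembly
    k = 31L,                     # De Bruijn k-mer size
    k_fallback = c(25L, 21L),    # retry ladder when no tag emerges at k
    min_kmer_cov = 2L,           # k-mer coverage floor
    max_contig_len = 100000L,
    placement_mm_frac = 0.05,    # read placement mismatch tolerance
    min_placed_reads = 2L,       # contigs with fewer placed reads are dropped
    ## breakpoint refinement
    min_flank = 30L,             # minimum flank length (bp)
    min_ins_part = 10L,          # minimum partial-insertion length (bp)
    flank_mm_tol = 0.02,         # flank mismatch tolerance
    refine_seed_k = 21L,         # seeding k-mer for contig anchoring
    refine_band = 16L,           # band half-width of the split aligner
    ## tracing
    trace_flank_len = 500L,      # reference flank used to locate synteny
    trace_seed_k = 31L,
    trace_seed_step = 25L,
    trace_identity = 0.90,       # min identity of ins parts on the candidate
    unique_ratio = 1.2,          # best/second-best score ratio for uniqueness
    concord_identity = 0.90,     # pairwise identity for concordance
    max_trace_size = 100000L,    # largest traceable insertion (bp)
    ## genotyping
    flank_extension_extra = 50L, # allele flank = read_length + this
    min_overlap = 10L,           # breakpoint overlap needed to count a read
    score_margin = 5,            # score difference for unambiguous assignment
    assign_k = 21L,
    t_low = 0.2,                 # alt ratio <= t_low -> 0/0
    t_high = 0.8,                # alt ratio >= t_high -> 1/1
    min_depth = 4L,              # informative reads below this -> ./.
    min_genotype_size = 100L,    # also must exceed the read length
    ## mechanism
    mech_flank = 100L,
    vntr_coverage = 0.85,
    vntr_min_period = 2L,
    nahr_min_homology = 50L,
    nahr_identity = 0.90,
    te_fraction = 0.80,
    ## evaluation
    eval_max_gap = 100L,
    eval_min_align_frac = 0.5
)

#' @describeIn SvPipelineConfig create a configuration; any default can be
#'   overridden by name, e.g. `svConfig(min_mapq = 30)`. Unknown names are an
#'   error.
#' @param ... named overrides of the defaults.
#' @export
svConfig <- function(...) {
    over <- list(...)
    if (length(over) && (is.null(names(over)) || any(names(over) == "")))
        stop("all config overrides must be named")
    unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
    if (length(unknown))
        stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
    values <- .CONFIG_DEFAULTS
    prov <- setNames(rep("default", length(values)), names(values))
    for (nm in names(over)) {
        values[[nm]] <- over[[nm]]
        prov[[nm]] <- "user"
    }
    new("SvPipelineConfig", values = values, provenance = prov)
}

#' @describeIn SvPipelineConfig fetch one parameter value.
#' @param x a `SvPipelineConfig`.
#' @param name parameter name.
#' @export
configValue <- function(x, name) {
    stopifnot(is(x, "SvPipelineConfig"))
    if (!name %in% names(x@values)) stop("unknown config parameter: ", name)
    x@values[[name]]
}

setMethod("show", "SvPipelineConfig", function(object) {
    cat("SvPipelineConfig:\n")
    user <- names(object@provenance)[object@provenance == "user"]
    for (nm in names(object@values)) {
        cat(sprintf("  %-24s %-10s %s\n", nm,
                    paste(format(object@values[[nm]]), collapse = ","),
                    if (nm %in% user) "[user]" else ""))
    }
})

#' Serialize a configuration to a key=value text file (and back)
#'
#' @param config a `SvPipelineConfig`.
#' @param file path of the text file.
#' @return `writeConfig` returns `file` invisibly; `readConfig` a
#'   `SvPipelineConfig`.
#' @export
writeConfig <- function(config, file) {
    vals <- config@values
    lines <- vapply(names(vals), function(nm)
        sprintf("%s = %s", nm, paste(format(vals[[nm]], digits = 15),
                                     collapse = ",")),
        character(1))
    writeLines(lines, file)
    invisible(file)
}

#' @rdname writeConfig
#' @export
readConfig <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    over <- list()
    for (p in kv) {
        nm <- trimws(p[[1]])
        val <- trimws(paste(p[-1], collapse = "="))
        def <- .CONFIG_DEFAULTS[[nm]]
        if (is.null(def)) stop("unknown config parameter in file: ", nm)
        parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
        over[[nm]] <- if (is.integer(def)) as.integer(parts)
                      else as.numeric(parts)
    }
    do.call(svConfig, over)
}
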