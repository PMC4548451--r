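#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `dosageArray()` returns the lines x loci x founders array, `lociTable()`
#' the locus map, `lineIds()` the line identifiers, `founderNames()` the
#' ordered founder strains (reference first), `strainLabels()` the per-sample
#' strain factor of a [FounderPanel-class], `exprValues()` its log2 assay,
#' `lodCurve()` a scan's LOD vector, `supportInterval()` its LOD-drop
#' interval, `hubTable()` a hub analysis summary table and `nullScores()`
#' its Monte Carlo null draws.
#'
#' @param x an object of the documented class.
#' @return see the individual descriptions above.
#' @name accessors
#' @aliases dosageArray lociTable lineIds founderNames strainLabels
#'   exprValues lodCurve supportInterval hubTable nullScores
NULL

#' @rdname accessors
#' @export
setGeneric("dosageArray", function(x) standardGeneric("dosageArray"))
#' @rdname accessors
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))
#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setGeneric("founderNames", function(x) standardGeneric("founderNames"))
#' @rdname accessors
#' @export
setGeneric("strainLabels", function(x) standardGeneric("strainLabels"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("lodCurve", function(x) standardGeneric("lodCurve"))
#' @rdname accessors
#' @export
setGeneric("supportInterval", function(x) standardGeneric("supportInterval"))
#' @rdname accessors
#' @export
setGeneric("hubTable", function(x) standardGeneric("hubTable"))
#' @rdname accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @rdname accessors
setMethod("dosageArray", "HaplotypeDosage", function(x) x@dosages)
#' @rdname accessors
setMethod("lociTable", "HaplotypeDosage", function(x) x@loci)
#' @rdname accessors
setMethod("lineIds", "HaplotypeDosage", function(x) x@lines)
#' @rdname accessors
setMethod("founderNames", "HaplotypeDosage", function(x) x@founders)
#' @rdname accessors
setMethod("strainLabels", "FounderPanel", function(x)
    SummarizedExperiment::colData(x)$strain)
#' @rdname accessors
setMethod("exprValues", "FounderPanel", function(x)
    SummarizedExperiment::assay(x, "exprs"))
#' @rdname accessors
setMethod("lodCurve", "ScanResult", function(x) x@lod)
#' @rdname accessors
setMethod("supportInterval", "ScanResult", function(x) x@support)
#' @rdname accessors
setMethod("hubTable", "HubResult", function(x) x@table)
#' @rdname accessors
setMethod("nullScores", "HubResult", function(x) x@nullScores)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nLines, "lines,",
        nrow(object@chromosomes), "chromosomes,",
        sum(object@chromosomes$n_markers), "markers,",
        length(object@plantedEqtl), "planted eQTL, seed", object@seed, "\n")
})

setMethod("show", "HaplotypeDosage", function(object) {
    cat("HaplotypeDosage:", length(object@lines), "lines x",
        nrow(object@loci), "loci x", length(object@founders), "founders\n")
    cat("  chromosomes:",
        paste(unique(object@loci$chrom), collapse = ", "), "\n")
})

setMethod("show", "QtlFit", function(object) {
    cat("QtlFit: n =", object@n,
        sprintf(" R2 = %.3f  RSS = %.3g\n", object@r2, object@rss))
    print(round(object@effects, 3))
    if (length(object@aliased))
        cat("  aliased:", paste(object@aliased, collapse = ", "), "\n")
})

setMethod("show", "ScanResult", function(object) {
    pk <- object@loci[object@peakIndex, ]
    cat("ScanResult for", object@mirna, "\n")
    cat(sprintf("  peak LOD %.2f at %s:%d", max(object@lod, na.rm = TRUE),
                pk$chrom, as.integer(pk$pos)))
    if (!is.na(object@adjP))
        cat(sprintf("  (adjusted p = %.4g)", object@adjP))
    cat("\n")
    if (nrow(object@support) == 1L)
        cat(sprintf("  support interval %s:%d-%d\n", object@support$chrom,
                    as.integer(object@support$start),
                    as.integer(object@support$end)))
    if (!is.na(object@classification[1L]))
        cat("  classification:", object@classification, "\n")
})

setMethod("show", "PermutationThresholds", function(object) {
    cat("PermutationThresholds:", object@nPerm, "permutations\n")
    cat("  observed max LOD", sprintf("%.2f", object@observedMax),
        " adjusted p", sprintf("%.4g", object@adjP), "\n")
    cat("  thresholds:", paste(sprintf("alpha %s -> %.2f",
        names(object@thresholds), object@thresholds), collapse = "; "), "\n")
})

setMethod("show", "HubResult", function(object) {
    cat("HubResult:", nrow(object@table), "miRNAs scored on",
        length(object@geneList), "genes,", object@nNull, "null lists\n")
    print(utils::head(object@table[order(object@table$p), ], 5L))
})
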