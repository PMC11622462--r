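#' @include AllClasses.R
NULL

#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))

#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' Extract the counts matrix of a FeatureTable
#'
#' @param x a [FeatureTable].
#' @return numeric matrix, features as rows, samples as columns.
#' @aliases featureCounts,FeatureTable-method
#' @export
setMethod("featureCounts", "FeatureTable", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Normalization state of a FeatureTable
#'
#' @param x a [FeatureTable].
#' @return `"raw"`, `"gcn"` or `"gcn_genome"`.
#' @aliases normalization,FeatureTable-method
#' @export
setMethod("normalization", "FeatureTable", function(x) x@normalization)

#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' Per-sample read frequencies (column sums)
#'
#' @param x a [FeatureTable].
#' @return named numeric vector of per-sample totals.
#' @aliases sampleTotals,FeatureTable-method
#' @export
setMethod("sampleTotals", "FeatureTable", function(x)
    colSums(featureCounts(x)))

setMethod("show", "MockDesign", function(object) {
    cat(sprintf("MockDesign '%s' (%s, mode %s): %d members\n",
                object@name, object@habitat, object@mode,
                length(object@members)))
    diluted <- names(object@dilution)[object@dilution != 0]
    if (length(diluted))
        cat("  diluted:", paste(sprintf("%s (10^%g)", diluted,
            object@dilution[diluted]), collapse = ", "), "\n")
    if (length(object@belowDetection))
        cat("  below detection limit (", object@detectionLimit, " log10):",
            paste(object@belowDetection, collapse = ", "), "\n", sep = "")
})

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable: %d features x %d samples [%s]\n",
                nrow(object), ncol(object), object@normalization))
    callNextMethod()
})

setMethod("show", "BiasReport", function(object) {
    cat(sprintf("BiasReport: %d sample/species rows, %d samples\n",
                nrow(object@perSpecies), nrow(object@perSample)))
    if (length(object@regression))
        cat(sprintf("  GC regression: slope %.4f, R^2 %.3f, p %.4g (n = %d)\n",
                    object@regression$slope, object@regression$r_squared,
                    object@regression$p_value, object@regression$n))
    if (nrow(object@groupTests))
        cat(sprintf("  %d group contrasts (Kruskal-Wallis, BH-corrected)\n",
                    nrow(object@groupTests)))
})

#' Accessors for BiasReport components
#'
#' @param x a [BiasReport].
#' @return `biasPerSpecies`: DataFrame of per-sample, per-species preset and
#'   observed abundances with log2 fold changes. `biasPerSample`: per-sample
#'   mean absolute log2 fold change. `biasRegression`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
biasPerSpecies <- function(x) x@perSpecies

#' @rdname biasPerSpecies
#' @export
biasPerSample <- function(x) x@perSample

#' @rdname biasPerSpecies
#' @export
biasRegression <- function(x) x@regression
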