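#' Accessors for isodrift classes
#'
#' \code{dosages} returns the variants-by-samples ALT-dosage matrix;
#' \code{variantInfo} the per-variant annotation as a data.frame;
#' \code{populationOf} the population label of every sample;
#' \code{haplotypes} the phased haplotype matrices (or NULL);
#' \code{altCounts}, \code{calledChroms}, \code{alleleFreqs} and
#' \code{derivedFreqs} the matching [FrequencyTable-class] matrices.
#'
#' @param x a GenotypeExperiment or FrequencyTable.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("populationOf", function(x) standardGeneric("populationOf"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname accessors
#' @export
setGeneric("calledChroms", function(x) standardGeneric("calledChroms"))

#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname accessors
#' @export
setGeneric("derivedFreqs", function(x) standardGeneric("derivedFreqs"))

#' @rdname accessors
#' @export
setGeneric("isolateLabel", function(x) standardGeneric("isolateLabel"))

#' @rdname accessors
#' @export
setGeneric("generalLabel", function(x) standardGeneric("generalLabel"))

#' @rdname accessors
#' @export
setGeneric("measures", function(x) standardGeneric("measures"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeExperiment",
          function(x) assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeExperiment",
          function(x) as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("populationOf", "GenotypeExperiment", function(x) {
    p <- as.character(colData(x)$population)
    names(p) <- as.character(colData(x)$sample)
    p
})

#' @rdname accessors
#' @export
setMethod("haplotypes", "GenotypeExperiment", function(x) {
    if (!all(c("hapA", "hapB") %in% assayNames(x))) return(NULL)
    list(hapA = assay(x, "hapA"), hapB = assay(x, "hapB"))
})

#' @rdname accessors
#' @export
setMethod("altCounts", "FrequencyTable", function(x) x@altCount)

#' @rdname accessors
#' @export
setMethod("calledChroms", "FrequencyTable", function(x) x@calledChroms)

#' @rdname accessors
#' @export
setMethod("alleleFreqs", "FrequencyTable", function(x) x@af)

#' @rdname accessors
#' @export
setMethod("derivedFreqs", "FrequencyTable", function(x) x@daf)

#' @rdname accessors
#' @export
setMethod("variantInfo", "FrequencyTable", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("isolateLabel", "CohortPair", function(x) x@isolate)

#' @rdname accessors
#' @export
setMethod("generalLabel", "CohortPair", function(x) x@general)

#' @rdname accessors
#' @export
setMethod("measures", "CohortPairResult", function(x) x@measures)

#' Subset a FrequencyTable by variant index
#'
#' @param x a FrequencyTable.
#' @param i integer or logical variant index.
#' @param j,...,drop ignored (rows only).
#' @export
setMethod("[", "FrequencyTable", function(x, i, j, ..., drop = FALSE) {
    new("FrequencyTable",
        altCount = x@altCount[i, , drop = FALSE],
        calledChroms = x@calledChroms[i, , drop = FALSE],
        af = x@af[i, , drop = FALSE],
        daf = x@daf[i, , drop = FALSE],
        variants = x@variants[i, , drop = FALSE])
})

setMethod("show", "GenotypeExperiment", function(object) {
    cat("GenotypeExperiment:", nrow(object), "variants x",
        ncol(object), "samples\n")
    pops <- table(populationOf(object))
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
              collapse = ", "), "\n")
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    cq <- table(variantInfo(object)$consequence)
    cat("consequences:",
        paste(sprintf("%s=%d", names(cq), as.integer(cq)), collapse = ", "),
        "\n")
    invisible(object)
})

setMethod("show", "CohortPair", function(object) {
    cat("CohortPair: isolate =", object@isolate,
        "| general =", object@general, "\n")
    invisible(object)
})

setMethod("show", "FrequencyTable", function(object) {
    cat("FrequencyTable:", nrow(object@altCount), "variants x",
        ncol(object@altCount), "populations (",
        paste(colnames(object@altCount), collapse = ", "), ")\n")
    invisible(object)
})

setMethod("show", "DriftedVariantSet", function(object) {
    cat("DriftedVariantSet for", object@pair@isolate, "vs",
        object@pair@general, "\n")
    cat(sprintf("  band [%.3f, %.3f], fold %.1f\n",
                object@band[1], object@band[2], object@fold))
    cat(sprintf("  drifted in isolate: %d; drifted in general: %d\n",
                length(object@dirX), length(object@dirY)))
    invisible(object)
})

setMethod("show", "CohortPairResult", function(object) {
    cat("CohortPairResult:", object@pair@isolate, "vs",
        object@pair@general, "\n")
    m <- object@measures
    for (nm in names(m))
        cat(sprintf("  %-14s %s\n", nm,
                    ifelse(is.na(m[[nm]]), "NA", format(m[[nm]], digits = 4))))
    invisible(object)
})
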