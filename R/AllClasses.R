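#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData rowData<- colData colData<-
#' @useDynLib isodrift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.CONSEQUENCE_LEVELS <- c("missense", "lof", "synonymous", "intergenic", "other")

#' GenotypeExperiment: genotypes plus variant annotation for cohort pairs
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' variants-by-samples allele-dosage matrix (assay \code{"dosage"}, values 0/1/2
#' counting the ALT allele, \code{NA} = missing call), optional phased
#' haplotype assays (\code{"hapA"}, \code{"hapB"}, ALT-allele indicators), the
#' per-variant annotation in \code{rowData} (chrom, pos, ref, alt, ancestral,
#' gene, consequence, cadd) and the sample-to-population mapping in
#' \code{colData} (columns \code{sample}, \code{population}).
#'
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    rd <- rowData(object)
    need <- c("chrom", "pos", "ref", "alt", "ancestral", "gene",
              "consequence", "cadd")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    cd <- colData(object)
    if (!all(c("sample", "population") %in% colnames(cd)))
        msg <- c(msg, "colData needs columns 'sample' and 'population'")
    if ("dosage" %in% assayNames(object)) {
        d <- assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
            msg <- c(msg, "dosage values must be in {0, 1, 2} or NA")
    }
    if ("consequence" %in% colnames(rd)) {
        cq <- as.character(rd$consequence)
        if (any(!cq %in% .CONSEQUENCE_LEVELS))
            msg <- c(msg, paste0("consequence must be one of: ",
                                 paste(.CONSEQUENCE_LEVELS, collapse = ", ")))
    }
    if (all(c("chrom", "pos") %in% colnames(rd)) && nrow(rd) > 1) {
        ok <- all(tapply(rd$pos, as.character(rd$chrom),
                         function(p) all(diff(p) > 0)))
        if (!isTRUE(ok))
            msg <- c(msg, "positions must be strictly increasing within chromosomes")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosage integer matrix, variants x samples, values 0/1/2 (ALT-allele
#'   dosage) or NA for missing calls.
#' @param variants data.frame with columns chrom, pos, ref, alt, ancestral
#'   (allele string or NA for unknown), gene (symbol or NA), consequence (one
#'   of missense/lof/synonymous/intergenic/other) and cadd (non-negative or
#'   NA).
#' @param samples data.frame with columns sample and population.
#' @param hapA,hapB optional phased haplotype matrices (0/1 ALT indicators)
#'   with the same dimensions as \code{dosage}.
#' @return a [GenotypeExperiment-class] object.
#' @export
GenotypeExperiment <- function(dosage, variants, samples,
                               hapA = NULL, hapB = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (nrow(dosage) != nrow(variants))
        stop("dosage rows must match variant table rows")
    if (ncol(dosage) != nrow(samples))
        stop("dosage columns must match sample table rows")
    variants <- as.data.frame(variants)
    variants$consequence <- as.character(variants$consequence)
    assays <- list(dosage = dosage)
    if (!is.null(hapA)) {
        stopifnot(!is.null(hapB), dim(hapA) == dim(dosage),
                  dim(hapB) == dim(dosage))
        storage.mode(hapA) <- "integer"
        storage.mode(hapB) <- "integer"
        assays$hapA <- hapA
        assays$hapB <- hapB
    }
    se <- SummarizedExperiment(
        assays = assays,
        rowData = DataFrame(variants),
        colData = DataFrame(sample = as.character(samples$sample),
                            population = as.character(samples$population),
                            row.names = as.character(samples$sample)))
    new("GenotypeExperiment", se)
}

#' CohortPair: an isolate / general population pairing
#'
#' @slot isolate label of the isolated population.
#' @slot general label of the matched general population.
#' @export
setClass("CohortPair",
         representation(isolate = "character", general = "character"))

setValidity("CohortPair", function(object) {
    if (length(object@isolate) != 1 || length(object@general) != 1)
        return("isolate and general must be single labels")
    if (!nzchar(object@isolate) || !nzchar(object@general))
        return("population labels must be non-empty")
    if (object@isolate == object@general)
        return("isolate and general labels must differ")
    TRUE
})

#' @param isolate,general population labels present in the data.
#' @rdname CohortPair-class
#' @export
cohortPair <- function(isolate, general)
    new("CohortPair", isolate = as.character(isolate),
        general = as.character(general))

#' FrequencyTable: per-variant, per-population allele counts
#'
#' Matrices are variants x populations. \code{altCount} holds integer ALT
#' allele counts, \code{calledChroms} the number of successfully called
#' chromosomes (missing genotypes are excluded from the denominator),
#' \code{af} the ALT allele frequency and \code{daf} the derived allele
#' frequency (NA where the ancestral allele is unknown or matches neither
#' allele). \code{variants} carries the annotation columns of the source
#' [GenotypeExperiment-class].
#'
#' @export
setClass("FrequencyTable",
         representation(altCount = "matrix", calledChroms = "matrix",
                        af = "matrix", daf = "matrix",
                        variants = "data.frame"))

setValidity("FrequencyTable", function(object) {
    d <- dim(object@altCount)
    if (!identical(d, dim(object@calledChroms)) ||
        !identical(d, dim(object@af)) || !identical(d, dim(object@daf)))
        return("all matrices must share dimensions")
    if (nrow(object@variants) != d[1])
        return("variant table must match matrix rows")
    if (any(object@altCount > object@calledChroms, na.rm = TRUE))
        return("altCount must not exceed calledChroms")
    af <- object@af[!is.na(object@af)]
    if (length(af) && (min(af) < 0 || max(af) > 1))
        return("af must lie in [0, 1]")
    TRUE
})

#' DriftedVariantSet: variants satisfying the drifted-variant rule
#'
#' Holds, for both directions of a cohort pair, the indices of variants at
#' derived allele frequency within the low-frequency band in the focal
#' population and at least \code{fold} times lower in the other.
#'
#' @export
setClass("DriftedVariantSet",
         representation(pair = "CohortPair", dirX = "integer",
                        dirY = "integer", dafX = "numeric", dafY = "numeric",
                        band = "numeric", fold = "numeric"))

#' CohortPairResult: all statistics for one isolate/general pair
#'
#' @slot pair the [CohortPair-class] analysed.
#' @slot measures named numeric vector of headline scalars (dvxyCoding,
#'   svXy, rxyMissense, fst, meanF, rohTotalMb, ldDecayKb, tdg, neRecent,
#'   deltaAncestry, isx, ...).
#' @slot tables list of per-statistic detail tables (data.frames).
#' @slot metadata list recording seed, subsetting scheme and toggles.
#' @export
setClass("CohortPairResult",
         representation(pair = "CohortPair", measures = "numeric",
                        tables = "list", metadata = "list"))
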