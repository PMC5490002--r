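#' Rxy genetic-load ratio for a variant class
#'
#' For a set of class sites, the load terms are
#' \eqn{L(x \not y) = \sum daf_x (1 - daf_y)} and
#' \eqn{L(y \not x) = \sum daf_y (1 - daf_x)}; the raw ratio is
#' \eqn{R = L(x \not y) / L(y \not x)}. The reported Rxy divides the class
#' ratio by the same ratio computed on a neutral control class (synonymous
#' or CADD < 5), so pure drift cancels and 1 means equal load. Sites with
#' \code{daf_x = daf_y = 0} contribute nothing and are skipped; intragenic
#' variants are not offered as a control class.
#'
#' @param ft a [FrequencyTable-class] (matched-sample-size data in the
#'   standard workflow).
#' @param pair a [CohortPair-class].
#' @param classIdx integer indices of the test-class sites.
#' @param controlIdx integer indices of the control-class sites (disjoint
#'   from \code{classIdx}).
#' @return list with \code{estimate} (normalised Rxy), \code{rawClass},
#'   \code{rawControl} and a \code{note} ("" or the zero-term flag).
#' @export
rxy <- function(ft, pair, classIdx, controlIdx) {
    stopIfNotPair(ft, pair)
    if (!length(classIdx) || !length(controlIdx))
        stop("both the class and the control set must be non-empty")
    if (length(intersect(classIdx, controlIdx)))
        stop("class and control sets must be disjoint")
    rawRatio <- function(idx) {
        dx <- ft@daf[idx, pair@isolate]
        dy <- ft@daf[idx, pair@general]
        ok <- !is.na(dx) & !is.na(dy) & (dx > 0 | dy > 0)
        lxy <- sum(dx[ok] * (1 - dy[ok]))
        lyx <- sum(dy[ok] * (1 - dx[ok]))
        c(lxy = lxy, lyx = lyx)
    }
    lc <- rawRatio(classIdx)
    lk <- rawRatio(controlIdx)
    if (any(c(lc, lk) == 0))
        return(list(estimate = NA_real_, rawClass = NA_real_,
                    rawControl = NA_real_,
                    note = "undefined: zero load term"))
    rawClass <- lc[["lxy"]] / lc[["lyx"]]
    rawControl <- lk[["lxy"]] / lk[["lyx"]]
    list(estimate = rawClass / rawControl, rawClass = rawClass,
         rawControl = rawControl, note = "")
}

#' Select variant indices for a named functional class
#'
#' Understood classes: \code{"missense"}, \code{"lof"},
#' \code{"missense+lof"}, \code{"synonymous"}, \code{"cadd>10"},
#' \code{"cadd>20"}, \code{"cadd<5"}.
#'
#' @param ft a [FrequencyTable-class].
#' @param class class label.
#' @return integer vector of variant indices.
#' @export
variantClassIndices <- function(ft, class) {
    vi <- ft@variants
    switch(class,
           "missense" = which(vi$consequence == "missense"),
           "lof" = which(vi$consequence == "lof"),
           "missense+lof" = which(vi$consequence %in% c("missense", "lof")),
           "synonymous" = which(vi$consequence == "synonymous"),
           "cadd>10" = which(!is.na(vi$cadd) & vi$cadd > 10),
           "cadd>20" = which(!is.na(vi$cadd) & vi$cadd > 20),
           "cadd<5" = which(!is.na(vi$cadd) & vi$cadd < 5),
           stop("unknown variant class: ", class))
}

#' Rxy with chromosome-block bootstrap dispersion
#'
#' Computes the point estimate of [rxy()] for each requested class against
#' its control, then resamples chromosome blocks with replacement
#' \code{reps} times (blocks preserve local LD) and reports the bootstrap
#' mean and standard deviation.
#'
#' @param ft a [FrequencyTable-class].
#' @param pair a [CohortPair-class].
#' @param classes character vector of test classes (see
#'   [variantClassIndices()]).
#' @param control control class, default \code{"synonymous"}
#'   (\code{"cadd<5"} is the whole-genome alternative).
#' @param reps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return data.frame: class, control, estimate, bootMean, bootSd, note.
#' @export
rxyBootstrap <- function(ft, pair, classes = "missense",
                         control = "synonymous", reps = 100, seed = 1) {
    chroms <- unique(ft@variants$chrom)
    if (length(chroms) < 2)
        stop("chromosome-block bootstrap needs at least 2 chromosomes")
    one <- function(ftSub, cls) {
        ci <- variantClassIndices(ftSub, cls)
        ki <- variantClassIndices(ftSub, control)
        ki <- setdiff(ki, ci)
        if (!length(ci) || !length(ki))
            return(list(estimate = NA_real_, note = "empty class"))
        rxy(ftSub, pair, ci, ki)
    }
    out <- lapply(classes, function(cls) {
        pt <- one(ft, cls)
        boots <- withSeed(seed, vapply(seq_len(reps), function(i) {
            ch <- sample(chroms, length(chroms), replace = TRUE)
            idx <- unlist(lapply(ch, function(cc)
                which(ft@variants$chrom == cc)), use.names = FALSE)
            one(ft[idx], cls)$estimate
        }, numeric(1)))
        data.frame(class = cls, control = control,
                   estimate = pt$estimate,
                   bootMean = mean(boots, na.rm = TRUE),
                   bootSd = stats::sd(boots, na.rm = TRUE),
                   note = pt$note, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
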