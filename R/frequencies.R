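#' Per-population allele counts and frequencies
#'
#' Computes, for each variant and each requested population, the ALT allele
#' count, the number of called chromosomes (missing genotypes excluded from
#' the denominator), the ALT allele frequency and the derived allele
#' frequency. DAF equals the ALT frequency when the ancestral allele is the
#' REF allele, its complement when the ancestral allele is the ALT allele,
#' and \code{NA} when the ancestral state is unknown.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param populations character vector of population labels (default: all
#'   populations present).
#' @return a [FrequencyTable-class].
#' @export
alleleFrequencies <- function(ge, populations = NULL) {
    pops_all <- populationOf(ge)
    if (is.null(populations)) populations <- unique(unname(pops_all))
    d <- dosages(ge)
    vi <- variantInfo(ge)
    nv <- nrow(d)
    altc <- called <- matrix(0L, nv, length(populations),
                             dimnames = list(NULL, populations))
    for (p in populations) {
        cols <- which(pops_all == p)
        if (!length(cols)) stop("empty population: ", p)
        dp <- d[, cols, drop = FALSE]
        altc[, p] <- as.integer(rowSums(dp, na.rm = TRUE))
        called[, p] <- as.integer(2L * rowSums(!is.na(dp)))
    }
    af <- altc / called
    af[called == 0L] <- NA_real_
    daf <- matrix(NA_real_, nv, length(populations),
                  dimnames = list(NULL, populations))
    anc_is_ref <- !is.na(vi$ancestral) & vi$ancestral == vi$ref
    anc_is_alt <- !is.na(vi$ancestral) & vi$ancestral == vi$alt
    daf[anc_is_ref, ] <- af[anc_is_ref, ]
    daf[anc_is_alt, ] <- 1 - af[anc_is_alt, ]
    new("FrequencyTable", altCount = altc, calledChroms = called,
        af = af, daf = daf, variants = vi)
}

#' Convert an allele count to a MAF percentage
#'
#' The convention used in cohort summary tables: an allele count of 4 in 36
#' diploid individuals (72 chromosomes) corresponds to a MAF of 5.6%, and a
#' count of 1 to 1.4%.
#'
#' @param alleleCount non-negative allele count (vectorised).
#' @param nDiploids number of diploid individuals sampled.
#' @return MAF in percent, rounded to one decimal.
#' @export
countToMaf <- function(alleleCount, nDiploids) {
    if (any(nDiploids <= 0)) stop("nDiploids must be positive")
    if (any(alleleCount < 0 | alleleCount > 2 * nDiploids))
        stop("alleleCount must lie in [0, 2 * nDiploids]")
    round(100 * alleleCount / (2 * nDiploids), 1)
}

#' Subsample cohorts to a common analysis scheme
#'
#' \code{"minimum"} draws \code{n} individuals from every population (the
#' minimum-sample-size scheme; default n = 36); \code{"matched"} downsamples
#' the larger population of a pair to the size of the smaller;
#' \code{"whole"} returns the input unchanged. Sampling is uniform without
#' replacement, deterministic given \code{seed}, and preserves input sample
#' order.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param scheme one of "minimum", "matched", "whole".
#' @param n minimum-scheme sample size per population.
#' @param pair a [CohortPair-class]; required for \code{"matched"}.
#' @param seed integer seed.
#' @return the subsampled GenotypeExperiment.
#' @export
subsampleCohorts <- function(ge, scheme = c("minimum", "matched", "whole"),
                             n = 36, pair = NULL, seed = 1) {
    scheme <- match.arg(scheme)
    if (scheme == "whole") return(ge)
    pops <- populationOf(ge)
    keep <- withSeed(seed, {
        if (scheme == "minimum") {
            unlist(lapply(unique(unname(pops)), function(p) {
                cols <- which(pops == p)
                if (length(cols) < n)
                    stop("population '", p, "' has only ", length(cols),
                         " samples; scheme 'minimum' needs ", n)
                sort(sample(cols, n))
            }))
        } else {
            if (is.null(pair))
                stop("scheme 'matched' requires a CohortPair")
            ci <- which(pops == pair@isolate)
            cg <- which(pops == pair@general)
            if (!length(ci) || !length(cg))
                stop("pair population missing from the data")
            target <- min(length(ci), length(cg))
            sort(c(if (length(ci) > target) sort(sample(ci, target)) else ci,
                   if (length(cg) > target) sort(sample(cg, target)) else cg))
        }
    })
    ge[, keep]
}

#' Count segregating variants by population, MAF bin and consequence
#'
#' Bins are half-open MAF intervals (lo, hi] covering (0, 0.5]; the default
#' reproduces the rare (MAF <= 2%), low-frequency (2-5%) and common (> 5%)
#' classification. A variant monomorphic in a population is not counted for
#' that population.
#'
#' @param ft a [FrequencyTable-class].
#' @param bins either a numeric break vector (e.g. \code{c(0, 0.02, 0.05,
#'   0.5)}) or a list of \code{c(lo, hi)} intervals (checked for overlap).
#' @param populations populations to tabulate (default: all in \code{ft}).
#' @return data.frame with columns population, bin, consequence, count.
#' @export
countVariantsStratified <- function(ft, bins = c(0, 0.02, 0.05, 0.5),
                                    populations = NULL) {
    if (is.list(bins)) {
        iv <- do.call(rbind, bins)
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
            stop("overlapping MAF bins")
        breaks <- unique(as.vector(t(iv)))
        if (length(breaks) != nrow(iv) + 1)
            stop("bins must tile (0, 0.5] without gaps")
    } else {
        breaks <- sort(bins)
    }
    if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - 0.5) > 1e-9)
        stop("bins must cover (0, 0.5]")
    pops <- colnames(ft@altCount)
    if (is.null(populations)) populations <- pops
    labels <- paste0("(", utils::head(breaks, -1) * 100, "%,",
                     utils::tail(breaks, -1) * 100, "%]")
    out <- list()
    for (p in populations) {
        seg <- ft@altCount[, p] > 0L &
            ft@altCount[, p] < ft@calledChroms[, p]
        maf <- pmin(ft@af[, p], 1 - ft@af[, p])
        bin <- cut(maf, breaks, labels = labels, right = TRUE,
                   include.lowest = FALSE)
        tab <- table(bin = bin[seg],
                     consequence = ft@variants$consequence[seg])
        df <- as.data.frame(tab, stringsAsFactors = FALSE)
        df$population <- p
        out[[p]] <- df[, c("population", "bin", "consequence", "Freq")]
    }
    out <- do.call(rbind, out)
    names(out)[names(out) == "Freq"] <- "count"
    rownames(out) <- NULL
    out
}
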