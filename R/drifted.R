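#' Identify drifted variants for a cohort pair
#'
#' A variant is drifted in the isolate (direction x) when its derived allele
#' frequency lies within \code{band} (endpoints inclusive) in the isolate
#' and is at least \code{fold} times the DAF in the general population
#' (\code{daf_y = 0} satisfies the rule: complete absence is the extreme
#' drift case). Direction y is defined symmetrically. Only variants with a
#' defined DAF in both populations are considered.
#'
#' @param ft a [FrequencyTable-class].
#' @param pair a [CohortPair-class].
#' @param band DAF band, default \code{c(0.02, 0.05)}.
#' @param fold fold-difference threshold, default 3.
#' @return a [DriftedVariantSet-class].
#' @export
findDriftedVariants <- function(ft, pair, band = c(0.02, 0.05), fold = 3) {
    stopIfNotPair(ft, pair)
    stopifnot(length(band) == 2, band[1] > 0, band[2] < 0.5,
              band[1] < band[2], fold > 1)
    dx <- ft@daf[, pair@isolate]
    dy <- ft@daf[, pair@general]
    ok <- !is.na(dx) & !is.na(dy)
    if (!any(ok))
        stop("no variants with a defined derived allele frequency")
    inBand <- function(v) v >= band[1] & v <= band[2]
    dirX <- which(ok & inBand(dx) & dx >= fold * dy)
    dirY <- which(ok & inBand(dy) & dy >= fold * dx)
    new("DriftedVariantSet", pair = pair,
        dirX = as.integer(dirX), dirY = as.integer(dirY),
        dafX = dx, dafY = dy, band = as.numeric(band), fold = as.numeric(fold))
}

# shared ratio-of-fractions core; returns NA (with reason) when any
# denominator count is zero
.dvRatio <- function(nFuncX, nNeutX, nFuncY, nNeutY) {
    zero <- c(if (nNeutX == 0) "nNeutX", if (nNeutY == 0) "nNeutY",
              if (nFuncY == 0) "nFuncY")
    if (length(zero))
        return(list(estimate = NA_real_,
                    note = paste("undefined: zero count in",
                                 paste(zero, collapse = ","))))
    list(estimate = (nFuncX / nNeutX) / (nFuncY / nNeutY), note = "")
}

#' DVxy for coding variants
#'
#' The fraction of functional drifted variants (missense + LoF by default)
#' over intergenic drifted variants in the isolate direction, divided by the
#' same fraction in the general direction. 1 means no enrichment; values
#' above 1 indicate enrichment of functional drifted variants in the
#' isolate. A zero count in any denominator yields an explicit \code{NA}
#' with the offending count named, never 0 or infinity.
#'
#' @param dv a [DriftedVariantSet-class].
#' @param variants variant annotation data.frame (needs a
#'   \code{consequence} column aligned with the frequency table used to
#'   build \code{dv}).
#' @param functional,neutral consequence classes treated as functional and
#'   as drift control.
#' @return one-row data.frame: stratum, estimate, ciLow, ciHigh, counts,
#'   note.
#' @export
dvxyCoding <- function(dv, variants, functional = c("missense", "lof"),
                       neutral = "intergenic") {
    cq <- variants$consequence
    nFx <- sum(cq[dv@dirX] %in% functional)
    nNx <- sum(cq[dv@dirX] %in% neutral)
    nFy <- sum(cq[dv@dirY] %in% functional)
    nNy <- sum(cq[dv@dirY] %in% neutral)
    r <- .dvRatio(nFx, nNx, nFy, nNy)
    data.frame(stratum = "coding", estimate = r$estimate,
               ciLow = NA_real_, ciHigh = NA_real_,
               nFuncX = nFx, nNeutX = nNx, nFuncY = nFy, nNeutY = nNy,
               note = r$note, stringsAsFactors = FALSE)
}

#' DVxy-wg across CADD-score strata
#'
#' Whole-genome analogue of [dvxyCoding()]: drifted variants are stratified
#' by CADD score into half-open bins (default \code{[0,5) [5,10) [10,20)
#' [20,Inf)}); the lowest bin is the neutral reference, and each higher bin
#' is compared against it in both directions.
#'
#' @param dv a [DriftedVariantSet-class].
#' @param variants variant annotation with a \code{cadd} column.
#' @param caddBreaks increasing break vector; first interval is the neutral
#'   reference class.
#' @return data.frame with one row per non-reference bin.
#' @export
dvxyWg <- function(dv, variants, caddBreaks = c(0, 5, 10, 20, Inf)) {
    cadd <- variants$cadd
    binOf <- function(idx) findInterval(cadd[idx], caddBreaks,
                                        rightmost.closed = FALSE)
    bx <- binOf(dv@dirX)
    by <- binOf(dv@dirY)
    bx <- bx[!is.na(bx)]
    by <- by[!is.na(by)]
    nbin <- length(caddBreaks) - 1
    out <- vector("list", nbin - 1)
    for (b in 2:nbin) {
        lab <- if (is.finite(caddBreaks[b + 1]))
            sprintf("cadd[%g,%g)", caddBreaks[b], caddBreaks[b + 1])
        else sprintf("cadd>=%g", caddBreaks[b])
        r <- .dvRatio(sum(bx == b), sum(bx == 1), sum(by == b), sum(by == 1))
        out[[b - 1]] <- data.frame(
            stratum = lab, estimate = r$estimate,
            ciLow = NA_real_, ciHigh = NA_real_,
            nFuncX = sum(bx == b), nNeutX = sum(bx == 1),
            nFuncY = sum(by == b), nNeutY = sum(by == 1),
            note = r$note, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Chromosome-resampling confidence interval
#'
#' Draws \code{nChroms} chromosomes without replacement \code{reps} times,
#' recomputes the statistic on the variants of the sampled chromosomes, and
#' returns the 2.5/97.5 percentile interval. Deterministic given
#' \code{seed}.
#'
#' @param statFn function taking a character vector of chromosome labels and
#'   returning a numeric scalar (or named vector).
#' @param chroms all available chromosome labels.
#' @param nChroms chromosomes per replicate (default 20).
#' @param reps replicates (default 100).
#' @param seed integer seed.
#' @return list with \code{ciLow}, \code{ciHigh} and the replicate matrix
#'   \code{values}.
#' @export
chromosomeResampleCI <- function(statFn, chroms, nChroms = 20, reps = 100,
                                 seed = 1) {
    chroms <- unique(as.character(chroms))
    if (length(chroms) < nChroms)
        stop("only ", length(chroms), " chromosomes available; ",
             "use nChroms <= ", length(chroms))
    vals <- withSeed(seed, {
        lapply(seq_len(reps), function(i)
            statFn(sample(chroms, nChroms)))
    })
    values <- do.call(rbind, lapply(vals, function(v) as.numeric(v)))
    colnames(values) <- names(vals[[1]])
    list(ciLow = apply(values, 2, stats::quantile, 0.025, na.rm = TRUE),
         ciHigh = apply(values, 2, stats::quantile, 0.975, na.rm = TRUE),
         values = values)
}

#' DVxy point estimates with chromosome-resampling CIs and jackknife tests
#'
#' Convenience wrapper: computes DVxy-coding and DVxy-wg on the full data,
#' then (when the data span at least \code{nChroms} chromosomes) attaches
#' percentile confidence intervals from [chromosomeResampleCI()] and a
#' leave-one-chromosome-out jackknife z-test on log(DVxy).
#'
#' @param ft a [FrequencyTable-class].
#' @param pair a [CohortPair-class].
#' @param band,fold drifted-variant rule parameters.
#' @param caddBreaks CADD strata for DVxy-wg.
#' @param nChroms,reps,seed resampling parameters; \code{nChroms = NULL}
#'   skips the CI.
#' @return data.frame of strata with estimates, CIs and jackknife p-values.
#' @export
dvxyStatistics <- function(ft, pair, band = c(0.02, 0.05), fold = 3,
                           caddBreaks = c(0, 5, 10, 20, Inf),
                           nChroms = 20, reps = 100, seed = 1) {
    full <- .dvxyAll(ft, pair, band, fold, caddBreaks)
    chroms <- unique(ft@variants$chrom)
    full$jackknifeP <- NA_real_
    if (!is.null(nChroms) && length(chroms) >= nChroms) {
        statFn <- function(ch) {
            sub <- ft[ft@variants$chrom %in% ch]
            .dvxyAll(sub, pair, band, fold, caddBreaks)$estimate
        }
        ci <- chromosomeResampleCI(statFn, chroms, nChroms, reps, seed)
        full$ciLow <- as.numeric(ci$ciLow)
        full$ciHigh <- as.numeric(ci$ciHigh)
    }
    if (length(chroms) >= 3) {
        jk <- vapply(chroms, function(ch) {
            sub <- ft[ft@variants$chrom != ch]
            .dvxyAll(sub, pair, band, fold, caddBreaks)$estimate
        }, numeric(nrow(full)))
        jk <- matrix(jk, nrow = nrow(full))
        full$jackknifeP <- vapply(seq_len(nrow(full)), function(i) {
            v <- log(jk[i, ])
            v <- v[is.finite(v)]
            n <- length(v)
            if (n < 3 || !is.finite(log(full$estimate[i]))) return(NA_real_)
            theta <- log(full$estimate[i])
            se <- sqrt((n - 1) / n * sum((v - mean(v))^2))
            if (se == 0) return(NA_real_)
            2 * stats::pnorm(-abs(theta / se))
        }, numeric(1))
    }
    full
}

.dvxyAll <- function(ft, pair, band, fold, caddBreaks) {
    dv <- findDriftedVariants(ft, pair, band, fold)
    rbind(dvxyCoding(dv, ft@variants),
          dvxyWg(dv, ft@variants, caddBreaks))
}

#' Variants common in the isolate but rare in the general population
#'
#' Applies the printed count thresholds of the cohort summary: ALT allele
#' count at least \code{minCount} (default 4, MAF >= 5.6% at n = 36) in the
#' isolate and at most \code{maxCount} (default 1, MAF <= 1.4%) in the
#' general population, computed on the minimum-sample-size data set. When
#' counts for additional general populations are supplied, variants rare in
#' all of them are flagged \code{novelStyle}.
#'
#' @param ft a [FrequencyTable-class] built on the minimum-sample-size data.
#' @param pair a [CohortPair-class].
#' @param minCount,maxCount count thresholds.
#' @param allGenerals optional character vector of further general-population
#'   labels present in \code{ft}.
#' @return data.frame of qualifying variants with counts and a
#'   \code{novelStyle} flag.
#' @export
commonInIsolateRareInGeneral <- function(ft, pair, minCount = 4,
                                         maxCount = 1, allGenerals = NULL) {
    stopIfNotPair(ft, pair)
    cx <- ft@altCount[, pair@isolate]
    cy <- ft@altCount[, pair@general]
    keep <- which(cx >= minCount & cy <= maxCount)
    novel <- rep(NA, length(keep))
    if (!is.null(allGenerals)) {
        gm <- ft@altCount[keep, allGenerals, drop = FALSE]
        novel <- apply(gm <= maxCount, 1, all)
    }
    out <- ft@variants[keep, c("chrom", "pos", "ref", "alt", "consequence"),
                       drop = FALSE]
    out$countIsolate <- cx[keep]
    out$countGeneral <- cy[keep]
    out$novelStyle <- novel
    rownames(out) <- NULL
    out
}
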