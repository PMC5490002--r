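#' Genome-wide Hudson FST (ratio of sums)
#'
#' Per-site Hudson numerator and denominator,
#' \eqn{N = (p_1 - p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' \eqn{D = p_1(1-p_2) + p_2(1-p_1)}, combined as the ratio of sums over
#' sites polymorphic in the pooled pair. A Weir-Cockerham two-population
#' alternative is available behind \code{estimator = "wc"}.
#'
#' @param ft a [FrequencyTable-class].
#' @param pair a [CohortPair-class].
#' @param estimator "hudson" (default) or "wc".
#' @return list with \code{fst}, per-site \code{num} and \code{den}
#'   vectors, and the site index used.
#' @export
hudsonFst <- function(ft, pair, estimator = c("hudson", "wc")) {
    estimator <- match.arg(estimator)
    stopIfNotPair(ft, pair)
    p1 <- ft@af[, pair@isolate]
    p2 <- ft@af[, pair@general]
    n1 <- ft@calledChroms[, pair@isolate]
    n2 <- ft@calledChroms[, pair@general]
    c1 <- ft@altCount[, pair@isolate]
    c2 <- ft@altCount[, pair@general]
    poly <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1 &
        (c1 + c2) > 0 & (c1 + c2) < (n1 + n2)
    idx <- which(poly)
    if (!length(idx))
        return(list(fst = NA_real_, num = numeric(), den = numeric(),
                    sites = integer(), note = "no polymorphic site"))
    p1 <- p1[idx]; p2 <- p2[idx]; n1 <- n1[idx]; n2 <- n2[idx]
    if (estimator == "hudson") {
        num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
            p2 * (1 - p2) / (n2 - 1)
        den <- p1 * (1 - p2) + p2 * (1 - p1)
    } else {
        # Weir & Cockerham (1984) theta for two populations, ratio of sums
        r <- 2
        nbar <- (n1 + n2) / 2 / 2            # mean sample size (diploids)
        m1 <- n1 / 2; m2 <- n2 / 2
        nc <- (m1 + m2 - (m1^2 + m2^2) / (m1 + m2)) / (r - 1)
        pbar <- (m1 * p1 + m2 * p2) / (m1 + m2)
        s2 <- (m1 * (p1 - pbar)^2 + m2 * (p2 - pbar)^2) / ((r - 1) * nbar)
        # heterozygosity terms omitted (haplotype-level frequencies)
        a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) /
                              (nbar - 1))
        b <- nbar / (nbar - 1) *
            (pbar * (1 - pbar) - (r - 1) / r * s2)
        num <- a
        den <- a + b
    }
    list(fst = sum(num) / sum(den), num = num, den = den, sites = idx,
         note = "")
}

#' Method-of-moments inbreeding coefficient F
#'
#' Per individual, \eqn{F = 1 - H_{obs} / H_{exp}} where the expected
#' heterozygosity sums \eqn{2 p (1-p) \cdot 2n/(2n-1)} over the
#' population's polymorphic sites with a non-missing call in that
#' individual.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param population population label.
#' @param minSites minimum number of polymorphic sites (default 50).
#' @return list with per-individual \code{F} (named) and \code{meanF}.
#' @export
inbreedingF <- function(ge, population, minSites = 50) {
    cols <- popColumns(ge, population)
    d <- dosages(ge)[, cols, drop = FALSE]
    altc <- rowSums(d, na.rm = TRUE)
    called <- 2 * rowSums(!is.na(d))
    p <- altc / called
    poly <- which(!is.na(p) & p > 0 & p < 1 & called > 2)
    if (length(poly) < minSites)
        stop("need at least ", minSites, " polymorphic sites (have ",
             length(poly), ")")
    dp <- d[poly, , drop = FALSE]
    p <- p[poly]
    eh_site <- 2 * p * (1 - p) * called[poly] / (called[poly] - 1)
    fvals <- vapply(seq_len(ncol(dp)), function(i) {
        ok <- !is.na(dp[, i])
        obs <- sum(dp[ok, i] == 1)
        expv <- sum(eh_site[ok])
        if (expv == 0) return(NA_real_)
        1 - obs / expv
    }, numeric(1))
    names(fvals) <- colnames(d)
    list(F = fvals, meanF = mean(fvals, na.rm = TRUE))
}

# admissible run-of-homozygosity segments for one het indicator vector:
# every window of `win` consecutive sites inside the segment has <= maxHet
# heterozygous calls (total het count for segments shorter than `win`)
.rohSegments <- function(het, win, maxHet) {
    L <- length(het)
    empty <- cbind(start = integer(0), end = integer(0))
    if (!L) return(empty)
    cs <- c(0, cumsum(het))
    winsum <- function(a, b) cs[b + 1] - cs[a]  # sum het[a..b]
    # avec[b] = smallest admissible start for a segment ending at b; a
    # segment [a, b] is admissible when every full window of `win` sites
    # inside it has <= maxHet hets (total het count when shorter than win)
    avec <- integer(L)
    a <- 1L
    for (b in seq_len(L)) {
        if (b - a + 1L >= win && winsum(b - win + 1L, b) > maxHet)
            a <- b - win + 2L
        while (b - a + 1L < win && b >= a && winsum(a, b) > maxHet)
            a <- a + 1L
        avec[b] <- a
    }
    emit <- which(seq_len(L) == L | c(avec[-1] > avec[-L], TRUE))
    m <- cbind(start = avec[emit], end = emit)
    m[m[, "start"] <= m[, "end"], , drop = FALSE]
}

#' Runs-of-homozygosity scan
#'
#' PLINK-style scan over each individual and chromosome: maximal segments
#' of consecutive calls in which every window of \code{windowSites}
#' consecutive sites contains at most \code{maxHetPerWindow} heterozygous
#' calls; segment ends are trimmed to homozygous sites and segments
#' spanning at least \code{minLengthKb} are reported. Window and length
#' defaults are PLINK-like conventions, not taken from any cohort study.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param population population label.
#' @param minLengthKb minimum segment span (default 1000 kb).
#' @param windowSites sites per window (default 50).
#' @param maxHetPerWindow allowed heterozygotes per window (default 1).
#' @return list with \code{segments} (data.frame: individual, chrom,
#'   startBp, endBp, lengthBp, nSites) and \code{summary} (per-individual
#'   totals in Mb and counts).
#' @export
rohScan <- function(ge, population, minLengthKb = 1000, windowSites = 50,
                    maxHetPerWindow = 1) {
    stopifnot(minLengthKb > 0, windowSites > 0, maxHetPerWindow >= 0)
    cols <- popColumns(ge, population)
    d <- dosages(ge)[, cols, drop = FALSE]
    vi <- variantInfo(ge)
    ids <- colnames(d)
    segs <- list()
    for (ch in unique(vi$chrom)) {
        ridx <- which(vi$chrom == ch)
        pos <- vi$pos[ridx]
        for (i in seq_along(ids)) {
            g <- d[ridx, i]
            ok <- which(!is.na(g))
            if (!length(ok)) next
            het <- as.integer(g[ok] == 1)
            m <- .rohSegments(het, windowSites, maxHetPerWindow)
            if (!nrow(m)) next
            for (k in seq_len(nrow(m))) {
                a <- m[k, 1]; b <- m[k, 2]
                while (a <= b && het[a] == 1) a <- a + 1
                while (b >= a && het[b] == 1) b <- b - 1
                if (a > b) next
                sp <- pos[ok[a]]; ep <- pos[ok[b]]
                if ((ep - sp + 1) / 1000 < minLengthKb) next
                segs[[length(segs) + 1L]] <- data.frame(
                    individual = ids[i], chrom = ch, startBp = sp,
                    endBp = ep, lengthBp = ep - sp + 1L,
                    nSites = b - a + 1L, stringsAsFactors = FALSE)
            }
        }
    }
    segments <- if (length(segs)) do.call(rbind, segs) else
        data.frame(individual = character(), chrom = character(),
                   startBp = integer(), endBp = integer(),
                   lengthBp = integer(), nSites = integer())
    totals <- vapply(ids, function(id) {
        s <- segments[segments$individual == id, , drop = FALSE]
        c(totalMb = sum(s$lengthBp) / 1e6, nRoh = nrow(s))
    }, numeric(2))
    list(segments = segments,
         summary = data.frame(individual = ids,
                              totalMb = totals["totalMb", ],
                              nRoh = totals["nRoh", ],
                              row.names = NULL))
}

#' Pairwise r-squared within a physical distance
#'
#' Computes squared correlations between all site pairs within
#' \code{maxDistBp} on the same chromosome. Uses phased haplotypes when
#' present (haplotype correlation), otherwise the composite Rogers-Huff
#' style dosage correlation.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param population population label.
#' @param maxDistBp maximum pair distance in bp.
#' @param minMaf drop sites below this minor allele frequency (default
#'   0.05; rare sites carry little LD information).
#' @return data.frame with columns chrom, i, j (variant indices into
#'   \code{ge}), distBp, r2, plus attributes \code{nChrUsed} (number of
#'   chromosomes sampled, i.e. haplotypes or diploids) and \code{phased}.
#' @export
pairwiseR2 <- function(ge, population, maxDistBp = 1e6, minMaf = 0.05) {
    cols <- popColumns(ge, population)
    hp <- haplotypes(ge)
    if (!is.null(hp)) {
        X <- cbind(hp$hapA[, cols, drop = FALSE],
                   hp$hapB[, cols, drop = FALSE])
        phased <- TRUE
    } else {
        X <- dosages(ge)[, cols, drop = FALSE]
        phased <- FALSE
    }
    vi <- variantInfo(ge)
    af <- rowMeans(X, na.rm = TRUE) / (if (phased) 1 else 2)
    keep <- which(pmin(af, 1 - af) >= minMaf)
    out <- list()
    for (ch in unique(vi$chrom[keep])) {
        idx <- keep[vi$chrom[keep] == ch]
        if (length(idx) < 2) next
        pos <- vi$pos[idx]
        M <- t(X[idx, , drop = FALSE])             # samples x sites
        R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
        r2 <- R^2
        ii <- jj <- integer(0)
        hi <- findInterval(pos + maxDistBp, pos)
        for (a in seq_along(idx)) {
            if (hi[a] > a)
                { ii <- c(ii, rep.int(a, hi[a] - a)); jj <- c(jj, (a + 1):hi[a]) }
        }
        if (!length(ii)) next
        out[[ch]] <- data.frame(chrom = ch, i = idx[ii], j = idx[jj],
                                distBp = pos[jj] - pos[ii],
                                r2 = r2[cbind(ii, jj)],
                                stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(), i = integer(), j = integer(),
                   distBp = integer(), r2 = numeric())
    rownames(res) <- NULL
    attr(res, "nChrUsed") <- ncol(X)
    attr(res, "phased") <- phased
    res
}

#' LD decay length
#'
#' Mean r-squared per physical-distance bin; the decay length is the
#' midpoint of the first (smallest-distance) bin whose mean r-squared drops
#' below \code{r2Threshold}. When no bin falls below the threshold the
#' largest bin midpoint is returned with \code{flagged = TRUE}.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param population population label.
#' @param r2Threshold decay threshold (default 0.1).
#' @param binsKb distance-bin breaks in kb (default 25 kb steps to 500 kb).
#' @param minMaf MAF filter passed to [pairwiseR2()].
#' @return list with \code{decayKb}, \code{flagged} and the binned
#'   \code{profile} data.frame.
#' @export
ldDecayLength <- function(ge, population, r2Threshold = 0.1,
                          binsKb = seq(0, 500, by = 25), minMaf = 0.05) {
    pr <- pairwiseR2(ge, population, maxDistBp = max(binsKb) * 1000,
                     minMaf = minMaf)
    if (!nrow(pr)) stop("no site pairs available for LD decay")
    bin <- cut(pr$distBp / 1000, binsKb, right = TRUE)
    prof <- stats::aggregate(list(meanR2 = pr$r2), by = list(bin = bin),
                             FUN = mean)
    mids <- (utils::head(binsKb, -1) + utils::tail(binsKb, -1)) / 2
    prof$midKb <- mids[match(prof$bin, levels(bin))]
    prof <- prof[order(prof$midKb), ]
    below <- which(prof$meanR2 < r2Threshold)
    if (length(below)) {
        list(decayKb = prof$midKb[below[1]], flagged = FALSE,
             profile = prof)
    } else {
        list(decayKb = max(prof$midKb), flagged = TRUE, profile = prof)
    }
}
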