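#' LD-based effective population size trajectory
#'
#' Site pairs are binned by genetic distance c (Morgans, from a constant
#' cM/Mb map). Per bin with mean distance c, the sample-size-adjusted
#' linkage is \eqn{r^2_{adj} = \bar{r^2} - 1/S} with S the number of
#' sampled haplotypes (phased input) or \eqn{\bar{r^2} - 1/(2n)} for
#' dosage-based r-squared, giving the effective size
#' \eqn{Ne = (1/(4c)) (1/r^2_{adj} - 2)} indexing time \eqn{t = 1/(2c)}
#' generations ago. The 5-95% interval comes from a seeded bootstrap over
#' the bin's site pairs (mapped through the same transform; an unbounded
#' side is reported as 0/Inf). Bins with too few pairs or with
#' \eqn{r^2_{adj}} outside (0, 0.5) are dropped and flagged.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param population population label.
#' @param cBinsM genetic-distance bin breaks in Morgans (default 20
#'   log-spaced bins over 0.0001-0.01 M, i.e. 0.01-1 cM, covering roughly
#'   50-5000 generations).
#' @param cmPerMb constant genetic map, default 1 cM/Mb.
#' @param minMaf MAF filter for informative pairs (default 0.05).
#' @param minPairs minimum usable pairs per bin (default 20).
#' @return data.frame: t (generations), ne (median), ciLow, ciHigh (5/95
#'   percentiles), cMean, nPairs; attribute \code{dropped} lists dropped
#'   bins.
#' @export
neFromLd <- function(ge, population,
                     cBinsM = exp(seq(log(1e-4), log(1e-2), length.out = 21)),
                     cmPerMb = 1, minMaf = 0.05, minPairs = 20) {
    maxDist <- max(cBinsM) / (cmPerMb / 100) * 1e6 # Morgans -> bp
    pr <- pairwiseR2(ge, population, maxDistBp = maxDist, minMaf = minMaf)
    if (!nrow(pr)) stop("no site pairs available for Ne inference")
    S <- attr(pr, "nChrUsed")
    corr <- if (attr(pr, "phased")) 1 / S else 1 / (2 * S)
    cM <- pr$distBp * cmPerMb / 100 / 1e6     # Morgans
    bin <- cut(cM, cBinsM)
    neOf <- function(r2bar, c0) neFromAdjustedR2(r2bar - corr, c0)
    out <- list()
    dropped <- character()
    bootQ <- withSeed(97, lapply(levels(bin), function(b) {
        inb <- which(!is.na(bin) & bin == b)
        if (length(inb) < minPairs) return(NULL)
        bmeans <- vapply(seq_len(40), function(i)
            mean(pr$r2[sample(inb, length(inb), replace = TRUE)]),
            numeric(1))
        stats::quantile(bmeans, c(0.95, 0.05))
    }))
    names(bootQ) <- levels(bin)
    for (b in levels(bin)) {
        inb <- which(!is.na(bin) & bin == b)
        cMean <- mean(cM[inb])
        ne <- if (length(inb) >= minPairs)
            neOf(mean(pr$r2[inb]), cMean) else NA_real_
        if (is.na(ne)) {
            dropped <- c(dropped, b)
            next
        }
        qs <- bootQ[[b]]
        lo <- neOf(qs[[1]], cMean)
        hi <- neOf(qs[[2]], cMean)
        out[[b]] <- data.frame(t = 1 / (2 * cMean), ne = ne,
                               ciLow = if (is.na(lo)) 0 else lo,
                               ciHigh = if (is.na(hi)) Inf else hi,
                               cMean = cMean, nPairs = length(inb))
    }
    if (!length(out)) stop("all genetic-distance bins were dropped")
    res <- do.call(rbind, out)
    res$bin <- rownames(res)
    res <- res[order(res$t), ]
    rownames(res) <- NULL
    attr(res, "dropped") <- dropped
    res
}

#' Effective size from adjusted linkage at a genetic distance
#'
#' The closed-form inversion used per distance bin:
#' \eqn{Ne = (1/(4c)) (1/r^2_{adj} - 2)} for \eqn{r^2_{adj}} in (0, 0.5);
#' values outside that range (no linkage signal above the sampling floor,
#' or linkage too strong for a positive size) return \code{NA}.
#'
#' @param r2adj sample-size-adjusted mean r-squared.
#' @param cMorgans genetic distance in Morgans (> 0), indexing time
#'   \eqn{t = 1/(2c)} generations ago.
#' @return effective population size, or NA when undefined.
#' @export
neFromAdjustedR2 <- function(r2adj, cMorgans) {
    stopifnot(cMorgans > 0)
    if (is.na(r2adj) || r2adj <= 0 || r2adj >= 0.5) return(NA_real_)
    (1 / (4 * cMorgans)) * (1 / r2adj - 2)
}

#' Harmonic-mean recent Ne from a trajectory
#'
#' Harmonic mean of the per-bin Ne over the most recent bins (t at most
#' \code{maxT}); falls back to the single youngest bin when none qualify.
#'
#' @param traj trajectory from [neFromLd()].
#' @param maxT recency cutoff in generations (default 500).
#' @return scalar Ne.
#' @export
recentNe <- function(traj, maxT = 500) {
    sel <- traj$t <= maxT
    if (!any(sel)) sel <- seq_len(nrow(traj)) == which.min(traj$t)
    ne <- traj$ne[sel]
    length(ne) / sum(1 / ne)
}

#' Divergence time between an isolate and its general population
#'
#' Two estimators are provided. \code{method = "drift"} (default) inverts
#' the pure-drift differentiation clock,
#' \eqn{F_{ST} = 1 - \exp(-T / (2 \tilde N))}, using the harmonic mean
#' \eqn{\tilde N} of the two populations' recent LD-based Ne, so
#' \eqn{T = -2 \tilde N \log(1 - F_{ST})}; it requires the pair's
#' genome-wide FST. \code{method = "overlap"} scans the two trajectories
#' from the oldest shared time bin towards the present and returns the
#' oldest time at which the 5-95% intervals stop overlapping and remain
#' non-overlapping through every younger shared bin; because a strong
#' bottleneck inflates LD at all distances, this scan tends to
#' overestimate deep isolation and is kept as a descriptive alternative.
#' Identical or always-overlapping trajectories give \code{tdg = 0} with
#' \code{flagged = TRUE}.
#'
#' @param trajIsolate,trajGeneral trajectories from [neFromLd()] on the
#'   same bin grid (matched by bin label).
#' @param fst genome-wide FST of the pair (required for
#'   \code{method = "drift"}).
#' @param method "drift" or "overlap".
#' @param maxT recency cutoff passed to [recentNe()] for the drift clock.
#' @return list with \code{tdg} (generations) and \code{flagged}.
#' @export
estimateTdg <- function(trajIsolate, trajGeneral, fst = NULL,
                        method = c("drift", "overlap"), maxT = 500) {
    method <- match.arg(method)
    if (method == "drift") {
        if (is.null(fst) || is.na(fst))
            stop("method 'drift' needs the pair's genome-wide FST")
        if (fst >= 1) stop("fst must be below 1")
        # self-consistent clock: the harmonic-mean size entering the drift
        # clock should only average trajectory bins younger than the split
        # itself, so iterate the estimate to its fixed point
        tdg <- maxT
        for (k in 1:4) {
            n1 <- recentNe(trajIsolate, tdg)
            n2 <- recentNe(trajGeneral, tdg)
            ntilde <- 2 / (1 / n1 + 1 / n2)
            tdg <- max(-2 * ntilde * log(1 - max(fst, 0)), 0)
        }
        return(list(tdg = tdg, flagged = fst <= 0))
    }
    shared <- intersect(trajIsolate$bin, trajGeneral$bin)
    if (!length(shared))
        stop("trajectories share no time bins (disjoint grids)")
    a <- trajIsolate[match(shared, trajIsolate$bin), ]
    b <- trajGeneral[match(shared, trajGeneral$bin), ]
    ord <- order(a$t)             # youngest first
    a <- a[ord, ]; b <- b[ord, ]
    disjoint <- a$ciLow > b$ciHigh | b$ciLow > a$ciHigh
    run <- which(!disjoint)
    k <- if (!length(run)) length(disjoint) else run[1] - 1L
    if (k == 0) return(list(tdg = 0, flagged = TRUE))
    list(tdg = a$t[k], flagged = FALSE)
}

#' Delta Ancestry (M) from a K = 2 admixture matrix
#'
#' The component with the higher isolate mean is taken as the isolate
#' component; M is the difference between its mean over isolate samples and
#' its mean over general samples, clamped to [0, 1]. Invariant to component
#' relabelling and to sample order. Higher Delta Ancestry means more
#' private isolate ancestry and serves as an inverse-migration proxy.
#'
#' @param q numeric matrix with 2 columns, rownames = sample IDs (or rows
#'   aligned with \code{populations}).
#' @param populations named (or aligned) character vector of population
#'   labels per sample.
#' @param pair a [CohortPair-class].
#' @return scalar M in [0, 1].
#' @export
deltaAncestry <- function(q, populations, pair) {
    if (ncol(q) != 2)
        stop("Delta Ancestry requires a K = 2 Q matrix (got K = ",
             ncol(q), ")")
    if (!is.null(rownames(q)) && !is.null(names(populations)))
        populations <- populations[rownames(q)]
    iso <- populations == pair@isolate
    gen <- populations == pair@general
    if (!any(iso) || !any(gen))
        stop("pair populations not found among Q matrix samples")
    comp <- which.max(colMeans(q[iso, , drop = FALSE]))
    m <- mean(q[iso, comp]) - mean(q[gen, comp])
    min(max(m, 0), 1)
}

#' Lightweight K = 2 admixture estimation by EM
#'
#' Block-relaxation maximum likelihood under the standard admixture model
#' (dosage ~ Binomial(2, q f1 + (1 - q) f2)). The log-likelihood is
#' monotone non-decreasing over iterations; iteration stops at a relative
#' change below \code{tol} or at \code{maxIter} (with a warning flag).
#'
#' @param ge a [GenotypeExperiment-class] restricted to the pair's samples
#'   (or a plain dosage matrix, variants x samples).
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param maxIter iteration cap (default 500).
#' @param seed seed for the jittered initialisation.
#' @param minSites minimum polymorphic sites (default 100).
#' @return list with \code{Q} (samples x 2), \code{f} (sites x 2),
#'   \code{logLik} trace, \code{converged}.
#' @export
admixtureEmK2 <- function(ge, tol = 1e-6, maxIter = 500, seed = 1,
                          minSites = 100) {
    d <- if (is(ge, "GenotypeExperiment")) dosages(ge) else as.matrix(ge)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    p <- rowMeans(d) / 2
    poly <- p > 0 & p < 1
    if (sum(poly) < minSites)
        stop("need at least ", minSites, " polymorphic sites (have ",
             sum(poly), ")")
    G <- t(d[poly, , drop = FALSE])               # individuals x sites
    p <- p[poly]
    n <- nrow(G); L <- ncol(G)
    eps <- 1e-6
    clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
    init <- withSeed(seed, list(
        q = stats::runif(n, 0.2, 0.8),
        f1 = clamp(p + stats::runif(L, -0.1, 0.1)),
        f2 = clamp(p + stats::runif(L, -0.1, 0.1))))
    q <- init$q; f1 <- init$f1; f2 <- init$f2
    ll <- function(q, f1, f2) {
        P <- clamp(outer(q, f1) + outer(1 - q, f2))
        sum(G * log(P) + (2 - G) * log(1 - P))
    }
    trace <- ll(q, f1, f2)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        P <- clamp(outer(q, f1) + outer(1 - q, f2))
        A <- outer(q, f1) / P                 # P(copy from comp1 | derived)
        B <- outer(q, 1 - f1) / (1 - P)       # P(comp1 | ancestral)
        E1d <- G * A                           # expected comp1-derived copies
        E1a <- (2 - G) * B
        E2d <- G * (1 - A)
        E2a <- (2 - G) * (1 - B)
        q <- clamp(rowSums(E1d + E1a) / (2 * L))
        f1 <- clamp(colSums(E1d) / pmax(colSums(E1d + E1a), eps))
        f2 <- clamp(colSums(E2d) / pmax(colSums(E2d + E2a), eps))
        trace <- c(trace, ll(q, f1, f2))
        k <- length(trace)
        if (abs(trace[k] - trace[k - 1]) <
            tol * (abs(trace[k - 1]) + eps)) {
            converged <- TRUE
            break
        }
    }
    Q <- cbind(Q1 = q, Q2 = 1 - q)
    rownames(Q) <- rownames(G)
    if (!converged)
        warning("admixture EM did not converge in ", maxIter, " iterations")
    list(Q = Q, f = cbind(f1 = f1, f2 = f2), logLik = trace,
         converged = converged)
}

#' Isolation index
#'
#' Combines the divergence time from the general population (Tdg,
#' generations), the isolate's recent effective size (Ne) and the Delta
#' Ancestry migration proxy (M) into
#' \eqn{Isx = Tdg \cdot M / Ne}: strictly increasing in Tdg and M,
#' strictly decreasing in Ne, so early-diverged, small, closed isolates
#' score highest.
#'
#' @param tdg divergence time in generations (>= 0).
#' @param ne effective population size (> 0).
#' @param m Delta Ancestry in [0, 1].
#' @return scalar index.
#' @export
isx <- function(tdg, ne, m) {
    if (any(ne <= 0)) stop("ne must be positive")
    stopifnot(all(tdg >= 0), all(m >= 0 & m <= 1))
    tdg * m / ne
}

#' Convert generations to years
#'
#' @param generations numeric vector.
#' @param generationTimeYears years per generation (default 29).
#' @return years.
#' @export
generationsToYears <- function(generations, generationTimeYears = 29)
    generations * generationTimeYears

#' Pairwise Pearson correlations across cohort measures
#'
#' @param measuresTable data.frame or matrix, cohorts (>= 3) in rows,
#'   measures in columns.
#' @return list with matrices \code{r} and \code{p} (two-sided) plus the
#'   Isx row extracted as \code{isxRow} when present; constant columns give
#'   NA with a warning.
#' @export
correlateMeasures <- function(measuresTable) {
    m <- as.matrix(measuresTable)
    if (nrow(m) < 3)
        stop("need at least 3 cohort pairs with all measures defined")
    k <- ncol(m)
    r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m),
                                                     colnames(m)))
    constant <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
    if (any(constant))
        warning("constant measure column(s): ",
                paste(colnames(m)[constant], collapse = ", "))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (constant[i] || constant[j]) next
        ok <- stats::complete.cases(m[, c(i, j)])
        if (sum(ok) < 3) next
        ct <- stats::cor.test(m[ok, i], m[ok, j])
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
    }
    isxRow <- if ("isx" %in% colnames(m)) r["isx", ] else NULL
    list(r = r, p = p, isxRow = isxRow)
}
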