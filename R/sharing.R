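#' f2 rare-variant sharing matrix
#'
#' For every variant whose pooled ALT allele count across all samples is
#' exactly 2, the cell of the unordered carrier pair is incremented; a
#' single homozygous carrier increments its own diagonal cell. The sum over
#' all cells (counting each off-diagonal pair once) therefore equals the
#' number of f2 variants.
#'
#' @param ge a [GenotypeExperiment-class] pooled over the
#'   minimum-sample-size sets of all populations.
#' @return list with the symmetric integer \code{matrix} (sample x sample),
#'   \code{class = "f2"} and \code{nVariants}.
#' @export
f2Sharing <- function(ge) {
    d <- dosages(ge)
    n <- ncol(d)
    ids <- colnames(d)
    if (is.null(ids)) ids <- as.character(colData(ge)$sample)
    pooled <- rowSums(d, na.rm = TRUE)
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    idx <- which(pooled == 2)
    for (v in idx) {
        carriers <- which(d[v, ] > 0)
        if (length(carriers) == 1) {
            m[carriers, carriers] <- m[carriers, carriers] + 1L
        } else {
            a <- carriers[1]; b <- carriers[2]
            m[a, b] <- m[a, b] + 1L
            m[b, a] <- m[b, a] + 1L
        }
    }
    list(matrix = m, class = "f2", nVariants = length(idx))
}

#' f3-10 rare-variant sharing matrix
#'
#' For every variant with pooled ALT allele count between 3 and 10, two of
#' its allele copies are drawn uniformly at random without replacement
#' (seeded) and the corresponding pair of carrier individuals is
#' incremented (the same individual twice increments the diagonal).
#'
#' @param ge pooled [GenotypeExperiment-class].
#' @param seed integer seed (recorded in the result).
#' @param range inclusive pooled-count range, default \code{c(3, 10)}.
#' @return list with \code{matrix}, \code{class = "f3_10"},
#'   \code{nVariants} and \code{seed}.
#' @export
f310Sharing <- function(ge, seed = 1, range = c(3, 10)) {
    d <- dosages(ge)
    n <- ncol(d)
    ids <- colnames(d)
    if (is.null(ids)) ids <- as.character(colData(ge)$sample)
    pooled <- rowSums(d, na.rm = TRUE)
    idx <- which(pooled >= range[1] & pooled <= range[2])
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    withSeed(seed, {
        for (v in idx) {
            row <- d[v, ]
            carriers <- which(!is.na(row) & row > 0)
            copies <- rep(carriers, row[carriers])
            pick <- sample(length(copies), 2)
            a <- copies[pick[1]]; b <- copies[pick[2]]
            if (a == b) {
                m[a, a] <- m[a, a] + 1L
            } else {
                m[a, b] <- m[a, b] + 1L
                m[b, a] <- m[b, a] + 1L
            }
        }
    })
    list(matrix = m, class = "f3_10", nVariants = length(idx), seed = seed)
}

#' Aggregate a sharing matrix by population
#'
#' Sums the individual-level sharing cells into population blocks. With
#' \code{normalise = TRUE} each block is divided by its number of
#' individual pairs.
#'
#' @param sharing result of [f2Sharing()] or [f310Sharing()].
#' @param populations named character vector mapping sample to population
#'   (e.g. [populationOf()]).
#' @param normalise divide block sums by the number of pairs per block.
#' @return population x population matrix.
#' @export
popAggregateSharing <- function(sharing, populations, normalise = FALSE) {
    m <- sharing$matrix
    pops <- populations[rownames(m)]
    labs <- unique(unname(pops))
    out <- matrix(0, length(labs), length(labs),
                  dimnames = list(labs, labs))
    npair <- out
    for (a in labs) for (b in labs) {
        ia <- which(pops == a)
        ib <- which(pops == b)
        block <- m[ia, ib, drop = FALSE]
        if (a == b) {
            tot <- (sum(block) - sum(diag(block))) / 2 + sum(diag(block))
            np <- length(ia) * (length(ia) + 1) / 2
        } else {
            tot <- sum(block)
            np <- length(ia) * length(ib)
        }
        out[a, b] <- tot
        npair[a, b] <- np
    }
    if (normalise) out <- out / npair
    out
}

#' Per-variant derived allele frequency difference (deltaDAF)
#'
#' Signed difference (isolate minus general) of derived allele frequencies,
#' one row per variant with a defined DAF in both populations; sort on
#' \code{delta} to rank the most differentiated variants.
#'
#' @param ft a [FrequencyTable-class].
#' @param pair a [CohortPair-class].
#' @return data.frame chrom, pos, ref, alt, dafIsolate, dafGeneral, delta.
#' @export
deltaDaf <- function(ft, pair) {
    stopIfNotPair(ft, pair)
    dx <- ft@daf[, pair@isolate]
    dy <- ft@daf[, pair@general]
    ok <- which(!is.na(dx) & !is.na(dy))
    out <- ft@variants[ok, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    out$dafIsolate <- dx[ok]
    out$dafGeneral <- dy[ok]
    out$delta <- dx[ok] - dy[ok]
    rownames(out) <- NULL
    out
}
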