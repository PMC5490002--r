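# Shared fixtures: a cache so expensive simulations are built once per run,
# a tiny hand-made GenotypeExperiment builder, and brute-force oracles.

.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, cfg) {
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateCohortPair(cfg)
    .simCache[[key]]
}

# small, fast configuration for unit tests (not the study-scale defaults)
tinyCfg <- function(...) {
    args <- list(neAncestral = 150, neGeneral = 150, neIsolate = 60,
                 tdgGens = 80, nSitesPerChrom = 1000, burninFactor = 6,
                 seed = 42)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(simConfig, args)
}

# hand-made GenotypeExperiment: dosage is variants x samples; ancestral
# defaults to the REF allele so DAF = ALT frequency
toyGe <- function(dosage, populations,
                  chrom = rep("chr1", nrow(dosage)),
                  pos = seq_len(nrow(dosage)) * 1000L,
                  consequence = rep("other", nrow(dosage)),
                  gene = rep(NA_character_, nrow(dosage)),
                  cadd = rep(NA_real_, nrow(dosage)),
                  ancestral = NULL) {
    dosage <- as.matrix(dosage)
    nv <- nrow(dosage)
    variants <- data.frame(
        chrom = chrom, pos = as.integer(pos),
        ref = rep("A", nv), alt = rep("G", nv),
        ancestral = if (is.null(ancestral)) rep("A", nv) else ancestral,
        gene = gene, consequence = consequence, cadd = cadd,
        stringsAsFactors = FALSE)
    samples <- data.frame(sample = sprintf("S%02d", seq_len(ncol(dosage))),
                          population = populations,
                          stringsAsFactors = FALSE)
    colnames(dosage) <- samples$sample
    GenotypeExperiment(dosage, variants, samples)
}

# exhaustive drifted-variant re-check (direction x)
bruteDriftedX <- function(dafX, dafY, band = c(0.02, 0.05), fold = 3) {
    which(!is.na(dafX) & !is.na(dafY) &
          dafX >= band[1] & dafX <= band[2] & dafX >= fold * dafY)
}

# brute-force f2 sharing matrix
bruteF2 <- function(dosage) {
    n <- ncol(dosage)
    m <- matrix(0L, n, n)
    for (v in seq_len(nrow(dosage))) {
        row <- dosage[v, ]
        if (sum(row, na.rm = TRUE) != 2) next
        carriers <- which(!is.na(row) & row > 0)
        if (length(carriers) == 1) {
            m[carriers, carriers] <- m[carriers, carriers] + 1L
        } else {
            m[carriers[1], carriers[2]] <- m[carriers[1], carriers[2]] + 1L
            m[carriers[2], carriers[1]] <- m[carriers[2], carriers[1]] + 1L
        }
    }
    m
}

# brute-force per-site Hudson FST terms
bruteHudson <- function(c1, n1, c2, n2) {
    p1 <- c1 / n1; p2 <- c2 / n2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
}

# brute-force ROH: enumerate every admissible segment, keep the maximal
# ones, trim ends to homozygous calls, apply the span filter
bruteRoh <- function(het, pos, win, maxHet, minLengthKb) {
    L <- length(het)
    admissible <- function(a, b) {
        len <- b - a + 1
        if (len < win) return(sum(het[a:b]) <= maxHet)
        starts <- a:(b - win + 1)
        all(vapply(starts, function(s) sum(het[s:(s + win - 1)]),
                   numeric(1)) <= maxHet)
    }
    segs <- list()
    for (a in seq_len(L)) for (b in a:L) {
        if (!admissible(a, b)) next
        if (a > 1 && admissible(a - 1, b)) next
        if (b < L && admissible(a, b + 1)) next
        segs[[length(segs) + 1]] <- c(a, b)
    }
    out <- list()
    for (s in segs) {
        a <- s[1]; b <- s[2]
        while (a <= b && het[a] == 1) a <- a + 1
        while (b >= a && het[b] == 1) b <- b - 1
        if (a > b) next
        if ((pos[b] - pos[a] + 1) / 1000 < minLengthKb) next
        out[[length(out) + 1]] <- c(startBp = pos[a], endBp = pos[b])
    }
    if (!length(out)) return(data.frame(startBp = integer(),
                                        endBp = integer()))
    unique(as.data.frame(do.call(rbind, out)))
}
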