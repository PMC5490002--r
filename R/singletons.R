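#' Find singleton variants in a population
#'
#' Singletons carry the ALT allele on exactly one chromosome of the
#' population's own sample (the minimum-sample-size set in the standard
#' workflow), regardless of their frequency elsewhere.
#'
#' @param ft a [FrequencyTable-class].
#' @param population population label.
#' @return integer vector of variant indices.
#' @export
findSingletons <- function(ft, population) {
    if (!population %in% colnames(ft@altCount))
        stop("population '", population, "' not in the frequency table")
    which(ft@altCount[, population] == 1L)
}

#' Per-gene missense and synonymous singleton counts for a cohort pair
#'
#' Counts missense and synonymous singletons per gene in each population of
#' the pair. The gene universe is restricted to genes with at least one
#' singleton (of either class) in at least one population of the pair.
#'
#' @param ft a [FrequencyTable-class] built on the minimum-sample-size data.
#' @param pair a [CohortPair-class].
#' @return data.frame with columns gene, misX, synX, misY, synY (X =
#'   isolate, Y = general).
#' @export
geneSingletonCounts <- function(ft, pair) {
    stopIfNotPair(ft, pair)
    vi <- ft@variants
    usable <- !is.na(vi$gene) & nzchar(vi$gene) &
        vi$consequence %in% c("missense", "synonymous")
    countPop <- function(pop) {
        idx <- intersect(findSingletons(ft, pop), which(usable))
        mis <- table(vi$gene[idx][vi$consequence[idx] == "missense"])
        syn <- table(vi$gene[idx][vi$consequence[idx] == "synonymous"])
        list(mis = mis, syn = syn)
    }
    cx <- countPop(pair@isolate)
    cy <- countPop(pair@general)
    genes <- sort(unique(c(names(cx$mis), names(cx$syn),
                           names(cy$mis), names(cy$syn))))
    grab <- function(tab, g) {
        v <- as.integer(tab[g])
        v[is.na(v)] <- 0L
        v
    }
    data.frame(gene = genes,
               misX = grab(cx$mis, genes), synX = grab(cx$syn, genes),
               misY = grab(cy$mis, genes), synY = grab(cy$syn, genes),
               stringsAsFactors = FALSE)
}

#' Per-gene singleton ratio SVgene
#'
#' Ratio of missense to synonymous singletons for a gene. A value above 1
#' indicates relaxation of purifying selection, 1 neutrality, below 1
#' purifying selection. Genes with missense singletons but no synonymous
#' singletons are classified \code{">1"} while their ratio is reported as
#' \code{NA} (so infinities never enter downstream averages); genes with no
#' singletons of either class must be excluded upstream.
#'
#' @param nMissense,nSynonymous non-negative integer vectors.
#' @return data.frame with columns ratio and class (\code{"<1"},
#'   \code{"=1"}, \code{">1"}).
#' @export
svGene <- function(nMissense, nSynonymous) {
    if (any(nMissense == 0 & nSynonymous == 0))
        stop("genes with no singletons of either class must be excluded")
    ratio <- ifelse(nSynonymous > 0, nMissense / nSynonymous, NA_real_)
    class <- ifelse(nSynonymous == 0 | nMissense > nSynonymous, ">1",
                    ifelse(nMissense == nSynonymous, "=1", "<1"))
    data.frame(ratio = ratio, class = class, stringsAsFactors = FALSE)
}

#' Pooled singleton ratio SVpop
#'
#' Sum of missense singletons over sum of synonymous singletons across the
#' shared gene universe of the pair (genes with at least one singleton in
#' either population).
#'
#' @param counts data.frame from [geneSingletonCounts()].
#' @return named numeric vector with elements \code{isolate} and
#'   \code{general}; \code{NA} (flagged by attribute \code{note}) when a
#'   synonymous sum is zero.
#' @export
svPop <- function(counts) {
    ratio1 <- function(mis, syn) {
        s <- sum(syn)
        if (s == 0) NA_real_ else sum(mis) / s
    }
    out <- c(isolate = ratio1(counts$misX, counts$synX),
             general = ratio1(counts$misY, counts$synY))
    if (anyNA(out))
        attr(out, "note") <- "undefined: zero synonymous singleton sum"
    out
}

#' Isolate-to-general ratio SVxy
#'
#' @param svPopIsolate,svPopGeneral pooled ratios from [svPop()].
#' @return their ratio; above 1 indicates relaxed purifying selection in
#'   the isolate. NA inputs propagate.
#' @export
svXy <- function(svPopIsolate, svPopGeneral) {
    if (is.na(svPopIsolate) || is.na(svPopGeneral)) return(NA_real_)
    svPopIsolate / svPopGeneral
}

#' Essential-gene relaxation statistic G_SV
#'
#' Percentage of essential genes with SVgene > 1 divided by the percentage
#' of non-essential genes with SVgene > 1, within the supplied gene
#' universe.
#'
#' @param genes character vector of gene symbols (the universe).
#' @param classes matching character vector of SVgene classes
#'   (\code{"<1"}, \code{"=1"}, \code{">1"}) from [svGene()].
#' @param essentialGenes character vector of essential gene symbols.
#' @return the ratio; \code{NA} when no non-essential gene is relaxed.
#' @export
gSv <- function(genes, classes, essentialGenes) {
    ess <- genes %in% essentialGenes
    if (!any(ess))
        stop("no essential gene present in the gene universe")
    if (all(ess))
        stop("no non-essential gene present in the gene universe")
    pEss <- mean(classes[ess] == ">1") * 100
    pNon <- mean(classes[!ess] == ">1") * 100
    if (pNon == 0) return(NA_real_)
    pEss / pNon
}

#' Gene-subsampling confidence interval
#'
#' Each replicate draws \code{floor(frac * G)} genes without replacement and
#' recomputes the statistic; the 2.5/97.5 percentiles of the replicates form
#' the interval. Deterministic given \code{seed}.
#'
#' @param statFn function taking a vector of gene names and returning a
#'   numeric scalar.
#' @param genes gene universe (>= 5 genes).
#' @param frac fraction per replicate (default 0.8).
#' @param reps replicates (default 100).
#' @param seed integer seed.
#' @return list with ciLow, ciHigh and replicate values.
#' @export
geneBootstrapCI <- function(statFn, genes, frac = 0.8, reps = 100, seed = 1) {
    genes <- unique(as.character(genes))
    if (length(genes) < 5)
        stop("need at least 5 genes for the gene bootstrap")
    k <- floor(frac * length(genes))
    vals <- withSeed(seed, vapply(seq_len(reps), function(i)
        statFn(sample(genes, k)), numeric(1)))
    list(ciLow = unname(stats::quantile(vals, 0.025, na.rm = TRUE)),
         ciHigh = unname(stats::quantile(vals, 0.975, na.rm = TRUE)),
         values = vals)
}

#' All singleton-based statistics for a cohort pair
#'
#' Computes the per-gene counts, SVpop for both populations, SVxy with a
#' gene-subsampling CI, and (when an essential-gene list is given) G_SV per
#' population.
#'
#' @param ft a [FrequencyTable-class] on the minimum-sample-size data.
#' @param pair a [CohortPair-class].
#' @param essentialGenes optional character vector.
#' @param reps,seed bootstrap parameters.
#' @return list with elements counts, svPop, svXy, ci, gSv.
#' @export
svStatistics <- function(ft, pair, essentialGenes = NULL, reps = 100,
                         seed = 1) {
    counts <- geneSingletonCounts(ft, pair)
    sp <- svPop(counts)
    sxy <- svXy(sp[["isolate"]], sp[["general"]])
    ci <- list(ciLow = NA_real_, ciHigh = NA_real_, values = numeric())
    if (reps > 0 && nrow(counts) >= 5) {
        statFn <- function(g) {
            sub <- counts[counts$gene %in% g, , drop = FALSE]
            spp <- svPop(sub)
            svXy(spp[["isolate"]], spp[["general"]])
        }
        ci <- geneBootstrapCI(statFn, counts$gene, reps = reps, seed = seed)
    }
    gsv <- c(isolate = NA_real_, general = NA_real_)
    if (!is.null(essentialGenes)) {
        clsFor <- function(mis, syn) {
            keep <- mis + syn > 0
            list(genes = counts$gene[keep],
                 class = svGene(mis[keep], syn[keep])$class)
        }
        gx <- clsFor(counts$misX, counts$synX)
        gy <- clsFor(counts$misY, counts$synY)
        gsv <- c(isolate = gSv(gx$genes, gx$class, essentialGenes),
                 general = gSv(gy$genes, gy$class, essentialGenes))
    }
    list(counts = counts, svPop = sp, svXy = sxy, ci = ci, gSv = gsv)
}
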