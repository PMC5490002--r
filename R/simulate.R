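#' Simulation configuration for an isolate/general cohort pair
#'
#' Defines a two-population split model: an ancestral Wright-Fisher
#' population of \code{neAncestral} diploids is burnt in for
#' \code{burninFactor * neAncestral} generations, splits into a general
#' population (\code{neGeneral}) and an isolate (\code{neIsolate}) that
#' exchange migrants at rate \code{mig} per generation for \code{tdgGens}
#' generations, after which \code{nSamples} diploids are drawn from each.
#' Sites live on a fixed grid (recurrent mutation, derived allele tracked),
#' genes tile \code{codingFraction} of each chromosome, and coding sites
#' are assigned missense/LoF/synonymous classes with per-class gamma
#' selection-coefficient distributions scaled by \code{selScale}
#' (\code{selScale = 0} gives a neutral genome with unchanged annotation).
#'
#' @param neAncestral,neGeneral,neIsolate diploid effective sizes.
#' @param tdgGens generations since the split.
#' @param mig symmetric per-generation migration fraction in [0, 0.5].
#' @param muSite per-site per-generation mutation rate on the grid.
#' @param cmPerMb constant recombination map (1 cM/Mb default, i.e. 1e-8
#'   per bp).
#' @param nChroms,chromLengthBp,nSitesPerChrom genome layout.
#' @param codingFraction fraction of each chromosome covered by genes.
#' @param geneLengthBp gene length.
#' @param classProps proportions of missense/lof/synonymous among coding
#'   sites.
#' @param selMissenseMean,selLofMean,selShape gamma severity distributions
#'   (|s|) for the deleterious classes.
#' @param selScale multiplies realized selection coefficients (0 = neutral
#'   null with annotation structure intact).
#' @param nSamples diploid sample size per population (default 36, the
#'   minimum-sample-size convention).
#' @param burninFactor burn-in length in units of neAncestral generations.
#' @param isolateLabel,generalLabel population labels.
#' @param seed integer seed governing every random draw.
#' @return a \code{SimConfig} (classed list).
#' @export
simConfig <- function(neAncestral = 300, neGeneral = 300, neIsolate = 60,
                      tdgGens = 200, mig = 0, muSite = 1.4e-4, cmPerMb = 1,
                      nChroms = 2, chromLengthBp = 5e6,
                      nSitesPerChrom = 3000, codingFraction = 0.4,
                      geneLengthBp = 25000,
                      classProps = c(missense = 0.65, lof = 0.05,
                                     synonymous = 0.30),
                      selMissenseMean = 0.03, selLofMean = 0.12,
                      selShape = 0.4, selScale = 1, nSamples = 36,
                      burninFactor = 8, isolateLabel = "ISO",
                      generalLabel = "GEN", seed = 1) {
    cfg <- list(neAncestral = neAncestral, neGeneral = neGeneral,
                neIsolate = neIsolate, tdgGens = tdgGens, mig = mig,
                muSite = muSite, cmPerMb = cmPerMb, nChroms = nChroms,
                chromLengthBp = chromLengthBp,
                nSitesPerChrom = nSitesPerChrom,
                codingFraction = codingFraction,
                geneLengthBp = geneLengthBp, classProps = classProps,
                selMissenseMean = selMissenseMean, selLofMean = selLofMean,
                selShape = selShape, selScale = selScale,
                nSamples = nSamples, burninFactor = burninFactor,
                isolateLabel = isolateLabel, generalLabel = generalLabel,
                seed = seed)
    validateSimConfig(cfg)
    structure(cfg, class = "SimConfig")
}

validateSimConfig <- function(cfg) {
    with(cfg, {
        stopifnot(neAncestral > 0, neGeneral > 0, neIsolate > 0,
                  tdgGens >= 0, mig >= 0, mig <= 0.5, muSite >= 0,
                  nChroms >= 1, chromLengthBp > 0, nSitesPerChrom > 1,
                  codingFraction >= 0, codingFraction < 1, selScale >= 0,
                  abs(sum(classProps) - 1) < 1e-8, nSamples > 0)
        if (nSamples > neGeneral || nSamples > neIsolate)
            stop("nSamples exceeds a population size (infeasible config)")
    })
    invisible(cfg)
}

#' Assign genes, consequence classes, severities and pseudo-CADD scores
#'
#' Sites inside gene intervals get missense/LoF/synonymous classes with the
#' configured proportions; sites outside are intergenic. Each deleterious
#' site receives a nominal severity |s| drawn from its class's gamma
#' distribution; the realized selection coefficient is \code{-selScale *
#' severity}. The pseudo-CADD score is a monotone noisy transform of the
#' nominal severity, \code{8 * log10(1 + severity / 1e-4) + noise}, clipped
#' to [0, 50]; neutral classes are centred in the 0-5 band. Because the
#' score follows nominal (annotated) rather than realized severity, a
#' neutral genome (\code{selScale = 0}) keeps a realistic score
#' distribution.
#'
#' @param pos integer positions (within one chromosome layout).
#' @param cfg a \code{SimConfig} (layout + selection fields used).
#' @param seed integer seed.
#' @return data.frame: gene, consequence, severity, s, cadd.
#' @export
assignAnnotations <- function(pos, cfg, seed = 1) {
    withSeed(seed, {
        nGenes <- max(1, floor(cfg$codingFraction * cfg$chromLengthBp /
                                   cfg$geneLengthBp))
        spacing <- cfg$chromLengthBp / nGenes
        starts <- round((seq_len(nGenes) - 1) * spacing +
                            (spacing - cfg$geneLengthBp) / 2)
        geneIdx <- findInterval(pos, starts)
        inGene <- geneIdx >= 1 &
            pos < starts[pmax(geneIdx, 1)] + cfg$geneLengthBp
        gene <- ifelse(inGene, sprintf("G%04d", geneIdx), NA_character_)
        consequence <- rep("intergenic", length(pos))
        nCoding <- sum(inGene)
        if (nCoding)
            consequence[inGene] <- sample(names(cfg$classProps), nCoding,
                                          replace = TRUE,
                                          prob = cfg$classProps)
        severity <- numeric(length(pos))
        mis <- consequence == "missense"
        lof <- consequence == "lof"
        if (any(mis))
            severity[mis] <- stats::rgamma(sum(mis), shape = cfg$selShape,
                                           scale = cfg$selMissenseMean /
                                               cfg$selShape)
        if (any(lof))
            severity[lof] <- stats::rgamma(sum(lof), shape = cfg$selShape,
                                           scale = cfg$selLofMean /
                                               cfg$selShape)
        cadd <- numeric(length(pos))
        del <- mis | lof
        cadd[del] <- 8 * log10(1 + severity[del] / 1e-4) +
            stats::rnorm(sum(del), 0, 2)
        cadd[!del] <- stats::rnorm(sum(!del), 2.5, 1.2)
        cadd <- pmin(pmax(cadd, 0), 50)
        data.frame(gene = gene, consequence = consequence,
                   severity = severity, s = -cfg$selScale * severity,
                   cadd = cadd, stringsAsFactors = FALSE)
    })
}

#' Simulate an isolate/general cohort pair with known ground truth
#'
#' Forward Wright-Fisher simulation (compiled core) of the two-population
#' split model described in [simConfig()], with recombination at the
#' configured map, recurrent mutation on the site grid, symmetric
#' migration after the split and multiplicative (genic, h = 0.5) selection
#' on deleterious sites. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{SimConfig}.
#' @return list with \code{ge} (a [GenotypeExperiment-class] with phased
#'   haplotype assays, restricted to sites segregating in the pooled
#'   sample), \code{truth} (a \code{SimTruth}: the config, per-site class,
#'   severity, realized s, pseudo-CADD, essential-gene list and the
#'   two-deme island-model FST expectation where migration is active) and
#'   \code{pair} (the [CohortPair-class]).
#' @export
simulateCohortPair <- function(cfg) {
    validateSimConfig(cfg)
    withSeed(cfg$seed, {
        chromLabels <- paste0("chr", seq_len(cfg$nChroms))
        pos <- lapply(seq_len(cfg$nChroms), function(i)
            sort(sample.int(cfg$chromLengthBp, cfg$nSitesPerChrom)))
        ann <- lapply(seq_len(cfg$nChroms), function(i) {
            a <- assignAnnotations(pos[[i]], cfg,
                                   seed = sample.int(2^30, 1))
            a$gene <- ifelse(is.na(a$gene), NA_character_,
                             paste0("c", i, a$gene))
            a
        })
        chromId <- rep(seq_len(cfg$nChroms), each = cfg$nSitesPerChrom)
        posAll <- unlist(pos)
        annAll <- do.call(rbind, ann)
        morgansPerBp <- cfg$cmPerMb / 100 / 1e6
        gpos <- (posAll + (chromId - 1) * cfg$chromLengthBp * 10) *
            morgansPerBp
        sim <- .wf_simulate(cfg$neAncestral, cfg$neGeneral, cfg$neIsolate,
                            as.integer(cfg$burninFactor * cfg$neAncestral),
                            as.integer(cfg$tdgGens), cfg$mig, cfg$muSite,
                            gpos, as.integer(chromId), annAll$s,
                            cfg$nSamples, cfg$nSamples)
        hapI <- sim$hap_isolate          # 2n x L, isolate first by convention
        hapG <- sim$hap_general
        derived <- colSums(hapI) + colSums(hapG)
        totalChroms <- nrow(hapI) + nrow(hapG)
        keep <- which(derived > 0 & derived < totalChroms)
        if (!length(keep)) stop("no segregating sites; increase muSite")
        hapI <- hapI[, keep, drop = FALSE]
        hapG <- hapG[, keep, drop = FALSE]

        bases <- c("A", "C", "G", "T")
        ancBase <- sample(bases, length(keep), replace = TRUE)
        derBase <- vapply(ancBase, function(b)
            sample(setdiff(bases, b), 1), character(1))
        ancIsRef <- stats::runif(length(keep)) < 0.7

        asDiploid <- function(hap) {
            n <- nrow(hap) / 2
            A <- hap[2 * seq_len(n) - 1, , drop = FALSE]
            B <- hap[2 * seq_len(n), , drop = FALSE]
            list(A = t(A), B = t(B))                  # variants x samples
        }
        hi <- asDiploid(hapI)
        hg <- asDiploid(hapG)
        hapA <- cbind(hi$A, hg$A)
        hapB <- cbind(hi$B, hg$B)
        flip <- !ancIsRef
        hapA[flip, ] <- 1L - hapA[flip, ]
        hapB[flip, ] <- 1L - hapB[flip, ]
        dosage <- hapA + hapB

        nI <- ncol(hi$A); nG <- ncol(hg$A)
        samples <- data.frame(
            sample = c(sprintf("%s_%03d", cfg$isolateLabel, seq_len(nI)),
                       sprintf("%s_%03d", cfg$generalLabel, seq_len(nG))),
            population = c(rep(cfg$isolateLabel, nI),
                           rep(cfg$generalLabel, nG)),
            stringsAsFactors = FALSE)
        variants <- data.frame(
            chrom = chromLabels[chromId[keep]],
            pos = posAll[keep],
            ref = ifelse(ancIsRef, ancBase, derBase),
            alt = ifelse(ancIsRef, derBase, ancBase),
            ancestral = ancBase,
            gene = annAll$gene[keep],
            consequence = annAll$consequence[keep],
            cadd = annAll$cadd[keep],
            stringsAsFactors = FALSE)
        colnames(dosage) <- samples$sample
        colnames(hapA) <- colnames(hapB) <- samples$sample
        ge <- GenotypeExperiment(dosage, variants, samples,
                                 hapA = hapA, hapB = hapB)

        genes <- sort(unique(stats::na.omit(annAll$gene[keep])))
        essential <- sort(sample(genes, max(1, round(0.3 * length(genes)))))
        truth <- structure(list(
            cfg = cfg,
            class = annAll$consequence[keep],
            severity = annAll$severity[keep],
            s = annAll$s[keep],
            cadd = annAll$cadd[keep],
            ancIsRef = ancIsRef,
            essentialGenes = essential,
            expectedFstIsland = if (cfg$mig > 0)
                1 / (1 + 8 * cfg$neGeneral * cfg$mig) else NA_real_),
            class = "SimTruth")
        list(ge = ge, truth = truth,
             pair = cohortPair(cfg$isolateLabel, cfg$generalLabel))
    })
}

#' Write all pipeline input files for a simulated cohort pair
#'
#' Writes a VCF 4.2 file (phased GT, AA INFO tag), the annotation TSV, the
#' sample map, the essential-gene list, a truth ancestry Q matrix with its
#' sample-order file, and a manifest JSON recording the configuration and
#' seed. Output is byte-stable for a given simulation.
#'
#' @param sim result of [simulateCohortPair()].
#' @param outdir output directory (created if absent).
#' @return invisible named vector of file paths.
#' @export
writeInputs <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ge <- sim$ge
    vi <- variantInfo(ge)
    hp <- haplotypes(ge)
    samples <- as.character(colData(ge)$sample)

    vcfPath <- file.path(outdir, "cohort_pair.vcf")
    header <- c("##fileformat=VCFv4.2",
                "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
    gt <- matrix(paste0(hp$hapA, "|", hp$hapB), nrow = nrow(vi))
    rows <- vapply(seq_len(nrow(vi)), function(v)
        paste(c(vi$chrom[v], vi$pos[v], ".", vi$ref[v], vi$alt[v], ".",
                "PASS", paste0("AA=", vi$ancestral[v]), "GT",
                gt[v, ]), collapse = "\t"), character(1))
    writeLines(c(header, rows), vcfPath)

    annPath <- file.path(outdir, "annotation.tsv")
    ann <- vi[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                  "cadd")]
    ann$cadd <- round(ann$cadd, 3)
    utils::write.table(ann, annPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    mapPath <- file.path(outdir, "sample_map.tsv")
    utils::write.table(
        data.frame(sample_id = samples,
                   population = as.character(colData(ge)$population)),
        mapPath, sep = "\t", quote = FALSE, row.names = FALSE)

    essPath <- file.path(outdir, "essential_genes.txt")
    writeLines(sim$truth$essentialGenes, essPath)

    qPath <- file.path(outdir, "truth_ancestry.Q")
    famPath <- file.path(outdir, "truth_ancestry.samples")
    isIso <- as.character(colData(ge)$population) ==
        isolateLabel(sim$pair)
    q <- cbind(ifelse(isIso, 1, 0), ifelse(isIso, 0, 1))
    utils::write.table(q, qPath, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(samples, famPath)

    manifestPath <- file.path(outdir, "manifest.json")
    cfg <- sim$truth$cfg
    jsonlite::write_json(
        list(config = unclass(cfg), seed = cfg$seed,
             nVariants = nrow(vi), nSamples = length(samples)),
        manifestPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(c(vcf = vcfPath, annotation = annPath, sampleMap = mapPath,
                essentialGenes = essPath, qMatrix = qPath,
                qSamples = famPath, manifest = manifestPath))
}

#' Simulate a panel of cohort pairs along an isolation gradient
#'
#' Generates \code{nCohorts} configurations whose split time increases,
#' isolate size decreases and migration rate decreases monotonically from
#' the weakest to the strongest isolation, then simulates each.
#'
#' @param baseCfg template \code{SimConfig}.
#' @param nCohorts number of cohorts (>= 3).
#' @param tdgRange,neIsolateRange,migRange gradient endpoints (weakest to
#'   strongest isolation).
#' @param seed integer master seed; cohort i uses \code{seed + i}.
#' @param simulate when FALSE only the configurations are returned.
#' @return list of cohorts, each with \code{cfg} and (when simulated)
#'   \code{ge}, \code{truth}, \code{pair}.
#' @export
makeCohortPanel <- function(baseCfg = simConfig(), nCohorts = 8,
                            tdgRange = c(60, 400),
                            neIsolateRange = c(240, 72),
                            migRange = c(0.02, 0), seed = 1,
                            simulate = TRUE) {
    if (nCohorts < 3) stop("a panel needs at least 3 cohorts")
    grad <- seq(0, 1, length.out = nCohorts)
    lapply(seq_len(nCohorts), function(i) {
        g <- grad[i]
        cfg <- baseCfg
        cfg$tdgGens <- round(tdgRange[1] + g * diff(tdgRange))
        cfg$neIsolate <- round(neIsolateRange[1] + g * diff(neIsolateRange))
        cfg$mig <- migRange[1] + g * diff(migRange)
        cfg$isolateLabel <- sprintf("ISO%02d", i)
        cfg$seed <- seed + i
        cfg <- do.call(simConfig, unclass(cfg))
        out <- list(cfg = cfg, gradientIndex = i)
        if (simulate) out <- c(out, simulateCohortPair(cfg))
        out
    })
}

#' Simulate admixed genotypes under a two-source model
#'
#' Source allele frequencies follow a Balding-Nichols drift model around a
#' shared ancestral frequency (differentiation \code{fst}); individual i
#' draws dosage ~ Binomial(2, q_i f1 + (1 - q_i) f2).
#'
#' @param q true ancestry proportions, one per individual.
#' @param nSites number of sites.
#' @param fst source differentiation (default 0.1).
#' @param seed integer seed.
#' @return list with \code{dosage} (sites x individuals), \code{q},
#'   \code{f1}, \code{f2}.
#' @export
simulateAdmixedGenotypes <- function(q, nSites = 2000, fst = 0.1, seed = 1) {
    withSeed(seed, {
        pAnc <- stats::runif(nSites, 0.05, 0.95)
        a <- pAnc * (1 - fst) / fst
        b <- (1 - pAnc) * (1 - fst) / fst
        f1 <- stats::rbeta(nSites, a, b)
        f2 <- stats::rbeta(nSites, a, b)
        P <- outer(f1, q) * 0 # shape sites x individuals
        for (i in seq_along(q))
            P[, i] <- q[i] * f1 + (1 - q[i]) * f2
        dosage <- matrix(stats::rbinom(length(P), 2, P), nrow = nSites)
        colnames(dosage) <- sprintf("IND_%03d", seq_along(q))
        list(dosage = dosage, q = q, f1 = f1, f2 = f2)
    })
}
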