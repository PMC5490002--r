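#' Run the full per-pair analysis
#'
#' Orchestrates the standard workflow for one isolate/general pair:
#' subsampling to the minimum-sample-size set (DVxy, SVxy, sharing, FST,
#' Ne/Tdg) and the matched set (Rxy, deltaDAF), then every toggled
#' statistic. Deterministic given \code{seed}.
#'
#' @param ge a [GenotypeExperiment-class] containing both populations.
#' @param pair a [CohortPair-class].
#' @param statistics character subset of \code{c("dvxy", "svxy", "rxy",
#'   "sharing", "popgen", "demography")}.
#' @param essentialGenes optional character vector for G_SV.
#' @param nMin minimum-sample-size per population (default 36).
#' @param nChromsCI chromosomes per DVxy resampling replicate
#'   (\code{NULL} = skip when fewer chromosomes are available).
#' @param reps resampling replicates for every CI (default 100).
#' @param seed integer seed.
#' @param ldParams list overriding [neFromLd()] arguments.
#' @return a [CohortPairResult-class].
#' @export
runPair <- function(ge, pair,
                    statistics = c("dvxy", "svxy", "rxy", "sharing",
                                   "popgen", "demography"),
                    essentialGenes = NULL, nMin = 36, nChromsCI = NULL,
                    reps = 100, seed = 1, ldParams = list()) {
    statistics <- match.arg(statistics, several.ok = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "': ", conditionMessage(e),
                 call. = FALSE))
    }
    geMin <- stage("subsample-minimum",
                   subsampleCohorts(ge, "minimum", n = nMin, seed = seed))
    geMatched <- stage("subsample-matched",
                       subsampleCohorts(ge, "matched", pair = pair,
                                        seed = seed))
    ftMin <- stage("frequencies",
                   alleleFrequencies(geMin, c(pair@isolate, pair@general)))
    ftMatched <- stage("frequencies",
                       alleleFrequencies(geMatched,
                                         c(pair@isolate, pair@general)))
    measures <- c()
    tables <- list()

    if ("dvxy" %in% statistics) {
        dvt <- stage("dvxy", dvxyStatistics(ftMin, pair,
                                            nChroms = nChromsCI,
                                            reps = reps, seed = seed))
        tables$dvxy <- dvt
        measures["dvxyCoding"] <- dvt$estimate[dvt$stratum == "coding"]
        top <- grep("cadd>=", dvt$stratum)
        measures["dvxyWgTop"] <- if (length(top)) dvt$estimate[top] else NA
    }
    if ("svxy" %in% statistics) {
        sv <- stage("svxy", svStatistics(ftMin, pair,
                                         essentialGenes = essentialGenes,
                                         reps = reps, seed = seed))
        tables$svxy <- data.frame(
            svPopIsolate = sv$svPop[["isolate"]],
            svPopGeneral = sv$svPop[["general"]],
            svXy = sv$svXy, ciLow = sv$ci$ciLow, ciHigh = sv$ci$ciHigh,
            gSvIsolate = sv$gSv[["isolate"]],
            gSvGeneral = sv$gSv[["general"]])
        measures["svXy"] <- sv$svXy
    }
    if ("rxy" %in% statistics) {
        rx <- stage("rxy", rxyBootstrap(ftMatched, pair,
                                        classes = c("missense",
                                                    "missense+lof"),
                                        reps = reps, seed = seed))
        tables$rxy <- rx
        measures["rxyMissense"] <- rx$estimate[rx$class == "missense"]
        tables$deltaDaf <- stage("deltadaf",
                                 utils::head(
                                     deltaDaf(ftMatched, pair)[
                                         order(-abs(deltaDaf(ftMatched,
                                                             pair)$delta)), ],
                                     100))
    }
    if ("sharing" %in% statistics) {
        f2 <- stage("sharing", f2Sharing(geMin))
        tables$f2ByPop <- popAggregateSharing(f2, populationOf(geMin))
        measures["f2WithinIsolate"] <-
            tables$f2ByPop[pair@isolate, pair@isolate]
        measures["f2Between"] <- tables$f2ByPop[pair@isolate, pair@general]
    }
    if ("popgen" %in% statistics) {
        fst <- stage("fst", hudsonFst(ftMin, pair))
        measures["fst"] <- fst$fst
        fh <- stage("inbreeding", inbreedingF(geMin, pair@isolate))
        measures["meanF"] <- fh$meanF
        roh <- stage("roh", rohScan(geMin, pair@isolate))
        measures["rohTotalMb"] <- mean(roh$summary$totalMb)
        ld <- stage("ld-decay", ldDecayLength(geMin, pair@isolate))
        measures["ldDecayKb"] <- ld$decayKb
        tables$roh <- roh$summary
        tables$ldProfile <- ld$profile
    }
    if ("demography" %in% statistics) {
        trajI <- stage("ne-ld", do.call(neFromLd,
                                        c(list(geMin, pair@isolate),
                                          ldParams)))
        trajG <- stage("ne-ld", do.call(neFromLd,
                                        c(list(geMin, pair@general),
                                          ldParams)))
        tables$neTrajectory <- rbind(
            cbind(population = pair@isolate, trajI),
            cbind(population = pair@general, trajG))
        fstMin <- stage("fst", hudsonFst(ftMin, pair))$fst
        td <- stage("tdg", estimateTdg(trajI, trajG, fst = fstMin))
        measures["tdg"] <- td$tdg
        measures["neRecent"] <- recentNe(trajI)
        em <- stage("admixture",
                    admixtureEmK2(ge[, c(popColumns(ge, pair@isolate),
                                         popColumns(ge, pair@general))],
                                  seed = seed))
        pops <- populationOf(ge)[c(popColumns(ge, pair@isolate),
                                   popColumns(ge, pair@general))]
        measures["deltaAncestry"] <- stage("delta-ancestry",
                                           deltaAncestry(em$Q, pops, pair))
        measures["isx"] <- isx(measures[["tdg"]], measures[["neRecent"]],
                               measures[["deltaAncestry"]])
    }
    new("CohortPairResult", pair = pair, measures = measures,
        tables = tables,
        metadata = list(seed = seed, nMin = nMin, statistics = statistics,
                        reps = reps))
}

#' Run a panel of cohort pairs and correlate the measures
#'
#' @param panel list of simulated cohorts from [makeCohortPanel()] (each
#'   with \code{ge}, \code{pair}, \code{truth}) or a list of
#'   \code{list(ge =, pair =)} entries.
#' @param ... passed to [runPair()].
#' @return list with per-pair \code{results}, the \code{measures}
#'   data.frame, \code{correlations} from [correlateMeasures()] and a
#'   one-line-per-measure \code{summary} of the Isx correlations.
#' @export
runPanel <- function(panel, ...) {
    if (length(panel) < 3)
        stop("a panel needs at least 3 cohort pairs")
    results <- lapply(panel, function(ch) {
        runPair(ch$ge, ch$pair,
                essentialGenes = ch$truth$essentialGenes, ...)
    })
    keep <- c("dvxyCoding", "svXy", "rxyMissense", "fst", "meanF",
              "rohTotalMb", "ldDecayKb", "tdg", "neRecent",
              "deltaAncestry", "isx")
    measures <- do.call(rbind, lapply(results, function(r) {
        m <- measures(r)
        out <- stats::setNames(rep(NA_real_, length(keep)), keep)
        out[intersect(names(m), keep)] <- m[intersect(names(m), keep)]
        as.data.frame(as.list(out))
    }))
    rownames(measures) <- make.unique(vapply(results, function(r)
        isolateLabel(r@pair), character(1)))
    use <- colnames(measures)[colSums(!is.na(measures)) >= 3]
    correlations <- correlateMeasures(measures[, use, drop = FALSE])
    summaryTxt <- if (!is.null(correlations$isxRow)) {
        rr <- correlations$isxRow
        pp <- correlations$p["isx", ]
        vapply(setdiff(names(rr), "isx"), function(nm)
            sprintf("Isx vs %-12s r = %6.3f  p = %.3g", nm, rr[[nm]],
                    pp[[nm]]), character(1))
    } else character()
    list(results = results, measures = measures,
         correlations = correlations, summary = summaryTxt)
}

#' Write the per-pair output tables
#'
#' Writes each detail table of a [CohortPairResult-class] as a TSV plus a
#' measures TSV; deterministic content for a given result.
#'
#' @param result a [CohortPairResult-class].
#' @param outdir output directory.
#' @return invisible vector of file paths.
#' @export
writePairOutputs <- function(result, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    m <- data.frame(measure = names(measures(result)),
                    value = unname(measures(result)))
    p <- file.path(outdir, "measures.tsv")
    utils::write.table(m, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    for (nm in names(result@tables)) {
        tab <- result@tables[[nm]]
        if (is.matrix(tab)) tab <- as.data.frame(tab)
        p <- file.path(outdir, paste0(nm, ".tsv"))
        utils::write.table(tab, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}
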