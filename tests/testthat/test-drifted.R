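# helper: frequency table with prescribed DAFs (ancestral = ref, one
# diploid per column scaled to give exact frequencies is impractical, so
# build the FrequencyTable directly through a dosage matrix of 50 diploids)
ftFromDaf <- function(dafX, dafY, consequence = NULL, cadd = NULL,
                      chrom = NULL) {
    n <- 500
    dX <- t(vapply(dafX, function(p) {
        k <- round(p * 2 * n)
        c(rep(1L, k), rep(0L, n - k))[seq_len(n)]
    }, integer(n)))
    dY <- t(vapply(dafY, function(p) {
        k <- round(p * 2 * n)
        c(rep(1L, k), rep(0L, n - k))[seq_len(n)]
    }, integer(n)))
    nv <- length(dafX)
    ge <- toyGe(cbind(dX, dY), populations = c(rep("X", n), rep("Y", n)),
                chrom = if (is.null(chrom)) rep("chr1", nv) else chrom,
                pos = seq_len(nv) * 1000L,
                consequence = if (is.null(consequence))
                    rep("other", nv) else consequence,
                cadd = if (is.null(cadd)) rep(NA_real_, nv) else cadd)
    alleleFrequencies(ge)
}

test_that("the drifted-variant rule follows band and fold thresholds", {
    ft <- ftFromDaf(c(0.03, 0.03, 0.06, 0.03),
                    c(0.00, 0.011, 0.01, 0.01))
    pair <- cohortPair("X", "Y")
    dv <- findDriftedVariants(ft, pair)
    expect_true(1 %in% dv@dirX)        # 0.03 vs 0: absence is extreme drift
    expect_false(2 %in% dv@dirX)       # fold 0.03/0.011 = 2.7 < 3
    expect_true(4 %in% dv@dirX)        # boundary: 0.03 >= 3 * 0.01 holds
    expect_false(3 %in% dv@dirX)       # 0.06 outside the 2-5% band
})

test_that("fold comparisons just under the threshold are rejected", {
    # daf_y = 0.011 -> 3 * 0.011 = 0.033 > 0.03
    ft <- ftFromDaf(0.03, 0.011)
    dv <- findDriftedVariants(ft, cohortPair("X", "Y"))
    expect_length(dv@dirX, 0)
})

test_that("drifted-variant calls match an exhaustive re-check on simulation", {
    sim <- cachedSim("tiny", tinyCfg())
    ft <- alleleFrequencies(subsampleCohorts(sim$ge, "minimum", seed = 1))
    dv <- findDriftedVariants(ft, sim$pair)
    bx <- bruteDriftedX(derivedFreqs(ft)[, "ISO"], derivedFreqs(ft)[, "GEN"])
    by <- bruteDriftedX(derivedFreqs(ft)[, "GEN"], derivedFreqs(ft)[, "ISO"])
    expect_identical(dv@dirX, as.integer(bx))
    expect_identical(dv@dirY, as.integer(by))
})

test_that("DVxy-coding reduces to the ratio-of-fractions arithmetic", {
    dv <- new("DriftedVariantSet", pair = cohortPair("X", "Y"),
              dirX = 1:330, dirY = 331:750,
              dafX = numeric(750), dafY = numeric(750),
              band = c(0.02, 0.05), fold = 3)
    variants <- data.frame(consequence = c(rep("missense", 30),
                                           rep("intergenic", 300),
                                           rep("missense", 20),
                                           rep("intergenic", 400)))
    res <- dvxyCoding(dv, variants)
    expect_equal(res$estimate, 2.0)        # (30/300) / (20/400)
    expect_equal(res$nFuncX, 30)
    expect_equal(res$nNeutY, 400)
})

test_that("symmetric counts give DVxy = 1 and zero denominators give NA", {
    dv <- new("DriftedVariantSet", pair = cohortPair("X", "Y"),
              dirX = 1:110, dirY = 111:220,
              dafX = numeric(220), dafY = numeric(220),
              band = c(0.02, 0.05), fold = 3)
    sym <- data.frame(consequence = rep(c(rep("missense", 10),
                                          rep("intergenic", 100)), 2))
    expect_equal(dvxyCoding(dv, sym)$estimate, 1.0)
    broken <- sym
    broken$consequence[111:220] <- "missense"   # no intergenic DV in y
    res <- dvxyCoding(dv, broken)
    expect_true(is.na(res$estimate))
    expect_match(res$note, "nNeutY")
})

test_that("DVxy-wg stratifies by CADD with the lowest bin as reference", {
    dv <- new("DriftedVariantSet", pair = cohortPair("X", "Y"),
              dirX = 1:165, dirY = 166:375,
              dafX = numeric(375), dafY = numeric(375),
              band = c(0.02, 0.05), fold = 3)
    cadd <- c(rep(2, 150), rep(25, 15),      # x: 150 neutral, 15 high
              rep(2, 200), rep(25, 10))      # y: 200 neutral, 10 high
    variants <- data.frame(consequence = "other", cadd = cadd)
    res <- dvxyWg(dv, variants)
    expect_equal(res$estimate[res$stratum == "cadd>=20"], 2.0)
    expect_true(all(is.na(res$estimate[res$stratum %in%
                                       c("cadd[5,10)", "cadd[10,20)")])))
})

test_that("swapping the populations inverts DVxy exactly, per stratum", {
    sim <- cachedSim("tinySel", tinyCfg(seed = 43))
    ft <- alleleFrequencies(subsampleCohorts(sim$ge, "minimum", seed = 1))
    fwd <- dvxyStatistics(ft, sim$pair, nChroms = NULL)
    rev <- dvxyStatistics(ft, cohortPair("GEN", "ISO"), nChroms = NULL)
    ok <- !is.na(fwd$estimate) & !is.na(rev$estimate)
    expect_true(any(ok))
    expect_equal(fwd$estimate[ok], 1 / rev$estimate[ok])
})

test_that("chromosome resampling is deterministic and degenerate-safe", {
    statConst <- function(chroms) 1.5
    ci <- chromosomeResampleCI(statConst, paste0("chr", 1:25),
                               nChroms = 20, reps = 50, seed = 3)
    expect_equal(unname(ci$ciLow), 1.5)
    expect_equal(unname(ci$ciHigh), 1.5)
    counter <- function(chroms) sum(as.integer(sub("chr", "", chroms)))
    a <- chromosomeResampleCI(counter, paste0("chr", 1:25), 20, 40, seed = 9)
    b <- chromosomeResampleCI(counter, paste0("chr", 1:25), 20, 40, seed = 9)
    expect_identical(a$values, b$values)
    expect_error(chromosomeResampleCI(statConst, paste0("chr", 1:10),
                                      nChroms = 20),
                 "nChroms <= 10")
})

test_that("common-in-isolate/rare-in-general applies the printed thresholds", {
    # counts: isolate then general
    d <- rbind(c(4, 1), c(4, 2), c(3, 0), c(10, 0))
    # expand into dosage over 36 + 36 diploids
    mk <- function(k, n = 36) c(rep(1L, k), rep(0L, n - k))
    dos <- t(apply(d, 1, function(r) c(mk(r[1]), mk(r[2]))))
    ge <- toyGe(dos, populations = c(rep("ISO", 36), rep("GEN", 36)))
    ft <- alleleFrequencies(ge)
    hits <- commonInIsolateRareInGeneral(ft, cohortPair("ISO", "GEN"))
    expect_equal(hits$countIsolate, c(4, 10))
    expect_equal(hits$countGeneral, c(1, 0))
    # MAF restatement of the thresholds
    expect_equal(countToMaf(min(hits$countIsolate), 36), 5.6)
    flagged <- commonInIsolateRareInGeneral(ft, cohortPair("ISO", "GEN"),
                                            allGenerals = "GEN")
    expect_true(all(flagged$novelStyle))
})
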