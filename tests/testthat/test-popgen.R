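test_that("Hudson FST matches per-site brute force on a toy table", {
    d <- rbind(c(1, 2, 0, 1, 0, 0),
               c(2, 2, 1, 0, 0, 1),
               c(0, 1, 1, 2, 2, 1))
    ge <- toyGe(d, populations = c(rep("A", 3), rep("B", 3)))
    ft <- alleleFrequencies(ge)
    res <- hudsonFst(ft, cohortPair("A", "B"))
    brute <- bruteHudson(rowSums(d[, 1:3]), rep(6, 3),
                         rowSums(d[, 4:6]), rep(6, 3))
    expect_equal(res$fst, brute)
})

test_that("FST hits its boundary cases", {
    dFix <- rbind(rep(c(2L, 0L), each = 10))
    ge <- toyGe(dFix, populations = rep(c("A", "B"), each = 10))
    expect_equal(hudsonFst(alleleFrequencies(ge), cohortPair("A", "B"))$fst,
                 1.0)
    # equal frequencies in large samples: estimator centred at ~0
    set.seed(3)
    dEq <- matrix(rbinom(200 * 100, 2, 0.5), nrow = 200)
    geEq <- toyGe(dEq, populations = rep(c("A", "B"), each = 50))
    expect_lt(abs(hudsonFst(alleleFrequencies(geEq),
                            cohortPair("A", "B"))$fst), 0.01)
    mono <- toyGe(rbind(rep(0L, 4)), populations = c("A", "A", "B", "B"))
    expect_true(is.na(hudsonFst(alleleFrequencies(mono),
                                cohortPair("A", "B"))$fst))
})

test_that("Weir-Cockerham flag stays close to Hudson on balanced samples", {
    sim <- cachedSim("tiny", tinyCfg())
    ft <- alleleFrequencies(subsampleCohorts(sim$ge, "minimum", seed = 6))
    h <- hudsonFst(ft, sim$pair)$fst
    w <- hudsonFst(ft, sim$pair, estimator = "wc")$fst
    expect_lt(abs(h - w), 0.1)
})

test_that("inbreeding F recovers Hardy-Weinberg and homozygous extremes", {
    set.seed(7)
    d <- matrix(rbinom(300 * 40, 2, 0.5), nrow = 300)
    d[, 40] <- ifelse(d[, 40] > 0, 2L, 0L)   # fully homozygous individual
    ge <- toyGe(d, populations = rep("P", 40))
    res <- inbreedingF(ge, "P")
    expect_lt(abs(mean(res$F[1:39])), 0.05)
    expect_equal(unname(res$F[40]), 1.0)
    tiny <- toyGe(matrix(1L, 10, 40), populations = rep("P", 40))
    expect_error(inbreedingF(tiny, "P"), "at least 50")
})

test_that("ROH scan equals exhaustive enumeration on a 200-site toy", {
    set.seed(21)
    for (rep in 1:3) {
        het <- as.integer(runif(200) < 0.08)
        pos <- sort(sample.int(5e6, 200))
        dos <- ifelse(het == 1, 1L, 0L)
        ge <- toyGe(matrix(dos, ncol = 1), populations = "P", pos = pos)
        scan <- rohScan(ge, "P", minLengthKb = 100, windowSites = 20,
                        maxHetPerWindow = 1)
        brute <- bruteRoh(het, pos, win = 20, maxHet = 1, minLengthKb = 100)
        expect_equal(nrow(scan$segments), nrow(brute))
        if (nrow(brute)) {
            expect_equal(scan$segments$startBp, brute$startBp)
            expect_equal(scan$segments$endBp, brute$endBp)
        }
    }
})

test_that("ROH degenerate patterns behave as defined", {
    pos <- seq(1, 5e6, length.out = 200)
    allHom <- toyGe(matrix(0L, 200, 1), populations = "P", pos = pos)
    res <- rohScan(allHom, "P", minLengthKb = 1000)
    expect_equal(nrow(res$segments), 1L)
    expect_gt(res$segments$lengthBp / 1e6, 4.9)
    altHet <- toyGe(matrix(rep(c(1L, 0L), 100), ncol = 1),
                    populations = "P", pos = pos)
    expect_equal(nrow(rohScan(altHet, "P", minLengthKb = 1000)$segments), 0L)
})

test_that("r-squared is 1 for perfectly linked sites and low for unlinked", {
    set.seed(9)
    h <- rbinom(60, 1, 0.5)
    ge <- toyGe(rbind(h * 1L + h, h + h, rbinom(60, 2, 0.5)),
                populations = rep("P", 60),
                pos = c(1000L, 2000L, 3000L))
    pr <- pairwiseR2(ge, "P", maxDistBp = 10000)
    expect_equal(pr$r2[pr$i == 1 & pr$j == 2], 1.0)
    expect_lt(pr$r2[pr$i == 1 & pr$j == 3], 0.2)
})

test_that("LD decay length reports the first bin under the threshold", {
    sim <- cachedSim("tiny", tinyCfg())
    geMin <- subsampleCohorts(sim$ge, "minimum", seed = 7)
    ld <- ldDecayLength(geMin, "GEN", r2Threshold = 0.25,
                        binsKb = seq(0, 500, 50))
    expect_true(ld$decayKb %in% (seq(0, 450, 50) + 25))
    expect_true(all(diff(ld$profile$midKb) > 0))
    # threshold no bin reaches -> flagged at the largest bin
    ld2 <- ldDecayLength(geMin, "ISO", r2Threshold = 1e-6,
                         binsKb = seq(0, 500, 50))
    expect_true(ld2$flagged)
    expect_equal(ld2$decayKb, 475)
})

test_that("drift measures rise together as the isolate Ne shrinks", {
    fsts <- rohs <- lds <- numeric(3)
    nes <- c(140, 70, 40)
    for (i in seq_along(nes)) {
        sim <- cachedSim(paste0("grad", nes[i]),
                         tinyCfg(neIsolate = nes[i], tdgGens = 100,
                                 seed = 50 + i))
        geMin <- subsampleCohorts(sim$ge, "minimum", seed = 1)
        ft <- alleleFrequencies(geMin)
        fsts[i] <- hudsonFst(ft, sim$pair)$fst
        rohs[i] <- mean(rohScan(geMin, "ISO", minLengthKb = 250,
                                windowSites = 25)$summary$totalMb)
        lds[i] <- ldDecayLength(geMin, "ISO", r2Threshold = 0.25,
                                binsKb = seq(0, 1000, 50))$decayKb
    }
    expect_true(all(diff(fsts) > 0))
    expect_true(all(diff(rohs) >= 0))
    expect_true(all(diff(lds) >= 0))
})
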