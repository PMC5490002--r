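test_that("the LD-to-Ne inversion follows its closed form", {
    # c = 0.0025 M, adjusted r2 = 0.1 -> Ne = 100 * (10 - 2) = 800,
    # indexing t = 1 / (2c) = 200 generations
    expect_equal(neFromAdjustedR2(0.1, 0.0025), 800)
    expect_equal(1 / (2 * 0.0025), 200)
    # r2adj at or beyond 0.5 has no positive solution -> dropped
    expect_true(is.na(neFromAdjustedR2(0.5, 0.005)))
    expect_true(is.na(neFromAdjustedR2(-0.01, 0.005)))
})

test_that("Ne trajectories come back on scale for a constant-size population", {
    sim <- cachedSim("const", tinyCfg(neIsolate = 150, tdgGens = 0,
                                      selScale = 0, seed = 61))
    traj <- neFromLd(sim$ge, "GEN")
    expect_true(all(traj$ne > 0))
    expect_true(all(traj$ciLow <= traj$ne & traj$ne <= traj$ciHigh))
    recent <- recentNe(traj, maxT = 300)
    expect_gt(recent, 150 / 2.5)
    expect_lt(recent, 150 * 2.5)
})

test_that("trajectory bins sort by time and drop uninformative distances", {
    sim <- cachedSim("const", tinyCfg(neIsolate = 150, tdgGens = 0,
                                      selScale = 0, seed = 61))
    traj <- neFromLd(sim$ge, "GEN")
    expect_true(all(diff(traj$t) > 0))
    expect_error(neFromLd(sim$ge, "GEN", minPairs = 1e7), "dropped")
})

test_that("the overlap scan finds constructed splits and flags identity", {
    mkTraj <- function(ne, lo, hi) data.frame(
        t = c(50, 100, 200, 400), ne = ne, ciLow = lo, ciHigh = hi,
        cMean = 1 / (2 * c(50, 100, 200, 400)), nPairs = 100,
        bin = paste0("b", 1:4))
    a <- mkTraj(c(100, 100, 300, 300), c(90, 90, 270, 270),
                c(110, 110, 330, 330))
    b <- mkTraj(c(300, 300, 300, 300), c(270, 270, 270, 270),
                c(330, 330, 330, 330))
    res <- estimateTdg(a, b, method = "overlap")
    expect_equal(res$tdg, 100)
    expect_false(res$flagged)
    same <- estimateTdg(a, a, method = "overlap")
    expect_equal(same$tdg, 0)
    expect_true(same$flagged)
    bad <- b
    bad$bin <- paste0("z", 1:4)
    expect_error(estimateTdg(a, bad, method = "overlap"), "disjoint grids")
})

test_that("the drift clock inverts FST given the recent sizes", {
    traj <- data.frame(t = 100, ne = 100, ciLow = 90, ciHigh = 110,
                       cMean = 0.005, nPairs = 10, bin = "b1")
    trajG <- traj
    trajG$ne <- 300
    fst <- 1 - exp(-150 / (2 * 150))    # harmonic mean of 100 and 300 = 150
    res <- estimateTdg(traj, trajG, fst = fst)
    expect_equal(res$tdg, 150, tolerance = 1e-8)
    expect_error(estimateTdg(traj, trajG), "needs the pair")
})

test_that("a 150-generation split is recovered within a factor of two", {
    tdgs <- vapply(71:73, function(sd) {
        sim <- cachedSim(paste0("split", sd),
                         tinyCfg(tdgGens = 150, neIsolate = 60, seed = sd,
                                 selScale = 0, nSitesPerChrom = 2000))
        ft <- alleleFrequencies(sim$ge)
        ti <- neFromLd(sim$ge, "ISO")
        tg <- neFromLd(sim$ge, "GEN")
        estimateTdg(ti, tg, fst = hudsonFst(ft, sim$pair)$fst)$tdg
    }, numeric(1))
    expect_gt(median(tdgs), 75)
    expect_lt(median(tdgs), 300)
})

test_that("Delta Ancestry is the aligned difference of component means", {
    q <- rbind(matrix(c(0.9, 0.1), 10, 2, byrow = TRUE),
               matrix(c(0.4, 0.6), 10, 2, byrow = TRUE))
    rownames(q) <- sprintf("S%02d", 1:20)
    pops <- setNames(rep(c("ISO", "GEN"), each = 10), rownames(q))
    pair <- cohortPair("ISO", "GEN")
    expect_equal(deltaAncestry(q, pops, pair), 0.5)
    # label swap leaves M unchanged
    expect_equal(deltaAncestry(q[, 2:1], pops, pair), 0.5)
    # sample order invariance
    ord <- sample(20)
    expect_equal(deltaAncestry(q[ord, ], pops[ord], pair), 0.5)
    # identical distributions -> 0
    qSame <- matrix(0.5, 20, 2, dimnames = list(rownames(q), NULL))
    expect_equal(deltaAncestry(qSame, pops, pair), 0)
    expect_error(deltaAncestry(cbind(q, 0), pops, pair), "K = 2")
})

test_that("the K = 2 EM separates fixed sources and keeps likelihood rising", {
    f1 <- rep(c(1, 0), 100)
    dosA <- matrix(rep(2L * f1, 20), ncol = 20)        # source-1 individuals
    dosB <- matrix(rep(2L * (1 - f1), 20), ncol = 20)  # source-2 individuals
    em <- admixtureEmK2(cbind(dosA, dosB), seed = 2)
    expect_true(all(diff(em$logLik) > -1e-6))
    comp <- which.max(colMeans(em$Q[1:20, , drop = FALSE]))
    expect_true(all(em$Q[1:20, comp] > 0.95))
    expect_true(all(em$Q[21:40, comp] < 0.05))
})

test_that("EM recovers 70/30 admixture within 0.1 mean absolute error", {
    q <- c(rep(0.7, 30), rep(0.3, 30))
    ad <- simulateAdmixedGenotypes(q, nSites = 5000, fst = 0.1, seed = 2)
    em <- admixtureEmK2(ad$dosage, seed = 3)
    err <- min(mean(abs(em$Q[, 1] - q)), mean(abs(em$Q[, 2] - q)))
    expect_lte(err, 0.1)
})

test_that("a panmictic sample yields near-zero Delta Ancestry", {
    set.seed(5)
    dos <- matrix(rbinom(400 * 40, 2, runif(400, 0.1, 0.9)), nrow = 400)
    em <- suppressWarnings(admixtureEmK2(dos, seed = 4, maxIter = 200))
    pops <- rep(c("ISO", "GEN"), each = 20)
    m <- deltaAncestry(em$Q, pops, cohortPair("ISO", "GEN"))
    expect_lt(m, 0.15)
})

test_that("Isx follows its arithmetic and monotonicities", {
    expect_equal(isx(200, 1000, 0.5), 0.1)
    expect_equal(isx(200, 1000, 0), 0)
    expect_equal(isx(400, 1000, 0.5), 2 * isx(200, 1000, 0.5))
    expect_equal(isx(200, 2000, 0.5), isx(200, 1000, 0.5) / 2)
    expect_error(isx(200, 0, 0.5), "positive")
    expect_error(isx(-1, 100, 0.5))
})

test_that("measure correlations flag identities, inversions and constants", {
    set.seed(8)
    x <- rnorm(10)
    tab <- data.frame(isx = x, dup = x, neg = -x, flat = rep(1, 10))
    expect_warning(res <- correlateMeasures(tab), "flat")
    expect_equal(res$r["isx", "dup"], 1)
    expect_equal(res$r["isx", "neg"], -1)
    expect_true(is.na(res$r["isx", "flat"]))
    expect_equal(unname(res$isxRow[["dup"]]), 1)
    expect_error(correlateMeasures(tab[1:2, ]), "at least 3")
})
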