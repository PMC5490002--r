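test_that("singletons are sites with exactly one ALT copy in the population", {
    d <- rbind(c(1, 0, 0, 0, 1, 1),       # 1 in A, 2 in B
               c(2, 0, 0, 0, 0, 0),       # count 2 in A
               c(0, 1, 0, 0, 0, 0))       # 1 in A, 0 in B
    ge <- toyGe(d, populations = c(rep("A", 3), rep("B", 3)))
    ft <- alleleFrequencies(ge)
    expect_equal(findSingletons(ft, "A"), c(1L, 3L))
    expect_equal(findSingletons(ft, "B"), integer(0))
})

test_that("singleton calls match a brute-force scan of a simulated matrix", {
    sim <- cachedSim("tiny", tinyCfg())
    geMin <- subsampleCohorts(sim$ge, "minimum", seed = 2)
    ft <- alleleFrequencies(geMin)
    d <- dosages(geMin)
    iso <- populationOf(geMin) == "ISO"
    brute <- which(rowSums(d[, iso, drop = FALSE]) == 1)
    expect_identical(findSingletons(ft, "ISO"), as.integer(brute))
})

test_that("SVgene ratio and class follow the counts", {
    res <- svGene(c(3, 2, 0, 4), c(1, 2, 2, 0))
    expect_equal(res$ratio, c(3, 1, 0, NA))
    expect_equal(res$class, c(">1", "=1", "<1", ">1"))
    expect_error(svGene(0, 0), "excluded")
})

test_that("SVpop pools counts over the shared gene universe", {
    counts <- data.frame(gene = c("g1", "g2"),
                         misX = c(3, 1), synX = c(1, 3),
                         misY = c(2, 2), synY = c(1, 1))
    sp <- svPop(counts)
    expect_equal(sp[["isolate"]], 1.0)      # (3+1)/(1+3)
    expect_equal(sp[["general"]], 2.0)
    expect_equal(svXy(sp[["isolate"]], sp[["general"]]), 0.5)
    expect_equal(svXy(1.2, 1.0), 1.2)
    expect_true(is.na(svXy(NA_real_, 1)))
    noSyn <- data.frame(gene = "g1", misX = 2, synX = 0, misY = 1, synY = 1)
    expect_true(is.na(svPop(noSyn)[["isolate"]]))
})

test_that("the gene universe requires a singleton within the pair", {
    d <- rbind(c(1, 0, 0, 0),    # singleton in A only, gene g1 missense
               c(0, 0, 1, 0))    # singleton in B only, gene g2 synonymous
    ge <- toyGe(d, populations = c("A", "A", "B", "B"),
                consequence = c("missense", "synonymous"),
                gene = c("g1", "g2"))
    counts <- geneSingletonCounts(alleleFrequencies(ge),
                                  cohortPair("A", "B"))
    expect_setequal(counts$gene, c("g1", "g2"))
    expect_equal(counts$misX[counts$gene == "g1"], 1)
    expect_equal(counts$synY[counts$gene == "g2"], 1)
})

test_that("G_SV compares relaxation between essential and other genes", {
    genes <- c(sprintf("e%02d", 1:10), sprintf("n%03d", 1:100))
    classes <- c(rep(">1", 6), rep("<1", 4),          # 6/10 essential
                 rep(">1", 40), rep("<1", 60))        # 40/100 the rest
    ess <- sprintf("e%02d", 1:10)
    expect_equal(gSv(genes, classes, ess), 1.5)
    expect_equal(gSv(genes, rep(">1", 110), ess), 1.0)
    expect_error(gSv(sprintf("n%03d", 1:100), rep(">1", 100), ess),
                 "no essential gene")
    # exhaustive enumeration on a 20-gene toy table
    g20 <- sprintf("g%02d", 1:20)
    cl20 <- rep(c(">1", "<1"), 10)
    ess20 <- g20[1:5]                       # classes >1 at odd positions
    pEss <- sum(cl20[1:5] == ">1") / 5
    pNon <- sum(cl20[6:20] == ">1") / 15
    expect_equal(gSv(g20, cl20, ess20), pEss / pNon)
})

test_that("the 80% gene bootstrap is seeded and degenerate-safe", {
    genes <- sprintf("g%02d", 1:30)
    constant <- function(g) 2.5
    ci <- geneBootstrapCI(constant, genes, seed = 4)
    expect_equal(ci$ciLow, 2.5)
    expect_equal(ci$ciHigh, 2.5)
    frac <- function(g) mean(grepl("g0", g))
    a <- geneBootstrapCI(frac, genes, seed = 7)
    b <- geneBootstrapCI(frac, genes, seed = 7)
    expect_identical(a$values, b$values)
    expect_error(geneBootstrapCI(constant, genes[1:3]), "at least 5")
})

test_that("swapping the pair inverts SVxy exactly", {
    sim <- cachedSim("tiny", tinyCfg())
    ft <- alleleFrequencies(subsampleCohorts(sim$ge, "minimum", seed = 3))
    fwd <- svStatistics(ft, sim$pair, seed = 1)
    rev <- svStatistics(ft, cohortPair("GEN", "ISO"), seed = 1)
    expect_equal(fwd$svXy, 1 / rev$svXy)
})

test_that("same-law Poisson singleton counts centre SVxy on 1", {
    # 60 pairs of populations with identical per-gene singleton laws
    set.seed(11)
    vals <- replicate(60, {
        counts <- data.frame(gene = sprintf("g%03d", 1:120),
                             misX = rpois(120, 1.0), synX = rpois(120, 0.8),
                             misY = rpois(120, 1.0), synY = rpois(120, 0.8))
        counts <- counts[rowSums(counts[, -1]) > 0, ]
        sp <- svPop(counts)
        svXy(sp[["isolate"]], sp[["general"]])
    })
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - 1), 3 * se + 0.02)
})
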