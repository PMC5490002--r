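test_that("identical configuration and seed give identical cohorts and files", {
    cfg <- tinyCfg(seed = 99)
    a <- simulateCohortPair(cfg)
    b <- simulateCohortPair(cfg)
    expect_identical(dosages(a$ge), dosages(b$ge))
    expect_identical(variantInfo(a$ge), variantInfo(b$ge))
    da <- withr::local_tempdir()
    db <- withr::local_tempdir()
    pa <- writeInputs(a, da)
    pb <- writeInputs(b, db)
    for (k in names(pa))
        expect_identical(readLines(pa[[k]]), readLines(pb[[k]]),
                         info = k)
    # a different seed changes the data
    c2 <- simulateCohortPair(tinyCfg(seed = 100))
    expect_false(identical(dosages(a$ge), dosages(c2$ge)))
})

test_that("annotation assignment hits the configured class proportions", {
    cfg <- simConfig(chromLengthBp = 5e6, codingFraction = 0.6)
    ann <- assignAnnotations(sort(sample.int(5e6, 30000)), cfg, seed = 3)
    coding <- ann$consequence != "intergenic"
    expect_gt(sum(coding), 10000)
    props <- table(ann$consequence[coding]) / sum(coding)
    expect_lt(abs(props[["missense"]] - 0.65), 0.02)
    expect_lt(abs(props[["lof"]] - 0.05), 0.02)
    expect_lt(abs(props[["synonymous"]] - 0.30), 0.02)
    # intergenic fraction tracks the coding fraction of the layout
    expect_lt(abs(mean(!coding) - 0.4), 0.05)
})

test_that("pseudo-CADD orders classes and tracks severity", {
    cfg <- simConfig()
    ann <- assignAnnotations(sort(sample.int(5e6, 20000)), cfg, seed = 4)
    expect_gt(mean(ann$cadd[ann$consequence == "lof"]),
              mean(ann$cadd[ann$consequence == "synonymous"]))
    del <- ann$consequence %in% c("missense", "lof")
    rho <- cor(ann$cadd[del], abs(ann$s[del]), method = "spearman")
    expect_gt(rho, 0.5)
    expect_true(all(ann$cadd >= 0 & ann$cadd <= 50))
    # neutral classes centre in the low-score band
    expect_lt(mean(ann$cadd[!del]), 4)
    expect_lt(quantile(ann$cadd[!del], 0.95), 6)
})

test_that("neutral scaling removes fitness effects but keeps annotation", {
    cfg <- tinyCfg(selScale = 0)
    ann <- assignAnnotations(sort(sample.int(5e6, 5000)), cfg, seed = 5)
    expect_true(all(ann$s == 0))
    expect_gt(sum(ann$cadd > 20), 0)      # score strata stay populated
})

test_that("written inputs are internally consistent", {
    sim <- cachedSim("tiny", tinyCfg())
    outdir <- withr::local_tempdir()
    paths <- writeInputs(sim, outdir)
    ann <- readAnnotationTsv(paths[["annotation"]])
    ess <- readLines(paths[["essentialGenes"]])
    expect_true(all(ess %in% ann$gene))
    vcf <- readLines(paths[["vcf"]])
    aa <- sub(".*AA=([ACGT]).*", "\\1", grep("^chr", vcf, value = TRUE))
    expect_equal(aa, variantInfo(sim$ge)$ancestral)
    manifest <- jsonlite::read_json(paths[["manifest"]])
    expect_equal(manifest$config$seed, sim$truth$cfg$seed)
    q <- readQMatrix(paths[["qMatrix"]], paths[["qSamples"]])
    expect_equal(nrow(q), ncol(sim$ge))
    expect_true(all(rowSums(q) == 1))
})

test_that("infeasible configurations are rejected", {
    expect_error(simConfig(nSamples = 100, neIsolate = 50), "infeasible")
    expect_error(simConfig(mig = 0.7))
    expect_error(simConfig(classProps = c(missense = 0.9, lof = 0.3,
                                          synonymous = 0.3)))
})

test_that("divergence and bottleneck raise differentiation above the null", {
    null <- cachedSim("null0", tinyCfg(tdgGens = 0, selScale = 0,
                                       neIsolate = 150, seed = 55))
    drift <- cachedSim("drift1", tinyCfg(tdgGens = 150, selScale = 0,
                                         neIsolate = 50, seed = 55))
    fstNull <- hudsonFst(alleleFrequencies(null$ge), null$pair)$fst
    fstDrift <- hudsonFst(alleleFrequencies(drift$ge), drift$pair)$fst
    expect_lt(abs(fstNull), 0.02)
    expect_gt(fstDrift, fstNull + 0.05)
})

test_that("a migration-drift equilibrium lands near the island expectation", {
    sims <- lapply(81:84, function(sd)
        cachedSim(paste0("isl", sd),
                  tinyCfg(tdgGens = 600, mig = 0.01, neIsolate = 150,
                          neGeneral = 150, selScale = 0, seed = sd)))
    fsts <- vapply(sims, function(s)
        hudsonFst(alleleFrequencies(s$ge), s$pair)$fst, numeric(1))
    expected <- sims[[1]]$truth$expectedFstIsland   # 1 / (1 + 8 Nm)
    expect_lt(abs(mean(fsts) - expected) / expected, 0.35)
})

test_that("the cohort panel varies its generating parameters monotonically", {
    panel <- makeCohortPanel(tinyCfg(), nCohorts = 5, simulate = FALSE,
                             seed = 7)
    tdg <- vapply(panel, function(p) p$cfg$tdgGens, numeric(1))
    ne <- vapply(panel, function(p) p$cfg$neIsolate, numeric(1))
    mig <- vapply(panel, function(p) p$cfg$mig, numeric(1))
    expect_true(all(diff(tdg) > 0))
    expect_true(all(diff(ne) < 0))
    expect_true(all(diff(mig) < 0))
    expect_error(makeCohortPanel(tinyCfg(), nCohorts = 2), "at least 3")
})
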