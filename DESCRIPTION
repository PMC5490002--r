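Package: isodrift
Title: Drift, Selection-Relaxation and Isolation Statistics for
    Population Cohort Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic statistics for comparing an isolated
    population with its closest general population from genotype data:
    drifted-variant enrichment (DVxy, coding and CADD-stratified),
    singleton-based relaxation of purifying selection (SVgene, SVpop,
    SVxy, G_SV), the Rxy genetic-load ratio, rare-variant sharing
    matrices (f2 and f3-10), Hudson FST, inbreeding coefficients, runs
    of homozygosity, LD decay, LD-based effective population size and
    divergence-time inference, Delta-Ancestry under a two-component
    admixture model, and the isolation index Isx, together with a
    seeded forward Wright-Fisher simulator of isolate/general cohort
    pairs with known demography and selection for calibration and
    ground-truth recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
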