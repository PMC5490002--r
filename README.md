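# isodrift

Population-genetic statistics for **isolate / general cohort pairs**:
quantifying how founder effects, drift and restricted gene flow reshape the
functional variant spectrum of an isolated population relative to its
closest general population, and summarising the level of isolation in a
single index.

The package is aimed at statistical geneticists designing association
studies in population isolates, and at anyone who needs reference
implementations of these pairwise statistics with calibrated null
behaviour.

## What it computes

For a pair (isolate *x*, general population *y*) built from genotypes
(VCF + annotation TSV + sample map, or the built-in simulator):

- **DVxy** — enrichment of *drifted variants* (DAF 2–5% in one population
  and at least three-fold lower in the other):

      DVxy = (n_func,x / n_intergenic,x) / (n_func,y / n_intergenic,y)

  for coding variants (missense + LoF over intergenic) and genome-wide by
  CADD strata 0–5 / 5–10 / 10–20 / >20 (`DVxy-wg`, lowest bin as
  reference), with 20-chromosome resampling CIs and a
  leave-one-chromosome-out jackknife.
- **SVgene / SVpop / SVxy / G_SV** — missense-to-synonymous singleton
  ratios per gene and pooled, `SVxy = SVpop_x / SVpop_y` with an
  80%-of-genes resampling CI, and the essential-gene contrast `G_SV`.
- **Rxy** — the genetic-load ratio `R = Σ daf_x(1−daf_y) / Σ daf_y(1−daf_x)`
  per functional class, normalised by a neutral control class, with a
  chromosome-block bootstrap.
- **f2 / f3–10 sharing** — individual-by-individual rare-allele sharing
  matrices, plus the signed `deltaDAF` differentiation scan.
- **FST (Hudson), inbreeding F, ROH, LD decay** — the standard isolation
  correlates, re-implemented with documented estimators.
- **Ne(t), Tdg, Delta Ancestry, Isx** — LD-based effective-size
  trajectories (`Ne = (1/(4c))(1/r²_adj − 2)` at time `t = 1/(2c)`), the
  divergence time from the drift clock `Tdg = −2Ñ ln(1−FST)`, the K = 2
  admixture ancestry contrast `M`, and the isolation index
  `Isx = Tdg·M/Ne`, plus the Pearson correlation of Isx with every other
  measure across a panel of cohorts.

A forward Wright–Fisher simulator (`simConfig()`, `simulateCohortPair()`,
`makeCohortPanel()`) generates cohort pairs with known demography,
selection and pseudo-CADD annotation, and writes every input format the
pipeline reads.

## Worked example

```r
library(isodrift)

# isolate of Ne 60 split 200 generations ago, 6 x 5 Mb genome
sim <- simulateCohortPair(simConfig(seed = 7, nChroms = 6))
res <- runPair(sim$ge, sim$pair,
               essentialGenes = sim$truth$essentialGenes, seed = 1)
res
#> CohortPairResult: ISO vs GEN
#>   dvxyCoding     1.467
#>   dvxyWgTop      1.819
#>   svXy           0.9293
#>   rxyMissense    1.232
#>   fst            0.6235
#>   rohTotalMb     7.166
#>   tdg            620.1
#>   neRecent       224.2
#>   deltaAncestry  0.9998
#>   isx            2.765
```

Read: drifted functional variants are ~1.5-fold enriched in the isolate
(`dvxyCoding > 1`), most strongly in the highest deleteriousness stratum
(`dvxyWgTop = 1.82`), while the normalised load ratio stays near 1 —
enrichment of low-frequency functional variation without a comparable
increase in per-genome load. `svXy` is noisy in a single small-genome
replicate (here 0.93); its relaxation signal emerges in replicate averages
(see the calibration suite). The remaining measures (FST, ROH, Ne
trajectory, Tdg, Delta Ancestry) feed the isolation index; across a
simulated gradient panel, `runPanel()` shows Isx ranking the cohorts.

A thin command-line wrapper for the same steps lives at
`inst/cli/isodrift.R` (`simulate`, `run-pair`, `run-panel`).

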