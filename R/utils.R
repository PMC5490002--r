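# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Variant key used for annotation joins.
variantKey <- function(chrom, pos, ref, alt)
    paste(chrom, pos, ref, alt, sep = ":")

# columns of a GenotypeExperiment belonging to one population
popColumns <- function(ge, population) {
    idx <- which(populationOf(ge) == population)
    if (!length(idx))
        stop("population '", population, "' not present in the data")
    idx
}

stopIfNotPair <- function(ft, pair) {
    pops <- colnames(ft@altCount)
    miss <- setdiff(c(pair@isolate, pair@general), pops)
    if (length(miss))
        stop("population(s) absent from the frequency table: ",
             paste(miss, collapse = ", "))
    invisible(TRUE)
}
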