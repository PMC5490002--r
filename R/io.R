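#' Consequence-term mapping table
#'
#' Returns the shipped mapping from annotation terms (VEP-style strings) to
#' the five consequence classes used throughout the package (missense, lof,
#' synonymous, intergenic, other). Loss-of-function collapses stop-gain,
#' splice-donor and splice-acceptor (plus frameshift/start-loss) into one
#' class. Unknown terms map to \code{other}.
#'
#' @return named character vector, names = input terms, values = classes.
#' @export
consequenceMapping <- function() {
    path <- system.file("extdata", "consequence_map.tsv", package = "isodrift")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stats::setNames(tab$class, tab$term)
}

mapConsequence <- function(terms) {
    map <- consequenceMapping()
    out <- unname(map[terms])
    out[is.na(out)] <- "other"
    out
}

#' Read a sample-to-population map
#'
#' Tab-separated file with columns \code{sample_id} and \code{population}
#' (header required).
#'
#' @param path file path.
#' @return data.frame with columns sample and population.
#' @export
readSampleMap <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "population") %in% colnames(tab)))
        stop("sample map needs columns 'sample_id' and 'population'")
    data.frame(sample = as.character(tab$sample_id),
               population = as.character(tab$population),
               stringsAsFactors = FALSE)
}

#' Read genotypes from a VCF into a GenotypeExperiment
#'
#' Reads a VCF 4.x file (plain or bgzipped) with
#' \code{VariantAnnotation::readVcf}, keeps biallelic SNVs, parses GT fields
#' into ALT-allele dosages (phased haplotypes are kept as \code{hapA}/
#' \code{hapB} assays when every call is phased), and takes the ancestral
#' allele from the \code{AA} INFO tag when present. Variant annotation
#' columns (gene, consequence, cadd) are initialised to \code{other}/NA and
#' filled by [joinAnnotation()].
#'
#' @param path VCF file path.
#' @param sampleMap data.frame as returned by [readSampleMap()]; every
#'   listed sample must be present in the VCF. Samples in the VCF but not in
#'   the map are dropped.
#' @param multiallelic \code{"skip"} (default) drops sites with more than
#'   one ALT allele; \code{"error"} stops.
#' @return a [GenotypeExperiment-class].
#' @export
readVcfGenotypes <- function(path, sampleMap,
                             multiallelic = c("skip", "error")) {
    multiallelic <- match.arg(multiallelic)
    if (!file.exists(path)) stop("cannot read VCF file: ", path)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")

    vcf_samples <- colnames(vcf)
    missing <- setdiff(sampleMap$sample, vcf_samples)
    if (length(missing))
        stop("sample(s) in map absent from VCF: ",
             paste(missing, collapse = ", "))
    vcf <- vcf[, sampleMap$sample]

    nalt <- lengths(VariantAnnotation::alt(vcf))
    if (any(nalt > 1)) {
        if (multiallelic == "error")
            stop("multi-allelic site(s) present; set multiallelic = 'skip'")
        vcf <- vcf[nalt == 1, ]
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
    snv <- nchar(ref) == 1 & nchar(alt) == 1
    vcf <- vcf[snv, ]
    rr <- rr[snv]
    ref <- ref[snv]
    alt <- alt[snv]

    gt <- VariantAnnotation::geno(vcf)$GT
    parse_gt <- function(g) {
        # returns c(dosage, hapA, hapB, phased); NA for missing
        known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
                   "1|0" = 1, "1/1" = 2, "1|1" = 2)
        d <- unname(known[g])
        d
    }
    dosage <- matrix(parse_gt(gt), nrow = nrow(gt), ncol = ncol(gt))
    storage.mode(dosage) <- "integer"
    phased <- all(grepl("|", gt, fixed = TRUE) | gt %in% c("./.", ".|."))
    hapA <- hapB <- NULL
    if (phased && nrow(gt)) {
        hapA <- matrix(as.integer(substr(gt, 1, 1) == "1"), nrow = nrow(gt))
        hapB <- matrix(as.integer(substr(gt, 3, 3) == "1"), nrow = nrow(gt))
        hapA[gt %in% c("./.", ".|.")] <- NA_integer_
        hapB[gt %in% c("./.", ".|.")] <- NA_integer_
    }

    info <- VariantAnnotation::info(vcf)
    ancestral <- rep(NA_character_, nrow(vcf))
    if ("AA" %in% colnames(info)) {
        aa <- as.character(info$AA)
        aa[!aa %in% c("A", "C", "G", "T")] <- NA_character_
        ancestral <- aa
    }

    variants <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = ref, alt = alt, ancestral = ancestral,
        gene = NA_character_, consequence = "other", cadd = NA_real_,
        stringsAsFactors = FALSE)

    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
    if (!is.null(hapA)) {
        hapA <- hapA[ord, , drop = FALSE]
        hapB <- hapB[ord, , drop = FALSE]
    }
    GenotypeExperiment(dosage, variants, sampleMap, hapA = hapA, hapB = hapB)
}

#' Read a variant-annotation table
#'
#' Tab-separated file with header
#' \code{chrom, pos, ref, alt, gene, consequence, cadd}. Consequence strings
#' are mapped onto the five-class scheme via [consequenceMapping()]; unknown
#' terms become \code{other}, missing CADD values may be given as \code{NA}
#' or an empty field.
#'
#' @param path annotation TSV path.
#' @return data.frame with mapped consequence column.
#' @export
readAnnotationTsv <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "cadd")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
    bad <- which(is.na(suppressWarnings(as.numeric(tab$pos))))
    if (length(bad))
        stop("malformed annotation row at line ", bad[1] + 1L,
             " (pos not numeric)")
    badc <- which(!is.na(tab$cadd) &
                  is.na(suppressWarnings(as.numeric(tab$cadd))))
    if (length(badc))
        stop("malformed annotation row at line ", badc[1] + 1L,
             " (cadd not numeric)")
    tab$pos <- as.integer(tab$pos)
    tab$cadd <- as.numeric(tab$cadd)
    tab$consequence <- mapConsequence(as.character(tab$consequence))
    tab$chrom <- as.character(tab$chrom)
    tab
}

#' Join annotation columns onto a GenotypeExperiment
#'
#' Matches by (chrom, pos, ref, alt). Variants without a matching annotation
#' row keep \code{consequence = "other"} and \code{cadd = NA}; annotation
#' rows without a matching variant are ignored (their count is reported via
#' \code{message()}).
#'
#' @param ge a [GenotypeExperiment-class].
#' @param annotation data.frame from [readAnnotationTsv()].
#' @return the annotated GenotypeExperiment.
#' @export
joinAnnotation <- function(ge, annotation) {
    vi <- variantInfo(ge)
    key_ge <- variantKey(vi$chrom, vi$pos, vi$ref, vi$alt)
    key_an <- variantKey(annotation$chrom, annotation$pos,
                         annotation$ref, annotation$alt)
    hit <- match(key_ge, key_an)
    unmatched_ann <- sum(!key_an %in% key_ge)
    if (unmatched_ann > 0)
        message(unmatched_ann,
                " annotation row(s) had no matching variant and were ignored")
    rd <- rowData(ge)
    rd$gene <- ifelse(is.na(hit), NA_character_,
                      as.character(annotation$gene[hit]))
    rd$consequence <- ifelse(is.na(hit), "other",
                             annotation$consequence[hit])
    rd$cadd <- ifelse(is.na(hit), NA_real_, annotation$cadd[hit])
    rowData(ge) <- rd
    validObject(ge)
    ge
}

#' Read an ADMIXTURE-style Q matrix
#'
#' Whitespace-delimited file with K columns per sample, one row per sample,
#' accompanied by a sample-order file (one sample ID per line, .fam-style
#' first column accepted).
#'
#' @param qPath path to the .Q file.
#' @param samplesPath path to the sample-order file.
#' @return numeric matrix with rownames = sample IDs.
#' @export
readQMatrix <- function(qPath, samplesPath) {
    q <- as.matrix(utils::read.table(qPath))
    ids <- utils::read.table(samplesPath, stringsAsFactors = FALSE)[[1]]
    if (length(ids) != nrow(q))
        stop("sample-order file length does not match Q matrix rows")
    rownames(q) <- ids
    colnames(q) <- paste0("Q", seq_len(ncol(q)))
    q
}
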