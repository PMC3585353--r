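#' Accessors for hapslide classes
#'
#' Small accessor generics so downstream code never touches slots:
#' \code{genotypeCalls} (samples x SNPs allele-count matrix),
#' \code{snpInfo} (SNP map as a data.frame), \code{phenotype}
#' (0/1 case-control labels), \code{covariateTable} (covariate columns of
#' the sample metadata), \code{poolHaplotypes}/\code{poolFreqs}
#' (haplotype pool content), \code{haplotypes}/\code{hapFreqs}/
#' \code{hapDosages} (fitted haplotype set), \code{minP}
#' (permutation minima) and \code{cohortGenotypes}/\code{truePairs}
#' (synthetic-cohort ground truth).
#'
#' @param x an object of the documented class.
#' @return the extracted component; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) {
    m <- t(SummarizedExperiment::assay(x, "calls"))
    colnames(m) <- names(SummarizedExperiment::rowRanges(x))
    m
})
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "SyntheticCohort", function(x)
    genotypeCalls(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(id = rr$snpID,
               chrom = as.character(GenomicRanges::seqnames(rr)),
               bp = GenomicRanges::start(rr),
               allele1 = rr$allele1, allele2 = rr$allele2,
               stringsAsFactors = FALSE)
})
#' @rdname accessors
#' @export
setMethod("snpInfo", "SyntheticCohort", function(x) snpInfo(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname accessors
#' @export
setMethod("phenotype", "GenotypeMatrix", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("phenotype" %in% colnames(cd)) as.integer(cd$phenotype)
    else rep(NA_integer_, ncol(x))
})
#' @rdname accessors
#' @export
setMethod("phenotype", "SyntheticCohort", function(x)
    phenotype(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))
#' @rdname accessors
#' @export
setMethod("covariateTable", "GenotypeMatrix", function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- setdiff(colnames(cd), c("phenotype", "sample_id",
                                    "exclusion_flag"))
    cd[, keep, drop = FALSE]
})
#' @rdname accessors
#' @export
setMethod("covariateTable", "SyntheticCohort", function(x)
    covariateTable(x@genotypes))

#' @rdname accessors
#' @export
setGeneric("poolHaplotypes", function(x) standardGeneric("poolHaplotypes"))
#' @rdname accessors
#' @export
setMethod("poolHaplotypes", "HaplotypePool", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setGeneric("poolFreqs", function(x) standardGeneric("poolFreqs"))
#' @rdname accessors
#' @export
setMethod("poolFreqs", "HaplotypePool", function(x) x@poolFreqs)

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypeSet", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setGeneric("hapFreqs", function(x) standardGeneric("hapFreqs"))
#' @rdname accessors
#' @export
setMethod("hapFreqs", "HaplotypeSet", function(x)
    setNames(x@freqs, x@haplotypes))

#' @rdname accessors
#' @export
setGeneric("hapDosages", function(x) standardGeneric("hapDosages"))
#' @rdname accessors
#' @export
setMethod("hapDosages", "HaplotypeSet", function(x) {
    d <- x@dosages
    colnames(d) <- x@haplotypes
    d
})

#' @rdname accessors
#' @export
setGeneric("minP", function(x) standardGeneric("minP"))
#' @rdname accessors
#' @export
setMethod("minP", "PermutationResult", function(x) x@minP)

#' @rdname accessors
#' @export
setGeneric("cohortGenotypes", function(x) standardGeneric("cohortGenotypes"))
#' @rdname accessors
#' @export
setMethod("cohortGenotypes", "SyntheticCohort", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("truePairs", function(x) standardGeneric("truePairs"))
#' @rdname accessors
#' @export
setMethod("truePairs", "SyntheticCohort", function(x) x@truePairs)

#' @rdname accessors
#' @export
setGeneric("localAncestry", function(x) standardGeneric("localAncestry"))
#' @rdname accessors
#' @export
setMethod("localAncestry", "SyntheticCohort", function(x) x@localAncestry)
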