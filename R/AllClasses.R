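#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowRanges
#' @importFrom stats rbinom runif rgamma plogis pchisq pnorm pbeta qnorm
#'   rnorm dbeta model.matrix sd quantile setNames ks.test complete.cases
#' @importFrom utils head read.table write.table
NULL

#' Class "GenotypeMatrix": unphased genotype calls with sample metadata
#'
#' Thin wrapper around
#' \linkS4class{RangedSummarizedExperiment} holding a single
#' \code{"calls"} assay of allele-count genotypes (rows = SNPs, columns =
#' samples; values 0, 1, 2 or \code{NA} counting copies of \code{allele1}).
#' Row ranges carry the SNP map (chromosome, 1-based bp position,
#' \code{snpID}, \code{allele1}, \code{allele2}); \code{colData} carries the
#' case-control phenotype (1 = case, 0 = control) and any covariates.
#'
#' Positions are strictly increasing within each chromosome. Use
#' \code{\link{genotypeCalls}}, \code{\link{snpInfo}},
#' \code{\link{phenotype}} and \code{\link{covariateTable}} rather than
#' touching slots.
#'
#' @seealso \code{\link{GenotypeMatrix}} (constructor),
#'   \code{\link{readGenotypes}}
#' @export
setClass("GenotypeMatrix",
    contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- NULL
    if (!("calls" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'calls' is required")
    else {
        m <- SummarizedExperiment::assay(object, "calls")
        bad <- !(m %in% c(0L, 1L, 2L)) & !is.na(m)
        if (any(bad))
            msg <- c(msg, "genotype calls must be 0, 1, 2 or NA")
    }
    cd <- SummarizedExperiment::colData(object)
    if ("phenotype" %in% colnames(cd)) {
        ph <- cd$phenotype
        if (!all(ph %in% c(0L, 1L) | is.na(ph)))
            msg <- c(msg, "phenotype must be 0, 1 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr) > 1L) {
        ch <- as.character(GenomicRanges::seqnames(rr))
        pos <- GenomicRanges::start(rr)
        for (c1 in unique(ch)) {
            p <- pos[ch == c1]
            if (any(diff(p) <= 0)) {
                msg <- c(msg, sprintf(
                    "bp positions not strictly increasing on chromosome %s", c1))
                break
            }
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix, samples x SNPs, entries 0/1/2/\code{NA}
#'   counting copies of \code{allele1}.
#' @param snps data.frame with columns \code{id}, \code{chrom}, \code{bp},
#'   \code{allele1}, \code{allele2} (one row per SNP, same order as the
#'   columns of \code{calls}).
#' @param samples data.frame of per-sample metadata; a \code{phenotype}
#'   column (1 = case, 0 = control) is recognised by the association
#'   machinery, every other column is treated as a covariate. Row order
#'   matches the rows of \code{calls}. May be \code{NULL}.
#' @param sort sort SNPs by (chromosome, position)? Default \code{TRUE}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' calls <- rbind(c(0, 1), c(2, 1))
#' snps <- data.frame(id = c("s1", "s2"), chrom = "1", bp = c(100, 200),
#'                    allele1 = c("A", "C"), allele2 = c("G", "T"))
#' gm <- GenotypeMatrix(calls, snps, data.frame(phenotype = c(1, 0)))
#' @export
GenotypeMatrix <- function(calls, snps, samples = NULL, sort = TRUE) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    stopifnot(ncol(calls) == nrow(snps))
    if (is.null(rownames(calls)))
        rownames(calls) <- if (!is.null(samples) && "sample_id" %in% colnames(samples))
            as.character(samples$sample_id) else paste0("sample", seq_len(nrow(calls)))
    if (sort) {
        o <- order(as.character(snps$chrom), snps$bp)
        snps <- snps[o, , drop = FALSE]
        calls <- calls[, o, drop = FALSE]
    }
    colnames(calls) <- as.character(snps$id)
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(snps$chrom),
        ranges = IRanges::IRanges(start = snps$bp, width = 1L),
        snpID = as.character(snps$id),
        allele1 = as.character(snps$allele1),
        allele2 = as.character(snps$allele2))
    names(rr) <- as.character(snps$id)
    cd <- if (is.null(samples))
        S4Vectors::DataFrame(row.names = rownames(calls))
    else S4Vectors::DataFrame(samples, row.names = rownames(calls))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = t(calls)), rowRanges = rr, colData = cd)
    new("GenotypeMatrix", se)
}

#' Class "HaplotypePool": a finite population of haplotypes
#'
#' The generative ground truth of the synthetic cohorts: a set of distinct
#' haplotypes over \code{nSnps} biallelic SNPs together with their
#' population frequencies. Diplotypes are drawn from the pool under
#' Hardy-Weinberg equilibrium.
#'
#' @slot nSnps number of SNPs.
#' @slot alleles 2 x nSnps character matrix; row 1 = allele1, row 2 = allele2.
#' @slot haplotypes character vector of allele strings of length nSnps.
#' @slot bits 0/1 integer matrix (haplotypes x SNPs), 1 = carries allele1.
#' @slot poolFreqs per-haplotype probabilities summing to one.
#' @seealso \code{\link{generateHaplotypePool}}
#' @export
setClass("HaplotypePool", representation(
    nSnps = "integer",
    alleles = "matrix",
    haplotypes = "character",
    bits = "matrix",
    poolFreqs = "numeric"))

setValidity("HaplotypePool", function(object) {
    msg <- NULL
    if (abs(sum(object@poolFreqs) - 1) > 1e-12)
        msg <- c(msg, "pool frequencies must sum to 1")
    if (any(nchar(object@haplotypes) != object@nSnps))
        msg <- c(msg, "haplotype strings must have length nSnps")
    if (anyDuplicated(object@haplotypes))
        msg <- c(msg, "haplotypes must be distinct")
    if (length(object@haplotypes) != length(object@poolFreqs))
        msg <- c(msg, "haplotypes and poolFreqs lengths differ")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "HaplotypePool", function(object) {
    cat("HaplotypePool:", length(object@haplotypes), "haplotypes over",
        object@nSnps, "SNPs\n")
    k <- min(6L, length(object@haplotypes))
    for (i in seq_len(k))
        cat(sprintf("  %s  f = %.4f\n", object@haplotypes[i],
                    object@poolFreqs[i]))
    if (length(object@haplotypes) > k) cat("  ...\n")
})

#' Class "DiseaseModel": logistic disease model used for simulation
#'
#' Disease probability is \code{plogis(intercept + betaH * d + X b)} where
#' \code{d} counts copies of the risk haplotype (the allele string
#' \code{riskHaplotype} matched at SNPs \code{riskStart..riskEnd} of the
#' pool) and \code{X b} collects any covariate effects.
#'
#' @slot intercept baseline log-odds.
#' @slot riskHaplotype allele string of the risk haplotype ("" for none).
#' @slot riskStart,riskEnd 1-based SNP index range the string refers to.
#' @slot betaH log-odds per copy of the risk haplotype.
#' @slot covariateEffects named numeric, log-odds per unit of the named
#'   covariate design column (empty for none).
#' @export
setClass("DiseaseModel", representation(
    intercept = "numeric",
    riskHaplotype = "character",
    riskStart = "integer",
    riskEnd = "integer",
    betaH = "numeric",
    covariateEffects = "numeric"))

#' Construct a DiseaseModel
#'
#' @param intercept baseline log-odds.
#' @param riskHaplotype risk-haplotype allele string; \code{""} disables the
#'   haplotype effect.
#' @param riskStart,riskEnd 1-based SNP index range of the risk haplotype.
#' @param betaH log-odds per copy.
#' @param covariateEffects named numeric vector of covariate log-odds.
#' @return a \linkS4class{DiseaseModel}.
#' @examples
#' DiseaseModel(intercept = 0, riskHaplotype = "AG", riskStart = 2,
#'              riskEnd = 3, betaH = log(1.5))
#' @export
DiseaseModel <- function(intercept = 0, riskHaplotype = "",
                         riskStart = 1L, riskEnd = 1L, betaH = 0,
                         covariateEffects = numeric(0)) {
    if (riskHaplotype != "") {
        riskEnd <- riskStart + nchar(riskHaplotype) - 1L
    }
    new("DiseaseModel", intercept = as.numeric(intercept),
        riskHaplotype = riskHaplotype,
        riskStart = as.integer(riskStart), riskEnd = as.integer(riskEnd),
        betaH = as.numeric(betaH),
        covariateEffects = covariateEffects)
}

setMethod("show", "DiseaseModel", function(object) {
    cat("DiseaseModel: intercept", object@intercept)
    if (object@riskHaplotype != "")
        cat(sprintf(", risk haplotype %s @ SNPs %d-%d, beta = %.4f (OR %.3f)",
                    object@riskHaplotype, object@riskStart, object@riskEnd,
                    object@betaH, exp(object@betaH)))
    cat("\n")
    if (length(object@covariateEffects))
        cat("  covariate effects:",
            paste(names(object@covariateEffects),
                  signif(object@covariateEffects, 3), collapse = ", "), "\n")
})

#' Class "LocalAncestryTrack": per-SNP local-ancestry posteriors
#'
#' For each sample and SNP, the posterior probabilities of carrying 0, 1 or
#' 2 copies of the European-ancestry allele. Each triple sums to one.
#'
#' @slot p0,p1,p2 numeric matrices (samples x SNPs).
#' @slot snpIds SNP identifiers (column order).
#' @slot sampleIds sample identifiers (row order).
#' @seealso \code{\link{localAncestryCovariate}}
#' @export
setClass("LocalAncestryTrack", representation(
    p0 = "matrix", p1 = "matrix", p2 = "matrix",
    snpIds = "character", sampleIds = "character"))

setValidity("LocalAncestryTrack", function(object) {
    s <- object@p0 + object@p1 + object@p2
    if (any(abs(s - 1) > 1e-9))
        return("posterior triples must sum to 1")
    if (any(object@p0 < 0 | object@p1 < 0 | object@p2 < 0) ||
        any(object@p0 > 1 | object@p1 > 1 | object@p2 > 1))
        return("posteriors must lie in [0, 1]")
    TRUE
})

setMethod("show", "LocalAncestryTrack", function(object) {
    cat("LocalAncestryTrack:", nrow(object@p0), "samples x",
        ncol(object@p0), "SNPs\n")
})

#' Class "SyntheticCohort": a simulated case-control cohort
#'
#' Holds the generated \linkS4class{GenotypeMatrix} (phenotype and
#' covariates in its \code{colData}) together with the generative ground
#' truth: the haplotype pool, the per-sample pair of pool haplotype indices,
#' the disease model, the seed, and (for admixed cohorts) the known
#' local-ancestry track.
#'
#' @slot genotypes the \linkS4class{GenotypeMatrix}.
#' @slot truePairs integer matrix (samples x 2) of pool haplotype indices;
#'   zero rows when per-copy haplotypes were not drawn from a single pool.
#' @slot pool the generating \linkS4class{HaplotypePool} (or \code{NULL}).
#' @slot model the \linkS4class{DiseaseModel} (or \code{NULL}).
#' @slot localAncestry a \linkS4class{LocalAncestryTrack} or \code{NULL}.
#' @slot seed integer seed used.
#' @export
setClass("SyntheticCohort", representation(
    genotypes = "GenotypeMatrix",
    truePairs = "matrix",
    pool = "ANY",
    model = "ANY",
    localAncestry = "ANY",
    seed = "integer"))

setValidity("SyntheticCohort", function(object) {
    if (nrow(object@truePairs) > 0 && !is.null(object@pool)) {
        gm <- object@genotypes
        calls <- t(SummarizedExperiment::assay(gm, "calls"))
        bits <- object@pool@bits
        expect <- bits[object@truePairs[, 1], , drop = FALSE] +
            bits[object@truePairs[, 2], , drop = FALSE]
        if (ncol(expect) == ncol(calls)) {
            ok <- is.na(calls) | calls == expect
            if (!all(ok))
                return("genotypes inconsistent with true haplotype pairs")
        }
    }
    TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
    ph <- phenotype(object@genotypes)
    cat("SyntheticCohort:", ncol(SummarizedExperiment::assay(object@genotypes)),
        "samples (", sum(ph == 1L, na.rm = TRUE), "cases /",
        sum(ph == 0L, na.rm = TRUE), "controls ),",
        nrow(SummarizedExperiment::assay(object@genotypes)), "SNPs\n")
    if (!is.null(object@model)) show(object@model)
})

#' Class "HaplotypeSet": E-M haplotype frequencies and dosages for a window
#'
#' Result of \code{\link{emFit}}: the haplotypes compatible with the
#' window's genotypes, their maximum-likelihood frequencies under
#' Hardy-Weinberg equilibrium, and the per-sample expected haplotype
#' dosages E[n_h | G] evaluated at the fitted frequencies. Dosage rows of
#' retained samples sum to 2.
#'
#' @slot haplotypes allele strings over the window's SNPs.
#' @slot freqs fitted frequencies (sum to one).
#' @slot dosages samples x haplotypes matrix of expected dosages; rows of
#'   dropped samples are \code{NA}.
#' @slot loglik final observed-data log-likelihood.
#' @slot loglikTrace per-iteration log-likelihood (ascent diagnostic).
#' @slot nIter iterations used.
#' @slot converged convergence flag.
#' @slot droppedSamples ids of samples dropped for excess ambiguity.
#' @export
setClass("HaplotypeSet", representation(
    haplotypes = "character",
    freqs = "numeric",
    dosages = "matrix",
    loglik = "numeric",
    loglikTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    droppedSamples = "character"))

setValidity("HaplotypeSet", function(object) {
    msg <- NULL
    if (length(object@freqs) &&
        (any(object@freqs < -1e-12) || abs(sum(object@freqs) - 1) > 1e-9))
        msg <- c(msg, "frequencies must be nonnegative and sum to 1")
    d <- object@dosages
    if (nrow(d) > 0) {
        rs <- rowSums(d)
        ok <- is.na(rs) | abs(rs - 2) < 1e-9
        if (!all(ok))
            msg <- c(msg, "dosage rows of retained samples must sum to 2")
        if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "HaplotypeSet", function(object) {
    cat("HaplotypeSet:", length(object@haplotypes), "haplotypes,",
        nrow(object@dosages), "samples; loglik", format(object@loglik),
        if (object@converged) "(converged)\n" else "(NOT converged)\n")
    o <- order(object@freqs, decreasing = TRUE)
    for (i in head(o, 6L))
        cat(sprintf("  %s  f = %.4f\n", object@haplotypes[i], object@freqs[i]))
    if (length(o) > 6L) cat("  ...\n")
})

#' Class "QcReport": itemized sample/SNP quality-control removals
#'
#' @slot samplesRemoved named integer counts per removal reason.
#' @slot snpsRemoved named integer counts per removal reason.
#' @slot survivors named integer: surviving \code{samples} and \code{snps}.
#' @slot hweFlagged SNP ids flagged (never removed) for Hardy-Weinberg
#'   deviation below the configured threshold.
#' @export
setClass("QcReport", representation(
    samplesRemoved = "integer",
    snpsRemoved = "integer",
    survivors = "integer",
    hweFlagged = "character"))

setMethod("show", "QcReport", function(object) {
    cat("QC report\n")
    if (length(object@samplesRemoved)) {
        cat("  samples removed:\n")
        for (r in names(object@samplesRemoved))
            cat(sprintf("    %-12s %d\n", r, object@samplesRemoved[[r]]))
    }
    if (length(object@snpsRemoved)) {
        cat("  SNPs removed:\n")
        for (r in names(object@snpsRemoved))
            cat(sprintf("    %-12s %d\n", r, object@snpsRemoved[[r]]))
    }
    cat("  survivors:", paste(names(object@survivors),
                              object@survivors, collapse = ", "), "\n")
    if (length(object@hweFlagged))
        cat("  HWE-flagged SNPs (kept):", length(object@hweFlagged), "\n")
})

#' Class "AssocResult": one association test result
#'
#' @slot term tested term label.
#' @slot beta,se log-odds estimate and standard error (1-df tests).
#' @slot oddsRatio,ciLow,ciHigh per-copy odds ratio and 95 percent bounds.
#' @slot p p-value.
#' @slot df degrees of freedom.
#' @slot test "wald" or "lr".
#' @slot lrStat likelihood-ratio statistic (LR tests).
#' @slot adjustedFor SNP ids adjusted for (possibly empty).
#' @slot converged fit convergence flag.
#' @slot note free-text flag, e.g. "collinear" or "df0".
#' @export
setClass("AssocResult", representation(
    term = "character",
    beta = "numeric", se = "numeric",
    oddsRatio = "numeric", ciLow = "numeric", ciHigh = "numeric",
    p = "numeric", df = "integer", test = "character",
    lrStat = "numeric", adjustedFor = "character",
    converged = "logical", note = "character"))

setMethod("show", "AssocResult", function(object) {
    cat(sprintf("AssocResult [%s, %d df] %s\n", object@test, object@df,
                object@term))
    if (!is.na(object@oddsRatio))
        cat(sprintf("  OR %.3f (%.3f-%.3f)\n", object@oddsRatio,
                    object@ciLow, object@ciHigh))
    cat(sprintf("  p = %s\n", format(object@p, digits = 4)))
    if (length(object@adjustedFor))
        cat("  adjusted for:", paste(object@adjustedFor, collapse = ", "), "\n")
    if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Class "PermutationResult": minimum global-test p-values over permutations
#'
#' @slot B replicate count.
#' @slot seed master seed.
#' @slot minP per-replicate minimum global-test p-value (NA when every
#'   window failed in that replicate).
#' @slot nWindows number of windows contributing to each minimum.
#' @seealso \code{\link{permutationMinP}}, \code{\link{calibrateScan}}
#' @export
setClass("PermutationResult", representation(
    B = "integer", seed = "integer", minP = "numeric", nWindows = "integer"))

setValidity("PermutationResult", function(object) {
    if (length(object@minP) != object@B)
        return("length(minP) must equal B")
    p <- object@minP[!is.na(object@minP)]
    if (any(p <= 0 | p > 1))
        return("minimum p-values must lie in (0, 1]")
    TRUE
})

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult: B =", object@B, "replicates over",
        object@nWindows, "windows\n")
    cat("  min p range:", format(range(object@minP, na.rm = TRUE)), "\n")
})

#' Class "BetaFit": maximum-likelihood beta-distribution fit
#'
#' @slot a,b fitted shape parameters.
#' @slot loglik log-likelihood at the fit.
#' @slot constrainedA1 was the first shape constrained to 1?
#' @seealso \code{\link{fitBetaMle}}
#' @export
setClass("BetaFit", representation(
    a = "numeric", b = "numeric", loglik = "numeric",
    constrainedA1 = "logical"))

setValidity("BetaFit", function(object) {
    if (object@a <= 0 || object@b <= 0)
        return("shape parameters must be positive")
    TRUE
})

setMethod("show", "BetaFit", function(object) {
    cat(sprintf("BetaFit: a = %.4f%s, b = %.2f, loglik = %.3f\n",
                object@a, if (object@constrainedA1) " (fixed)" else "",
                object@b, object@loglik))
})

#' Class "GofResult": EDF goodness-of-fit statistics against a beta law
#'
#' Kolmogorov-Smirnov, Cramer-von Mises and Anderson-Darling statistics
#' with asymptotic p-values for a fully specified null.
#'
#' @slot statistics named numeric (ks, cvm, ad).
#' @slot pValues named numeric (ks, cvm, ad).
#' @seealso \code{\link{edfGof}}
#' @export
setClass("GofResult", representation(
    statistics = "numeric", pValues = "numeric"))

setMethod("show", "GofResult", function(object) {
    cat("EDF goodness of fit\n")
    for (k in names(object@statistics))
        cat(sprintf("  %-4s stat = %.4f  p = %s\n", k,
                    object@statistics[[k]],
                    format(object@pValues[[k]], digits = 4)))
})

#' Class "CalibrationResult": permutation-calibrated significance thresholds
#'
#' @slot thresholdT empirical percentile of the minimum p-values (the
#'   permutation-based chromosome-wide threshold).
#' @slot neffPercentile effective test count 0.05 / t.
#' @slot neffPercentileExact exact Beta(1, n) inversion log(0.95)/log(1-t).
#' @slot neffMle constrained-MLE estimate (Beta(1, b) fit).
#' @slot neffHalf half the window count, rounded half away from zero.
#' @slot neffSource which estimate feeds \code{alphaChromosome}.
#' @slot alphaChromosome 0.05 / n_eff.
#' @slot alphaGenome 0.05 / (ratio x total genome windows).
#' @slot betaConstrained,betaFree the two \linkS4class{BetaFit}s.
#' @seealso \code{\link{calibrateScan}}
#' @export
setClass("CalibrationResult", representation(
    thresholdT = "numeric",
    neffPercentile = "numeric",
    neffPercentileExact = "numeric",
    neffMle = "numeric",
    neffHalf = "numeric",
    neffSource = "character",
    alphaChromosome = "numeric",
    alphaGenome = "numeric",
    betaConstrained = "ANY",
    betaFree = "ANY"))

setMethod("show", "CalibrationResult", function(object) {
    cat("Permutation calibration\n")
    cat("  threshold t (empirical percentile):",
        format(object@thresholdT, digits = 4), "\n")
    cat(sprintf("  n_eff: percentile %.1f (exact %.1f), MLE %.1f, half %d\n",
                object@neffPercentile, object@neffPercentileExact,
                object@neffMle, as.integer(object@neffHalf)))
    cat(sprintf("  alpha (chromosome, via %s) = %s\n", object@neffSource,
                format(object@alphaChromosome, digits = 4)))
    cat("  alpha (genome) =", format(object@alphaGenome, digits = 4), "\n")
})
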