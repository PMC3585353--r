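# Permutation analysis of minimum global-test p-values, beta-distribution
# fitting of the minima, and the effective number of independent tests.

#' Permute case-control labels
#'
#' Each replicate is a uniform random permutation of the label vector, so
#' the case and control counts are preserved exactly. Per-replicate
#' sub-seeds are derived from the master seed, making any replicate
#' reproducible on its own.
#'
#' @param labels 0/1 vector.
#' @param B number of replicates.
#' @param seed master seed.
#' @return n x B integer matrix of permuted labels.
#' @export
permuteLabels <- function(labels, B, seed) {
    stopifnot(B >= 1L)
    seeds <- deriveSeeds(seed, B)
    out <- matrix(0L, nrow = length(labels), ncol = B)
    for (b in seq_len(B))
        out[, b] <- withSeed(seeds[b], sample(labels))
    out
}

#' Minimum global-test p-values over label permutations
#'
#' Runs the sliding-window global haplotype test on \code{B} phenotype
#' permutations and records each replicate's minimum p-value. Haplotype
#' inference is phenotype-free, so the per-window E-M dosages are computed
#' once and every replicate refits only the logistic models (covariates
#' unchanged). Windows that cannot be tested (monomorphic, unconverged,
#' fewer than two common haplotypes) are excluded from the minima; a
#' replicate in which every window fails is recorded as \code{NA} with a
#' message.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with phenotypes.
#' @param covariates covariate data.frame (default: from \code{gm}).
#' @param w window size in SNPs (default 5).
#' @param B replicate count.
#' @param seed master seed.
#' @param freqThreshold common-haplotype cutoff (default 0.01).
#' @param permutations optional precomputed n x B label matrix (overrides
#'   \code{B} and \code{seed}); used mainly for testing.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationMinP <- function(gm, covariates = covariateTable(gm), w = 5L,
                            B = 1000L, seed = 1L, freqThreshold = 0.01,
                            permutations = NULL) {
    labels <- phenotype(gm)
    if (anyNA(labels))
        stop("permutationMinP: missing phenotypes", call. = FALSE)
    wd <- windowDesigns(gm, w = w, freqThreshold = freqThreshold)
    ok <- which(wd$windows$status == "ok")
    if (length(ok) == 0L)
        stop("permutationMinP: no testable windows", call. = FALSE)
    Y <- if (is.null(permutations))
        permuteLabels(labels, B, seed)
    else {
        B <- ncol(permutations)
        permutations
    }
    covX <- covariateDesign(covariates, n = length(labels))
    assertFullRank(covX, "covariate design")
    P <- cpp_perm_scan(covX, wd$dosage[ok], Y,
                       wd$windows$df[ok])
    mp <- apply(P, 1L, function(r)
        if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
    if (anyNA(mp))
        message("permutationMinP: ", sum(is.na(mp)),
                " replicate(s) had no testable window and are NA")
    new("PermutationResult", B = as.integer(B), seed = as.integer(seed),
        minP = as.numeric(mp), nWindows = length(ok))
}

#' Maximum-likelihood beta-distribution fit
#'
#' Fits Beta(a, b) to values strictly inside (0, 1). With
#' \code{constrainA1 = TRUE} the first shape is fixed at 1, for which the
#' MLE is closed form: \code{b = -n / sum(log(1 - p))}. Otherwise both
#' shapes are free and the digamma score equations are solved by Newton
#' iteration (method-of-moments start, tolerance 1e-10, fallback to
#' quasi-Newton optimization of the log-likelihood).
#'
#' For n independent uniform p-values, the minimum follows Beta(1, n), so
#' the constrained fit to minimum p-values estimates the effective number
#' of independent tests.
#'
#' @param pvals numeric vector in (0, 1), length >= 2 (length 1 permitted
#'   for the constrained fit).
#' @param constrainA1 fix the first shape at 1?
#' @return a \linkS4class{BetaFit}.
#' @examples
#' fitBetaMle(1 - exp(-1), constrainA1 = TRUE)   # b = 1
#' @export
fitBetaMle <- function(pvals, constrainA1 = FALSE) {
    p <- as.numeric(pvals)
    if (any(p <= 0 | p >= 1))
        stop("fitBetaMle: values must lie strictly inside (0, 1)",
             call. = FALSE)
    n <- length(p)
    if (constrainA1) {
        b <- -n / sum(log1p(-p))
        ll <- sum(dbeta(p, 1, b, log = TRUE))
        return(new("BetaFit", a = 1, b = b, loglik = ll,
                   constrainedA1 = TRUE))
    }
    stopifnot(n >= 2L)
    s1 <- sum(log(p)); s2 <- sum(log1p(-p))
    m <- mean(p); v <- stats::var(p)
    v <- max(v, 1e-12)
    common <- max(m * (1 - m) / v - 1, 1e-3)
    th <- c(max(m * common, 1e-3), max((1 - m) * common, 1e-3))
    score <- function(th) c(
        n * (digamma(sum(th)) - digamma(th[1])) + s1,
        n * (digamma(sum(th)) - digamma(th[2])) + s2)
    ok <- FALSE
    for (it in 1:200) {
        s <- score(th)
        if (max(abs(s)) / n < 1e-10) { ok <- TRUE; break }
        tg <- trigamma(sum(th))
        J <- matrix(c(n * (tg - trigamma(th[1])), n * tg,
                      n * tg, n * (tg - trigamma(th[2]))), 2, 2)
        step <- tryCatch(solve(J, -s), error = function(e) NULL)
        if (is.null(step)) break
        fac <- 1
        while (any(th + fac * step <= 0) && fac > 1e-8) fac <- fac / 2
        thNew <- th + fac * step
        if (max(abs(thNew - th)) < 1e-12) { th <- thNew; ok <- TRUE; break }
        th <- thNew
    }
    if (!ok) {
        nll <- function(lt) -sum(dbeta(p, exp(lt[1]), exp(lt[2]),
                                       log = TRUE))
        opt <- stats::optim(log(th), nll, method = "BFGS",
                            control = list(reltol = 1e-14))
        th <- exp(opt$par)
    }
    ll <- sum(dbeta(p, th[1], th[2], log = TRUE))
    new("BetaFit", a = th[1], b = th[2], loglik = ll, constrainedA1 = FALSE)
}

# Asymptotic upper-tail of the Cramer-von Mises statistic (fully
# specified null), via the classical Bessel-function series.
cvmPvalue <- function(x) {
    if (x <= 0) return(1)
    if (x > 10) return(0)
    j <- 0:10
    a <- (4 * j + 1)^2 / (16 * x)
    terms <- exp(lgamma(j + 0.5) - lgamma(0.5) - lgamma(j + 1)) *
        sqrt(4 * j + 1) * exp(-2 * a) * besselK(a, 0.25,
                                                expon.scaled = TRUE)
    Fx <- sum(terms) / (pi * sqrt(x))
    min(max(1 - Fx, 0), 1)
}

# Asymptotic upper-tail of the Anderson-Darling statistic
# (Marsaglia & Marsaglia polynomial approximation, fully specified null).
adPvalue <- function(z) {
    if (z <= 0) return(1)
    if (z < 2)
        p <- 1 - exp(-1.2337141 / z) / sqrt(z) *
            (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
                (0.011672 - 0.00168691 * z) * z) * z) * z) * z)
    else
        p <- 1 - exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
                (0.008056 - 0.0003146 * z) * z) * z) * z) * z))
    min(max(p, 0), 1)
}

#' EDF goodness-of-fit tests against a fully specified beta distribution
#'
#' Transforms the values through the candidate beta CDF (regularized
#' incomplete beta function) and tests the transforms for uniformity with
#' the Kolmogorov-Smirnov D, Cramer-von Mises W-squared and
#' Anderson-Darling A-squared statistics, using the standard asymptotic
#' p-values for a fully specified null (no parameters estimated from the
#' data).
#'
#' @param pvals numeric vector in (0, 1).
#' @param a,b beta shape parameters of the candidate distribution.
#' @return a \linkS4class{GofResult}.
#' @export
edfGof <- function(pvals, a, b) {
    stopifnot(a > 0, b > 0, all(pvals > 0 & pvals < 1))
    u <- sort(pbeta(pvals, a, b))
    n <- length(u)
    i <- seq_len(n)
    D <- max(i / n - u, u - (i - 1) / n)
    ksP <- suppressWarnings(ks.test(u, "punif", exact = FALSE)$p.value)
    W2 <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
    uc <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    A2 <- -n - mean((2 * i - 1) * (log(uc) + log(1 - rev(uc))))
    new("GofResult",
        statistics = c(ks = D, cvm = W2, ad = A2),
        pValues = c(ks = ksP, cvm = cvmPvalue(W2), ad = adPvalue(A2)))
}

#' Calibrate significance thresholds from permutation minima
#'
#' Computes the permutation-based chromosome-wide threshold (the
#' \code{percentile} order statistic of the minimum p-values, taken at
#' position \code{ceiling(percentile * B)} of the ascending sort) and
#' three estimates of the effective number of independent tests:
#' the percentile ratio \code{0.05 / t} (with the exact Beta(1, n)
#' inversion \code{log(0.95) / log(1 - t)} alongside), the constrained
#' Beta(1, b) maximum-likelihood estimate, and half the number of windows
#' (rounded half away from zero). The chromosome-wide level is
#' \code{0.05 / n_eff} for the chosen source, and the genome-wide level is
#' \code{0.05 / (ratio * totalWindowsGenome)}.
#'
#' @param pr a \linkS4class{PermutationResult}.
#' @param totalWindowsGenome total sliding-window count genome-wide.
#' @param percentile type-I error rate of the chromosome-wide threshold
#'   (default 0.05).
#' @param ratio fraction of genome-wide windows treated as independent
#'   (default 1/2).
#' @param neffSource which estimate drives \code{alphaChromosome}:
#'   "half" (default), "mle" or "percentile".
#' @return a \linkS4class{CalibrationResult}.
#' @export
calibrateScan <- function(pr, totalWindowsGenome, percentile = 0.05,
                          ratio = 0.5,
                          neffSource = c("half", "mle", "percentile")) {
    neffSource <- match.arg(neffSource)
    mp <- sort(pr@minP[!is.na(pr@minP)])
    stopifnot(length(mp) >= 1L)
    t <- mp[ceiling(percentile * length(mp))]
    neffPct <- percentile / t
    neffPctExact <- log(1 - percentile) / log(1 - t)
    bc <- fitBetaMle(pmin(pmax(mp, 1e-300), 1 - 1e-16), constrainA1 = TRUE)
    bf <- if (length(mp) >= 2L)
        fitBetaMle(pmin(pmax(mp, 1e-300), 1 - 1e-16)) else NULL
    neffHalf <- floor(pr@nWindows / 2 + 0.5)
    neff <- switch(neffSource, half = neffHalf, mle = bc@b,
                   percentile = neffPct)
    new("CalibrationResult",
        thresholdT = t,
        neffPercentile = neffPct,
        neffPercentileExact = neffPctExact,
        neffMle = bc@b,
        neffHalf = neffHalf,
        neffSource = neffSource,
        alphaChromosome = 0.05 / neff,
        alphaGenome = 0.05 / (ratio * totalWindowsGenome),
        betaConstrained = bc,
        betaFree = bf)
}
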