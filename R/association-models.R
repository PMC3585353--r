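# Expectation-substitution logistic association tests: haplotype-specific
# Wald tests, the global multi-haplotype likelihood-ratio test, and
# LR tests of a haplotype conditional on single-SNP effects.

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial-logit model by iteratively reweighted least squares
#' (Newton scoring with step-halving). Convergence is declared when the
#' log-likelihood changes by less than \code{tol}; quasi-complete
#' separation is flagged (\code{converged = FALSE}) when any coefficient
#' exceeds 30 in absolute value. A rank-deficient design is an error that
#' names the redundant column.
#'
#' @param labels 0/1 response vector (at least one case and one control).
#' @param design numeric samples x terms matrix including the intercept
#'   column.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxIter iteration cap.
#' @return list with components \code{coefficients}, \code{se} (named),
#'   \code{loglik}, \code{nIter}, \code{converged}, \code{nSamples}.
#' @examples
#' X <- cbind(1, c(rep(0, 50), rep(1, 50)))
#' y <- rbinom(100, 1, plogis(X[, 2]))
#' fitLogistic(y, X)$coefficients
#' @export
fitLogistic <- function(labels, design, tol = 1e-8, maxIter = 50L) {
    y <- as.numeric(labels)
    X <- as.matrix(design)
    storage.mode(X) <- "double"
    stopifnot(length(y) == nrow(X))
    if (anyNA(y) || anyNA(X))
        stop("fitLogistic: missing values in response or design",
             call. = FALSE)
    if (sum(y == 1) < 1L || sum(y == 0) < 1L)
        stop("fitLogistic: need at least one case and one control",
             call. = FALSE)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    assertFullRank(X)
    f <- cpp_irls(X, y, tol, as.integer(maxIter))
    list(coefficients = setNames(as.numeric(f$coefficients), colnames(X)),
         se = setNames(as.numeric(f$se), colnames(X)),
         loglik = f$loglik,
         nIter = f$iter,
         converged = f$converged,
         nSamples = length(y))
}

.assocResult <- function(term, beta = NA_real_, se = NA_real_, p = NA_real_,
                         df = 1L, test = "wald", lrStat = NA_real_,
                         adjustedFor = character(0), converged = TRUE,
                         note = "") {
    or <- exp(beta)
    new("AssocResult", term = term, beta = beta, se = se,
        oddsRatio = or, ciLow = exp(beta - 1.959963984540054 * se),
        ciHigh = exp(beta + 1.959963984540054 * se),
        p = p, df = as.integer(df), test = test, lrStat = lrStat,
        adjustedFor = adjustedFor, converged = converged, note = note)
}

#' Haplotype-specific association test
#'
#' Expectation-substitution test of one haplotype: the expected dosage
#' E[n_h | G] enters a covariate-adjusted logistic model as a per-copy
#' additive term; significance is a 1-df Wald test of its coefficient
#' (likelihood-ratio by \code{test = "lr"}), with per-copy odds ratio
#' \code{exp(beta)} and symmetric 95 percent confidence bounds.
#'
#' @param dosage per-sample expected haplotype dosage in [0, 2].
#' @param covariates covariate data.frame (or \code{NULL}).
#' @param labels 0/1 case-control vector.
#' @param test "wald" (default) or "lr".
#' @param term label for the tested haplotype.
#' @return an \linkS4class{AssocResult}.
#' @export
haplotypeSpecificTest <- function(dosage, covariates, labels,
                                  test = c("wald", "lr"),
                                  term = "haplotype") {
    test <- match.arg(test)
    stopifnot(all(dosage >= -1e-9 & dosage <= 2 + 1e-9, na.rm = TRUE))
    covX <- covariateDesign(covariates, n = length(labels))
    X <- cbind(covX, dosage = dosage)
    fit <- fitLogistic(labels, X)
    b <- fit$coefficients[["dosage"]]
    s <- fit$se[["dosage"]]
    if (test == "wald") {
        z <- b / s
        p <- 2 * pnorm(-abs(z))
        .assocResult(term, beta = b, se = s, p = max(p, .Machine$double.xmin),
                     df = 1L, test = "wald", converged = fit$converged)
    } else {
        fit0 <- fitLogistic(labels, covX)
        stat <- max(0, 2 * (fit$loglik - fit0$loglik))
        p <- pchisq(stat, df = 1, lower.tail = FALSE)
        .assocResult(term, beta = b, se = s, p = max(p, .Machine$double.xmin),
                     df = 1L, test = "lr", lrStat = stat,
                     converged = fit$converged && fit0$converged)
    }
}

# Internal: indices of common haplotypes and the reference (most frequent,
# ties broken by lexicographically smallest allele string).
commonHapIndices <- function(hs, freqThreshold) {
    common <- which(hs@freqs > freqThreshold)
    if (length(common) <= 1L)
        return(list(common = common, ref = common, nonref = integer(0)))
    fm <- max(hs@freqs[common])
    cand <- common[hs@freqs[common] >= fm - 1e-15]
    ref <- cand[order(hs@haplotypes[cand])][1L]
    list(common = common, ref = ref, nonref = setdiff(common, ref))
}

#' Global multi-haplotype test for one window
#'
#' Joint likelihood-ratio test of all common haplotypes in a window:
#' haplotypes with frequency strictly above \code{freqThreshold} are kept,
#' the most frequent is the reference (its dosage column is excluded), and
#' the remaining k-1 dosage terms are tested jointly against the
#' covariates-only model on k-1 degrees of freedom.
#'
#' @param hs a \linkS4class{HaplotypeSet} from \code{\link{emFit}}.
#' @param covariates covariate data.frame (or \code{NULL}).
#' @param labels 0/1 case-control vector aligned with the dosage rows.
#' @param freqThreshold common-haplotype frequency cutoff (strict ">",
#'   default 0.01).
#' @return an \linkS4class{AssocResult}; when fewer than two haplotypes
#'   are common the result carries \code{df = 0}, \code{p = NA} and
#'   \code{note = "df0"}.
#' @export
globalHaplotypeTest <- function(hs, covariates, labels,
                                freqThreshold = 0.01) {
    ch <- commonHapIndices(hs, freqThreshold)
    k <- length(ch$common)
    if (k <= 1L)
        return(.assocResult("global", p = NA_real_, df = 0L, test = "lr",
                            note = "df0"))
    D <- hs@dosages[, ch$nonref, drop = FALSE]
    colnames(D) <- paste0("hap_", hs@haplotypes[ch$nonref])
    keep <- complete.cases(D)
    y <- labels[keep]
    covX <- covariateDesign(covariates, n = length(labels))[keep, , drop = FALSE]
    fit0 <- fitLogistic(y, covX)
    fit1 <- fitLogistic(y, cbind(covX, D[keep, , drop = FALSE]))
    stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
    df <- k - 1L
    p <- pchisq(stat, df = df, lower.tail = FALSE)
    .assocResult("global", p = max(p, .Machine$double.xmin), df = df,
                 test = "lr", lrStat = stat,
                 converged = fit0$converged && fit1$converged)
}

#' Likelihood-ratio test of a haplotype adjusted for SNP effects
#'
#' Tests whether a haplotype effect persists after conditioning on
#' additively coded single-SNP effects: the full model carries the
#' haplotype dosage, the adjustment SNPs and the covariates; the nested
#' model drops only the dosage. The 1-df LR p-value and the adjusted
#' per-copy OR (Wald interval from the full model) are reported. When the
#' dosage is numerically collinear with the adjustment set the LR
#' statistic is reported as 0 with \code{note = "collinear"}.
#'
#' @param dosage per-sample expected haplotype dosage.
#' @param adjustSnps matrix (samples x SNPs) of additive genotype codes, or
#'   \code{NULL}/zero columns for no adjustment.
#' @param covariates covariate data.frame (or \code{NULL}).
#' @param labels 0/1 case-control vector.
#' @param term label for the tested haplotype.
#' @return an \linkS4class{AssocResult} with \code{adjustedFor} naming the
#'   adjustment SNPs.
#' @export
snpAdjustedLrTest <- function(dosage, adjustSnps, covariates, labels,
                              term = "haplotype") {
    covX <- covariateDesign(covariates, n = length(labels))
    A <- if (is.null(adjustSnps)) NULL else as.matrix(adjustSnps)
    if (!is.null(A) && ncol(A) == 0L) A <- NULL
    adjNames <- if (is.null(A)) character(0) else
        (colnames(A) %||% paste0("snp", seq_len(ncol(A))))
    X0 <- if (is.null(A)) covX else cbind(covX, A)
    keep <- complete.cases(cbind(X0, dosage))
    X0 <- X0[keep, , drop = FALSE]
    d <- dosage[keep]
    y <- labels[keep]
    if (isCollinearWith(X0, d)) {
        out <- .assocResult(term, p = 1, df = 1L, test = "lr", lrStat = 0,
                            adjustedFor = adjNames, note = "collinear")
        return(out)
    }
    fit0 <- fitLogistic(y, X0)
    X1 <- cbind(X0, dosage = d)
    fit1 <- fitLogistic(y, X1)
    stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    b <- fit1$coefficients[["dosage"]]
    s <- fit1$se[["dosage"]]
    .assocResult(term, beta = b, se = s, p = max(p, .Machine$double.xmin),
                 df = 1L, test = "lr", lrStat = stat,
                 adjustedFor = adjNames,
                 converged = fit0$converged && fit1$converged)
}
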