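# E-M estimation of within-window haplotype frequencies and expected
# per-individual haplotype dosages from unphased genotypes, assuming
# Hardy-Weinberg equilibrium. Cases and controls are pooled.

bitsToKey <- function(bits) paste(bits, collapse = "")

bitsToString <- function(bits, alleles) {
    paste(ifelse(bits == 1L, alleles[1L, ], alleles[2L, ]), collapse = "")
}

defaultAlleles <- function(w) {
    matrix(rep(c("1", "2"), w), nrow = 2L,
           dimnames = list(c("allele1", "allele2"), NULL))
}

#' Enumerate haplotype pairs compatible with an unphased genotype
#'
#' Lists every unordered pair of haplotypes whose per-SNP allele-count sums
#' reproduce the observed genotype vector. Haplotypes are 0/1 vectors
#' (1 = carries allele1). Heterozygous sites double the pair count (the
#' first heterozygous site is fixed to break the phase symmetry, giving
#' \code{2^(m-1)} pairs for \code{m} heterozygous sites); missing sites are
#' expanded over all three genotype completions.
#'
#' When the enumeration would exceed \code{maxPairs} the sample is flagged
#' as too ambiguous and an empty list with attribute \code{flagged = TRUE}
#' is returned.
#'
#' @param genotype integer vector over one window, values 0/1/2/\code{NA}.
#' @param maxPairs ambiguity bound (default \code{2^20}).
#' @return list of pairs; each element is \code{list(h1 =, h2 =)} of 0/1
#'   integer vectors with \code{h1 >= h2} lexicographically.
#' @examples
#' length(enumerateCompatiblePairs(c(2, 0, 1)))   # one het site: 1 pair
#' length(enumerateCompatiblePairs(c(1, 1, 1)))   # three het sites: 4 pairs
#' @export
enumerateCompatiblePairs <- function(genotype, maxPairs = 2^20) {
    g <- as.integer(genotype)
    w <- length(g)
    stopifnot(w >= 1L)
    nNA <- sum(is.na(g))
    nHet <- sum(g == 1L, na.rm = TRUE)
    # ordered assignments: 2 per het, 4 per missing site
    if (nHet + 2 * nNA > log2(maxPairs) + 1) {
        out <- list()
        attr(out, "flagged") <- TRUE
        return(out)
    }
    naIdx <- which(is.na(g))
    completions <- if (length(naIdx) == 0L) list(g) else {
        grid <- expand.grid(rep(list(0:2), length(naIdx)))
        lapply(seq_len(nrow(grid)), function(r) {
            gi <- g
            gi[naIdx] <- as.integer(grid[r, ])
            gi
        })
    }
    pairs <- list()
    for (gc in completions) {
        het <- which(gc == 1L)
        base <- integer(w)
        base[gc == 2L] <- 1L
        m <- length(het)
        if (m == 0L) {
            pairs[[length(pairs) + 1L]] <- list(h1 = base, h2 = base)
        } else {
            free <- het[-1L]
            for (code in 0:(2^(m - 1L) - 1L)) {
                h1 <- base; h2 <- base
                h1[het[1L]] <- 1L
                if (m > 1L) {
                    bits <- as.integer(intToBits(code))[seq_len(m - 1L)]
                    h1[free] <- bits
                    h2[free] <- 1L - bits
                }
                pairs[[length(pairs) + 1L]] <- list(h1 = h1, h2 = h2)
            }
        }
    }
    attr(pairs, "flagged") <- FALSE
    pairs
}

# Group genotype rows into unique patterns and enumerate each pattern's
# compatible pairs against a shared haplotype universe. Internal.
windowPatterns <- function(calls, maxPairs = 2^20) {
    n <- nrow(calls)
    keys <- apply(calls, 1L, function(r) paste(r, collapse = ","))
    uk <- unique(keys)
    patOf <- match(keys, uk)
    hapKey <- character(0)
    hapBits <- list()
    pat <- vector("list", length(uk))
    flagged <- logical(length(uk))
    for (p in seq_along(uk)) {
        g <- calls[match(p, patOf), ]
        prs <- enumerateCompatiblePairs(g, maxPairs)
        if (isTRUE(attr(prs, "flagged")) || length(prs) == 0L) {
            flagged[p] <- TRUE
            next
        }
        i1 <- integer(length(prs)); i2 <- integer(length(prs))
        for (k in seq_along(prs)) {
            for (side in 1:2) {
                b <- prs[[k]][[side]]
                key <- bitsToKey(b)
                j <- match(key, hapKey)
                if (is.na(j)) {
                    hapKey <- c(hapKey, key)
                    hapBits[[length(hapBits) + 1L]] <- b
                    j <- length(hapKey)
                }
                if (side == 1L) i1[k] <- j else i2[k] <- j
            }
        }
        pat[[p]] <- list(i1 = i1, i2 = i2, mult = ifelse(i1 == i2, 1, 2))
    }
    list(patOf = patOf, patterns = pat, flagged = flagged,
         hapBits = if (length(hapBits))
             do.call(rbind, hapBits) else matrix(0L, 0L, ncol(calls)))
}

#' Fit haplotype frequencies and dosages by the E-M algorithm
#'
#' Maximum-likelihood haplotype frequencies for one window of unphased
#' genotypes under Hardy-Weinberg equilibrium, with the expected number of
#' copies of each haplotype per individual, E[n_h | G], evaluated at the
#' fitted frequencies. The E-step weights each pair (h1, h2) compatible
#' with an individual's genotype by \code{f_h1 f_h2} (doubled for
#' heterozygous pairs) and normalizes within individual; the M-step sets
#' each frequency to the mean expected dosage over individuals divided
#' by two. Frequencies are initialized from the product of observed
#' per-SNP allele frequencies (lightly smoothed so every compatible
#' haplotype starts with positive mass) and iterated until the largest
#' absolute frequency change drops below \code{tol}.
#'
#' Samples whose compatible-pair enumeration exceeds \code{maxPairs}
#' (possible only with many missing sites) are dropped from the window and
#' reported in \code{droppedSamples}. Haplotypes whose final frequency
#' falls below \code{pruneTol} are pruned.
#'
#' @param calls samples x SNPs genotype matrix for the window (0/1/2/NA,
#'   copies of allele1).
#' @param alleles optional 2 x w character matrix of allele codes used to
#'   label haplotypes (row 1 = allele1); defaults to codes "1"/"2".
#' @param tol convergence tolerance on max |change in f| (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @param maxPairs per-sample ambiguity bound (default 2^20).
#' @param pruneTol frequency below which haplotypes are pruned.
#' @param fixedFreqs optional named frequency vector (names are haplotype
#'   allele strings). When given, no iteration is performed: the E-step
#'   dosages and the observed-data log-likelihood are evaluated at these
#'   frequencies (haplotypes absent from the names get frequency zero).
#' @return a \linkS4class{HaplotypeSet}.
#' @examples
#' calls <- rbind(c(2, 2), c(0, 0), c(1, 1), c(1, 1))
#' hs <- emFit(calls)
#' hapFreqs(hs)
#' @export
emFit <- function(calls, alleles = NULL, tol = 1e-8, maxIter = 1000L,
                  maxPairs = 2^20, pruneTol = 1e-12, fixedFreqs = NULL) {
    calls <- as.matrix(calls)
    w <- ncol(calls)
    n <- nrow(calls)
    if (is.null(alleles)) alleles <- defaultAlleles(w)
    if (is.null(rownames(calls))) rownames(calls) <- as.character(seq_len(n))
    wp <- windowPatterns(calls, maxPairs)
    retained <- !wp$flagged[wp$patOf]
    dropped <- rownames(calls)[!retained]
    nRet <- sum(retained)
    if (nRet == 0L)
        stop("emFit: no retained samples in window", call. = FALSE)
    H <- nrow(wp$hapBits)
    patCount <- tabulate(wp$patOf[retained], nbins = length(wp$patterns))
    live <- which(patCount > 0L & !wp$flagged)

    # flatten pair lists for vectorized iterations
    I1 <- integer(0); I2 <- integer(0); MULT <- numeric(0); PAT <- integer(0)
    for (p in live) {
        pp <- wp$patterns[[p]]
        I1 <- c(I1, pp$i1); I2 <- c(I2, pp$i2)
        MULT <- c(MULT, pp$mult); PAT <- c(PAT, rep(p, length(pp$i1)))
    }
    CNT <- patCount

    # initialization: product of per-SNP allele-1 frequencies, smoothed
    tot1 <- colSums(calls[retained, , drop = FALSE], na.rm = TRUE)
    nObs <- colSums(!is.na(calls[retained, , drop = FALSE]))
    p1 <- (tot1 + 0.5) / (2 * nObs + 1)
    f <- exp(wp$hapBits %*% log(p1) + (1 - wp$hapBits) %*% log(1 - p1))
    f <- as.numeric(f / sum(f))

    hapStrings <- apply(wp$hapBits, 1L, bitsToString, alleles = alleles)
    # deterministic symmetry-breaking: the allele-frequency-product start
    # can sit exactly on a saddle between phase-symmetric optima; a tiny
    # canonical (lexicographic-rank) tilt lets the iteration leave it
    # without introducing randomness or sample-order dependence
    f <- f * (1 + 1e-3 * (rank(hapStrings) / length(hapStrings))^2)
    f <- f / sum(f)
    patIdx <- sort(unique(PAT))
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    if (!is.null(fixedFreqs)) {
        f <- unname(ifelse(is.na(fixedFreqs[hapStrings]), 0,
                           fixedFreqs[hapStrings]))
        converged <- TRUE
        maxIter <- 0L
    }
    while (maxIter > 0L) {
        iter <- iter + 1L
        wts <- f[I1] * f[I2] * MULT
        denomByPat <- rowsum(wts, PAT)               # ordered by sort(unique(PAT))
        denom <- setNames(as.numeric(denomByPat), rownames(denomByPat))
        dPat <- denom[as.character(PAT)]
        dPat[dPat < 1e-300] <- 1e-300
        trace <- c(trace, sum(CNT[patIdx] * log(pmax(denom, 1e-300))))
        wn <- wts / dPat * CNT[PAT]
        numer <- rowsum(c(wn, wn), c(I1, I2))
        fNew <- numeric(H)
        fNew[as.integer(rownames(numer))] <- as.numeric(numer)
        fNew <- fNew / (2 * nRet)
        # keep every universe haplotype at a tiny positive mass: exact
        # zeros make pair weights underflow to 0, which silently removes
        # a sample's contribution when all its pairs involve such
        # haplotypes (the floor is far below pruneTol, so the reported
        # fit is unaffected)
        fNew <- pmax(fNew, 1e-150)
        delta <- max(abs(fNew - f))
        f <- fNew
        if (delta < tol) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }

    # final log-likelihood and per-pattern dosages at the fitted f
    wts <- f[I1] * f[I2] * MULT
    denomByPat <- rowsum(wts, PAT)
    denom <- setNames(as.numeric(denomByPat), rownames(denomByPat))
    loglik <- sum(CNT[patIdx] * log(pmax(denom, 1e-300)))
    dPat <- pmax(denom[as.character(PAT)], 1e-300)
    wr <- wts / dPat
    keyAgg <- (c(PAT, PAT) - 1) * H + c(I1, I2)
    agg <- rowsum(c(wr, wr), keyAgg)
    Epat <- matrix(0, nrow = length(wp$patterns), ncol = H)
    keys <- as.numeric(rownames(agg))
    Epat[cbind(((keys - 1) %/% H) + 1, ((keys - 1) %% H) + 1)] <-
        as.numeric(agg)

    keep <- which(f >= pruneTol)
    fKeep <- f[keep]
    dos <- matrix(NA_real_, nrow = n, ncol = length(keep),
                  dimnames = list(rownames(calls), NULL))
    dos[retained, ] <- Epat[wp$patOf[retained], keep, drop = FALSE]
    # pruning can shave a sliver of dosage mass off samples partly
    # explained by near-zero haplotypes; rescale rows back to total 2
    rs <- rowSums(dos)
    fixr <- which(!is.na(rs) & rs > 0)
    dos[fixr, ] <- dos[fixr, , drop = FALSE] * (2 / rs[fixr])
    haps <- apply(wp$hapBits[keep, , drop = FALSE], 1L, bitsToString,
                  alleles = alleles)
    o <- order(fKeep, decreasing = TRUE)
    new("HaplotypeSet",
        haplotypes = haps[o], freqs = fKeep[o],
        dosages = dos[, o, drop = FALSE],
        loglik = loglik, loglikTrace = trace,
        nIter = iter, converged = converged,
        droppedSamples = dropped)
}

#' Observed-data log-likelihood of haplotype frequencies for a window
#'
#' Evaluates the multinomial-HWE observed-data log-likelihood
#' \code{sum_i log sum_pairs f_h1 f_h2 (2 if h1 != h2)} over the haplotype
#' pairs compatible with each individual's genotype. Haplotypes absent
#' from \code{haplotypes} have frequency zero; a sample whose compatible
#' pairs all have zero probability contributes \code{-Inf} (its id is
#' reported in a message).
#'
#' @param freqs probabilities, one per element of \code{haplotypes}.
#' @param calls samples x SNPs genotype matrix (0/1/2/NA).
#' @param haplotypes allele strings the frequencies refer to.
#' @param alleles optional 2 x w allele-code matrix (as in
#'   \code{\link{emFit}}).
#' @return scalar log-likelihood (possibly \code{-Inf}).
#' @export
observedLoglik <- function(freqs, calls, haplotypes, alleles = NULL) {
    calls <- as.matrix(calls)
    w <- ncol(calls)
    if (is.null(alleles)) alleles <- defaultAlleles(w)
    stopifnot(length(freqs) == length(haplotypes))
    lut <- setNames(freqs, haplotypes)
    ll <- 0
    for (i in seq_len(nrow(calls))) {
        prs <- enumerateCompatiblePairs(calls[i, ])
        if (length(prs) == 0L) next
        li <- 0
        for (pr in prs) {
            s1 <- bitsToString(pr$h1, alleles)
            s2 <- bitsToString(pr$h2, alleles)
            f1 <- lut[s1]; f2 <- lut[s2]
            if (is.na(f1)) f1 <- 0
            if (is.na(f2)) f2 <- 0
            li <- li + f1 * f2 * (if (s1 == s2) 1 else 2)
        }
        if (li <= 0) {
            message("observedLoglik: zero likelihood for sample ",
                    rownames(calls)[i] %||% i)
            return(-Inf)
        }
        ll <- ll + log(li)
    }
    as.numeric(ll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
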