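# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately naive (enumeration, grid refinement,
# generic optimizers) and shares no code with the package internals it
# checks.

# Default allele labelling used by emFit when no allele codes are given:
# "1" = allele1, "2" = allele2.
bitsKey <- function(bits) paste(ifelse(bits == 1L, "1", "2"), collapse = "")

# All haplotype strings over w SNPs in the default labelling.
allHapStrings <- function(w) {
    g <- expand.grid(rep(list(c("1", "2")), w), stringsAsFactors = FALSE)
    apply(g[, rev(seq_len(w)), drop = FALSE], 1L, paste, collapse = "")
}

# Brute-force observed-data likelihood of a frequency vector: for each
# sample, enumerate every ordered haplotype pair over the full 2^w
# universe and keep the ones whose allele sums match the genotype.
bruteLoglik <- function(freqs, haps, calls) {
    w <- ncol(calls)
    hapBits <- t(vapply(strsplit(allHapStrings(w), ""),
                        function(z) as.integer(z == "1"), integer(w)))
    rownames(hapBits) <- allHapStrings(w)
    f <- setNames(rep(0, 2^w), allHapStrings(w))
    f[haps] <- freqs
    ll <- 0
    for (i in seq_len(nrow(calls))) {
        g <- calls[i, ]
        li <- 0
        for (a in seq_len(2^w)) for (b in seq_len(2^w)) {
            s <- hapBits[a, ] + hapBits[b, ]
            okv <- is.na(g) | s == g
            if (all(okv)) li <- li + f[a] * f[b]
        }
        if (li <= 0) return(-Inf)
        ll <- ll + log(li)
    }
    as.numeric(ll)
}

# Grid-search maximizer of the observed-data likelihood over the simplex
# of the full haplotype universe for a w-SNP window, by iterative grid
# refinement around the incumbent (start step 0.05, shrink x5 down to
# 1e-4). Returns the maximum log-likelihood found.
gridSearchMaxLoglik <- function(calls, w = ncol(calls)) {
    haps <- allHapStrings(w)
    K <- length(haps)
    center <- rep(1 / K, K)
    best <- bruteLoglik(center, haps, calls)
    step <- 0.05
    while (step >= 1e-4) {
        improved <- TRUE
        while (improved) {
            improved <- FALSE
            for (i in seq_len(K)) for (j in seq_len(K)) {
                if (i == j) next
                cand <- center
                if (cand[j] < step) next
                cand[i] <- cand[i] + step
                cand[j] <- cand[j] - step
                ll <- bruteLoglik(cand, haps, calls)
                if (ll > best + 1e-12) {
                    best <- ll
                    center <- cand
                    improved <- TRUE
                }
            }
        }
        step <- step / 5
    }
    best
}

# Generic-optimizer maximizer of the same likelihood (softmax
# parametrization, several random starts).
directMaxLoglik <- function(calls, w = ncol(calls), nStarts = 5L,
                            seed = 42L) {
    haps <- allHapStrings(w)
    K <- length(haps)
    nll <- function(theta) {
        f <- exp(theta - max(theta))
        f <- f / sum(f)
        -bruteLoglik(f, haps, calls)
    }
    best <- -Inf
    set.seed(seed)
    for (s in seq_len(nStarts)) {
        th0 <- if (s == 1L) rep(0, K) else rnorm(K)
        opt <- tryCatch(
            optim(th0, nll, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12)),
            error = function(e) NULL)
        if (!is.null(opt)) best <- max(best, -opt$value)
    }
    best
}

# Brute-force HWE exact test: conditional probabilities of every
# heterozygote count compatible with the observed allele counts, computed
# from the unnormalized weights 2^h / (n11! h! n22!), then two-sided
# summation.
bruteHweExact <- function(nHom1, nHet, nHom2) {
    n <- nHom1 + nHet + nHom2
    nA <- 2 * nHom1 + nHet
    nB <- 2 * nHom2 + nHet
    if (nA == 0 || nB == 0) return(1)
    hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
    logw <- vapply(hs, function(h) {
        h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
            lfactorial((nB - h) / 2)
    }, numeric(1))
    pr <- exp(logw - max(logw))
    pr <- pr / sum(pr)
    obs <- pr[hs == nHet]
    min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Small standard fixture: an 8-haplotype pool over 5 SNPs and a null
# cohort drawn from it.
smallPool <- function(seed = 7L) generateHaplotypePool(5L, 8L, seed = seed)

nullCohort <- function(n = 200L, seed = 11L, pool = smallPool()) {
    generateCohort(pool, n %/% 2L, n - n %/% 2L, DiseaseModel(),
                   seed = seed)
}

# emFit over a whole GenotypeMatrix with the map's allele codes, so the
# fitted haplotype strings are comparable with pool haplotypes.
emFitCohort <- function(gm, idx = NULL) {
    info <- snpInfo(gm)
    if (is.null(idx)) idx <- seq_len(nrow(info))
    emFit(genotypeCalls(gm)[, idx, drop = FALSE],
          alleles = rbind(info$allele1[idx], info$allele2[idx]))
}
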