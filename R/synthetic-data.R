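# Synthetic case-control cohorts with known haplotype structure, planted
# per-copy haplotype effects on the logit scale, covariates, and two-way
# admixture. Every downstream stage is validated against the ground truth
# these generators record.

# Default study mixture: nine case-control studies with the source
# cohort's relative sizes as sampling weights.
studyWeightsDefault <- c(MEC = 1737, CARE = 604, WCHS = 512, SFBCS = 403,
                         NCBCFR = 493, CBCS = 1264, PLCO = 197, NBHS = 496,
                         WFBC = 278) / 5984

# Age ~ U(35, 75); study ~ categorical over nine levels; ten standard
# normal principal-component stand-ins.
drawCovariates <- function(n) {
    data.frame(
        age = runif(n, 35, 75),
        study = factor(sample(names(studyWeightsDefault), n, replace = TRUE,
                              prob = studyWeightsDefault),
                       levels = names(studyWeightsDefault)),
        matrix(rnorm(n * 10L), nrow = n,
               dimnames = list(NULL, paste0("pc", 1:10))),
        stringsAsFactors = TRUE)
}

covariateContribution <- function(cov, effects) {
    if (length(effects) == 0L) return(numeric(nrow(cov)))
    mm <- model.matrix(~ ., data = cov)
    missing <- setdiff(names(effects), colnames(mm))
    if (length(missing))
        stop("covariateEffects name(s) not in the covariate design: ",
             paste(missing, collapse = ", "), call. = FALSE)
    as.numeric(mm[, names(effects), drop = FALSE] %*% effects)
}

# Which pool haplotypes carry the model's risk haplotype.
riskCarrierFlags <- function(pool, model) {
    if (model@riskHaplotype == "") return(rep(FALSE, length(pool@haplotypes)))
    sub <- substr(pool@haplotypes, model@riskStart, model@riskEnd)
    flags <- sub == model@riskHaplotype
    if (model@betaH != 0 && !any(flags))
        stop("risk haplotype not present in the pool", call. = FALSE)
    flags
}

defaultSnpMap <- function(nSnps, alleles, chrom = "1", spacingBp = 1000L,
                          offset = 0L) {
    data.frame(id = paste0("snp", offset + seq_len(nSnps)),
               chrom = chrom,
               bp = spacingBp * (offset + seq_len(nSnps)),
               allele1 = alleles[1L, ], allele2 = alleles[2L, ],
               stringsAsFactors = FALSE)
}

#' Generate a random haplotype pool
#'
#' Draws \code{nHaplotypes} distinct haplotypes over \code{nSnps}
#' biallelic SNPs (two distinct nucleotides sampled per SNP) with
#' Dirichlet(\code{dirichletConc}) population frequencies. Deterministic
#' given the seed.
#'
#' @param nSnps number of SNPs (>= 1).
#' @param nHaplotypes number of distinct haplotypes
#'   (2 <= nHaplotypes <= 2^nSnps).
#' @param dirichletConc Dirichlet concentration for the frequencies
#'   (default 1 = uniform on the simplex).
#' @param seed integer seed.
#' @param freqs optional explicit frequency vector (length
#'   \code{nHaplotypes}, summing to one) overriding the Dirichlet draw,
#'   for designs that pin a haplotype at a chosen frequency.
#' @return a \linkS4class{HaplotypePool}.
#' @examples
#' generateHaplotypePool(5, 8, seed = 7)
#' @export
generateHaplotypePool <- function(nSnps, nHaplotypes, dirichletConc = 1,
                                  seed, freqs = NULL) {
    nSnps <- as.integer(nSnps); nHaplotypes <- as.integer(nHaplotypes)
    stopifnot(nSnps >= 1L)
    if (nHaplotypes < 2L ||
        (nSnps < 31L && nHaplotypes > 2^nSnps))
        stop("infeasible nHaplotypes: need 2 <= nHaplotypes <= 2^nSnps",
             call. = FALSE)
    withSeed(seed, {
        alleles <- vapply(seq_len(nSnps), function(j)
            sample(c("A", "C", "G", "T"), 2L), character(2))
        rownames(alleles) <- c("allele1", "allele2")
        if (nSnps <= 24L) {
            codes <- sample.int(2^nSnps, nHaplotypes) - 1L
            bits <- vapply(codes, function(cd)
                as.integer(intToBits(cd))[seq_len(nSnps)], integer(nSnps))
            bits <- if (nSnps == 1L) matrix(bits, ncol = 1L) else t(bits)
        } else {
            bits <- matrix(0L, 0L, nSnps)
            while (nrow(bits) < nHaplotypes) {
                add <- matrix(as.integer(runif(nSnps * nHaplotypes) < 0.5),
                              ncol = nSnps)
                bits <- unique(rbind(bits, add))
            }
            bits <- bits[seq_len(nHaplotypes), , drop = FALSE]
        }
        if (is.null(freqs)) {
            freqs <- rgamma(nHaplotypes, shape = dirichletConc)
            freqs <- freqs / sum(freqs)
        } else {
            stopifnot(length(freqs) == nHaplotypes,
                      abs(sum(freqs) - 1) < 1e-9)
        }
        haps <- apply(bits, 1L, bitsToString, alleles = alleles)
        new("HaplotypePool", nSnps = nSnps, alleles = alleles,
            haplotypes = haps, bits = bits, poolFreqs = freqs)
    })
}

# Rejection sampler shared by the single-pool and admixed generators.
# drawFun(m) must return list(callsPart, dose, cov, extra...) for m fresh
# individuals; disease status is Bernoulli(logit^-1(lp)).
rejectionSample <- function(nCases, nControls, model, drawFun,
                            maxAttempts = 1000L) {
    nTot <- nCases + nControls
    got <- list(); gotLab <- integer(0)
    needCase <- nCases; needCtrl <- nControls
    drawn <- 0L
    while (needCase > 0L || needCtrl > 0L) {
        m <- max(256L, 2L * (needCase + needCtrl))
        drawn <- drawn + m
        if (drawn > maxAttempts * nTot)
            stop("generation error: case/control counts unreachable ",
                 "under this disease model", call. = FALSE)
        d <- drawFun(m)
        lp <- model@intercept + model@betaH * d$dose +
            covariateContribution(d$cov, model@covariateEffects)
        y <- rbinom(m, 1L, plogis(lp))
        takeCase <- which(y == 1L)[seq_len(min(needCase, sum(y == 1L)))]
        takeCtrl <- which(y == 0L)[seq_len(min(needCtrl, sum(y == 0L)))]
        take <- c(takeCase, takeCtrl)
        if (length(take)) {
            got[[length(got) + 1L]] <- lapply(d, function(z)
                if (is.matrix(z)) z[take, , drop = FALSE]
                else if (is.data.frame(z)) z[take, , drop = FALSE]
                else z[take])
            gotLab <- c(gotLab, y[take])
            needCase <- needCase - length(takeCase)
            needCtrl <- needCtrl - length(takeCtrl)
        }
    }
    parts <- list()
    for (nm in names(got[[1L]]))
        parts[[nm]] <- if (is.data.frame(got[[1L]][[nm]]))
            do.call(rbind, lapply(got, `[[`, nm))
        else if (is.matrix(got[[1L]][[nm]]))
            do.call(rbind, lapply(got, `[[`, nm))
        else do.call(c, lapply(got, `[[`, nm))
    ord <- sample.int(length(gotLab))   # shuffle case/control runs
    parts <- lapply(parts, function(z)
        if (is.matrix(z) || is.data.frame(z)) z[ord, , drop = FALSE]
        else z[ord])
    parts$labels <- gotLab[ord]
    parts
}

#' Generate a case-control cohort from a haplotype pool
#'
#' Haplotype pairs are drawn independently per chromosome copy with the
#' pool frequencies (Hardy-Weinberg equilibrium); disease status follows
#' the logistic model given the true risk-haplotype dosage and the
#' generated covariates (age, nine-level study, ten ancestry
#' principal-component stand-ins); rejection sampling continues until the
#' exact case and control counts are reached. Genotypes are the unphased
#' allele-count sums of the two true haplotypes.
#'
#' @param pool a \linkS4class{HaplotypePool}.
#' @param nCases,nControls exact case and control counts.
#' @param model a \linkS4class{DiseaseModel}.
#' @param seed integer seed.
#' @param chrom chromosome label for the SNP map (default "1").
#' @param spacingBp inter-SNP spacing in bp for the synthetic map.
#' @param maxAttempts bound on rejection-sampling draws, as a multiple of
#'   the cohort size.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' pool <- generateHaplotypePool(5, 8, seed = 1)
#' model <- DiseaseModel(riskHaplotype = poolHaplotypes(pool)[1],
#'                       riskStart = 1, betaH = log(1.5))
#' cohort <- generateCohort(pool, 100, 100, model, seed = 2)
#' @export
generateCohort <- function(pool, nCases, nControls, model = DiseaseModel(),
                           seed, chrom = "1", spacingBp = 1000L,
                           maxAttempts = 1000L) {
    stopifnot(nCases + nControls >= 2L)
    carrier <- riskCarrierFlags(pool, model)
    H <- length(pool@haplotypes)
    withSeed(seed, {
        draw <- function(m) {
            idx <- matrix(sample.int(H, 2L * m, replace = TRUE,
                                     prob = pool@poolFreqs), ncol = 2L)
            dose <- carrier[idx[, 1L]] + carrier[idx[, 2L]]
            list(pairs = idx, dose = dose, cov = drawCovariates(m))
        }
        parts <- rejectionSample(nCases, nControls, model, draw,
                                 maxAttempts)
        calls <- pool@bits[parts$pairs[, 1L], , drop = FALSE] +
            pool@bits[parts$pairs[, 2L], , drop = FALSE]
        n <- nrow(calls)
        rownames(calls) <- sprintf("S%05d", seq_len(n))
        samples <- data.frame(sample_id = rownames(calls),
                              phenotype = parts$labels,
                              parts$cov, stringsAsFactors = TRUE)
        gm <- GenotypeMatrix(calls,
                             defaultSnpMap(pool@nSnps, pool@alleles,
                                           chrom, spacingBp),
                             samples, sort = FALSE)
        new("SyntheticCohort", genotypes = gm,
            truePairs = parts$pairs, pool = pool, model = model,
            localAncestry = NULL, seed = as.integer(seed))
    })
}

#' Generate an admixed case-control cohort
#'
#' Each chromosome copy is a Markov mosaic over two ancestral populations
#' A and B: between adjacent SNPs the ancestry is redrawn (A with the
#' sample's \code{admixtureProp}) with probability
#' \code{1 - exp(-switchRate * distance_bp / 1e6)}. Alleles are drawn from
#' the active pool's marginal per-SNP allele frequencies. The known-truth
#' local-ancestry track stores degenerate posterior triples for the number
#' of B ("European") allele copies at each SNP, and each sample's realized
#' B-ancestry fraction is recorded as covariate \code{globalB}.
#'
#' @param poolA,poolB \linkS4class{HaplotypePool}s sharing \code{nSnps}
#'   and allele codes.
#' @param switchRate ancestry switch rate per Mb.
#' @param admixtureProp probability that a chromosome segment is of A
#'   ancestry; scalar or per-sample (recycled over rejection draws by
#'   sampling from it).
#' @param positions strictly increasing bp positions of the SNPs.
#' @param model a \linkS4class{DiseaseModel}; the risk haplotype is matched
#'   on the allele string of each chromosome copy.
#' @param nCases,nControls exact counts.
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @param maxAttempts rejection-sampling bound.
#' @return a \linkS4class{SyntheticCohort} with a
#'   \linkS4class{LocalAncestryTrack}.
#' @export
generateAdmixedCohort <- function(poolA, poolB, switchRate, admixtureProp,
                                  positions, model = DiseaseModel(),
                                  nCases, nControls, seed, chrom = "1",
                                  maxAttempts = 1000L) {
    if (poolA@nSnps != poolB@nSnps ||
        !identical(poolA@alleles, poolB@alleles))
        stop("pools must share nSnps and allele codes", call. = FALSE)
    w <- poolA@nSnps
    stopifnot(length(positions) == w, all(diff(positions) > 0))
    pA <- as.numeric(colSums(poolA@bits * poolA@poolFreqs))
    pB <- as.numeric(colSums(poolB@bits * poolB@poolFreqs))
    stay <- exp(-switchRate * diff(positions) / 1e6)
    riskBits <- NULL
    if (model@riskHaplotype != "") {
        chars <- strsplit(model@riskHaplotype, "")[[1L]]
        rng <- model@riskStart:model@riskEnd
        riskBits <- as.integer(chars == poolA@alleles[1L, rng])
        if (!all(chars == poolA@alleles[1L, rng] |
                 chars == poolA@alleles[2L, rng]))
            stop("risk haplotype uses unknown allele codes", call. = FALSE)
    }
    withSeed(seed, {
        drawCopies <- function(m, prop) {
            anc <- matrix(0L, m, w)           # 1 = ancestry A
            anc[, 1L] <- rbinom(m, 1L, prop)
            for (j in 2:w) {
                keep <- runif(m) < stay[j - 1L]
                anc[, j] <- ifelse(keep, anc[, j - 1L],
                                   rbinom(m, 1L, prop))
            }
            p <- anc * rep(pA, each = m) + (1L - anc) * rep(pB, each = m)
            bits <- matrix(rbinom(m * w, 1L, as.numeric(p)), m, w)
            list(anc = anc, bits = bits)
        }
        draw <- function(m) {
            prop <- if (length(admixtureProp) == 1L)
                rep(admixtureProp, m)
            else sample(admixtureProp, m, replace = TRUE)
            c1 <- drawCopies(m, prop); c2 <- drawCopies(m, prop)
            dose <- numeric(m)
            if (!is.null(riskBits)) {
                rng <- model@riskStart:model@riskEnd
                match1 <- rowSums(c1$bits[, rng, drop = FALSE] !=
                                  rep(riskBits, each = m)) == 0L
                match2 <- rowSums(c2$bits[, rng, drop = FALSE] !=
                                  rep(riskBits, each = m)) == 0L
                dose <- match1 + match2
            }
            eur <- (1L - c1$anc) + (1L - c2$anc)   # copies of B ancestry
            cov <- drawCovariates(m)
            cov$globalB <- rowMeans(eur) / 2
            list(calls = c1$bits + c2$bits, dose = dose, cov = cov,
                 eur = eur)
        }
        parts <- rejectionSample(nCases, nControls, model, draw,
                                 maxAttempts)
        calls <- parts$calls
        n <- nrow(calls)
        rownames(calls) <- sprintf("S%05d", seq_len(n))
        snpMap <- defaultSnpMap(w, poolA@alleles, chrom)
        snpMap$bp <- as.integer(positions)
        samples <- data.frame(sample_id = rownames(calls),
                              phenotype = parts$labels,
                              parts$cov, stringsAsFactors = TRUE)
        gm <- GenotypeMatrix(calls, snpMap, samples, sort = FALSE)
        eur <- parts$eur
        track <- new("LocalAncestryTrack",
                     p0 = matrix(as.numeric(eur == 0L), n, w,
                                 dimnames = list(rownames(calls),
                                                 snpMap$id)),
                     p1 = matrix(as.numeric(eur == 1L), n, w,
                                 dimnames = list(rownames(calls),
                                                 snpMap$id)),
                     p2 = matrix(as.numeric(eur == 2L), n, w,
                                 dimnames = list(rownames(calls),
                                                 snpMap$id)),
                     snpIds = snpMap$id, sampleIds = rownames(calls))
        new("SyntheticCohort", genotypes = gm,
            truePairs = matrix(0L, 0L, 2L), pool = NULL, model = model,
            localAncestry = track, seed = as.integer(seed))
    })
}

#' Generate a multi-block chromosome cohort
#'
#' Concatenates independent haplotype blocks into one synthetic
#' chromosome: the causal block (whose pool the disease model refers to)
#' is drawn under rejection sampling to exact case/control counts, and
#' every other block is drawn independently of phenotype under
#' Hardy-Weinberg equilibrium. Block boundaries and the causal SNP range
#' are recorded in the genotype metadata (\code{causal_snp_range},
#' \code{risk_snp_range}).
#'
#' @param blockPools list of \linkS4class{HaplotypePool}s, one per block.
#' @param causalBlock index of the block the disease model refers to.
#' @param model a \linkS4class{DiseaseModel} with SNP indices relative to
#'   the causal block.
#' @param nCases,nControls exact counts.
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @param spacingBp inter-SNP spacing.
#' @param maxAttempts rejection-sampling bound.
#' @return a \linkS4class{SyntheticCohort}; \code{truePairs} holds the
#'   causal block's haplotype pair indices.
#' @export
generateChromosomeCohort <- function(blockPools, causalBlock = 1L,
                                     model = DiseaseModel(), nCases,
                                     nControls, seed, chrom = "1",
                                     spacingBp = 1000L,
                                     maxAttempts = 1000L) {
    stopifnot(causalBlock >= 1L, causalBlock <= length(blockPools))
    causal <- generateCohort(blockPools[[causalBlock]], nCases, nControls,
                             model, seed = seed, chrom = chrom,
                             maxAttempts = maxAttempts)
    n <- nCases + nControls
    widths <- vapply(blockPools, function(p) p@nSnps, integer(1))
    offsets <- cumsum(c(0L, widths))[seq_along(widths)]
    withSeed(seed + 1L, {
        blocks <- vector("list", length(blockPools))
        for (b in seq_along(blockPools)) {
            if (b == causalBlock) {
                blocks[[b]] <- genotypeCalls(causal)
                next
            }
            pool <- blockPools[[b]]
            idx <- matrix(sample.int(length(pool@haplotypes), 2L * n,
                                     replace = TRUE,
                                     prob = pool@poolFreqs), ncol = 2L)
            blocks[[b]] <- pool@bits[idx[, 1L], , drop = FALSE] +
                pool@bits[idx[, 2L], , drop = FALSE]
        }
        calls <- do.call(cbind, blocks)
        rownames(calls) <- rownames(genotypeCalls(causal))
        snpMap <- do.call(rbind, lapply(seq_along(blockPools), function(b)
            defaultSnpMap(widths[b], blockPools[[b]]@alleles, chrom,
                          spacingBp, offset = offsets[b])))
        cd <- as.data.frame(
            SummarizedExperiment::colData(cohortGenotypes(causal)))
        gm <- GenotypeMatrix(calls, snpMap, cd, sort = FALSE)
        S4Vectors::metadata(gm)$causal_snp_range <-
            c(offsets[causalBlock] + 1L, offsets[causalBlock] +
                  widths[causalBlock])
        S4Vectors::metadata(gm)$risk_snp_range <-
            c(offsets[causalBlock] + model@riskStart,
              offsets[causalBlock] + model@riskEnd)
        new("SyntheticCohort", genotypes = gm,
            truePairs = truePairs(causal),
            pool = blockPools[[causalBlock]], model = model,
            localAncestry = NULL, seed = as.integer(seed))
    })
}

#' Generate the quality-control fixture cohort
#'
#' A 5,984-sample null cohort (3,153 cases, 2,831 controls; 120 SNPs in
#' fifteen 8-SNP blocks) carrying non-overlapping exclusion conditions in
#' fixed counts: 52 low-DNA, 29 related, 100 low call rate (10 percent of
#' their genotypes set missing so their call rate falls below 95 percent),
#' 36 low African ancestry and 6 ambiguous-sex samples; every other sample
#' passes every filter, so sample QC retains 5,761 subjects (3,016 cases
#' and 2,745 controls). Exclusion flags are stored in the
#' \code{exclusion_flag} sample-metadata column.
#'
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticCohort}.
#' @seealso \code{\link{sampleQC}}
#' @export
generateQcFixture <- function(seed) {
    pools <- lapply(1:15, function(b)
        generateHaplotypePool(8L, 8L, seed = seed + 100L + b))
    cohort <- generateChromosomeCohort(pools, causalBlock = 1L,
                                       model = DiseaseModel(),
                                       nCases = 3153L, nControls = 2831L,
                                       seed = seed)
    gm <- cohortGenotypes(cohort)
    calls <- genotypeCalls(gm)
    ph <- phenotype(gm)
    n <- nrow(calls)
    withSeed(seed + 2L, {
        caseIdx <- sample(which(ph == 1L))
        ctrlIdx <- sample(which(ph == 0L))
        # disjoint reason groups, split across cases/controls so that the
        # survivors keep the 3,016 / 2,745 case-control design
        splitCase <- c(low_dna = 32L, related = 18L, call_rate = 61L,
                       low_ancestry = 22L, ambiguous_sex = 4L)
        splitCtrl <- c(low_dna = 20L, related = 11L, call_rate = 39L,
                       low_ancestry = 14L, ambiguous_sex = 2L)
        flags <- rep("none", n)
        lowCallIdx <- integer(0)
        posC <- 0L; posK <- 0L
        for (r in names(splitCase)) {
            ic <- caseIdx[posC + seq_len(splitCase[[r]])]
            ik <- ctrlIdx[posK + seq_len(splitCtrl[[r]])]
            posC <- posC + splitCase[[r]]; posK <- posK + splitCtrl[[r]]
            if (r == "call_rate") lowCallIdx <- c(ic, ik)
            else flags[c(ic, ik)] <- r
        }
        for (i in lowCallIdx)
            calls[i, sample.int(ncol(calls), ceiling(0.10 * ncol(calls)))] <-
                NA_integer_
    })
    cd <- as.data.frame(SummarizedExperiment::colData(gm))
    cd$exclusion_flag <- flags
    gm2 <- GenotypeMatrix(calls, snpInfo(gm), cd, sort = FALSE)
    S4Vectors::metadata(gm2) <- S4Vectors::metadata(gm)
    methods::initialize(cohort, genotypes = gm2)
}
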