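# Generators: pool construction, exact case/control counts,
# genotype/haplotype consistency, HWE at generation, the E-M dosage
# oracle, admixture tracks, and the QC fixture's determinism.

test_that("pool generation respects feasibility and determinism", {
    # a single SNP admits exactly the two single-allele haplotypes
    p1 <- generateHaplotypePool(1L, 2L, seed = 1L)
    expect_setequal(nchar(poolHaplotypes(p1)), 1L)
    expect_identical(sort(poolHaplotypes(p1)),
                     sort(as.vector(p1@alleles)))
    expect_equal(sum(poolFreqs(p1)), 1, tolerance = 1e-12)
    # same seed, same pool
    expect_identical(poolHaplotypes(generateHaplotypePool(5L, 8L, seed = 7L)),
                     poolHaplotypes(generateHaplotypePool(5L, 8L, seed = 7L)))
    # more haplotypes than 2^nSnps is a parameter error
    expect_error(generateHaplotypePool(2L, 5L, seed = 1L), "infeasible")
})

test_that("cohorts hit the exact case/control counts with consistent genotypes", {
    pool <- smallPool()
    co <- generateCohort(pool, 50L, 50L, DiseaseModel(), seed = 2L)
    ph <- phenotype(co)
    expect_identical(sum(ph == 1L), 50L)
    expect_identical(sum(ph == 0L), 50L)
    # genotype equals the allele contribution of the two true haplotypes
    tp <- truePairs(co)
    expect_true(all(genotypeCalls(co) ==
                    pool@bits[tp[, 1], ] + pool@bits[tp[, 2], ]))
    # determinism
    co2 <- generateCohort(pool, 50L, 50L, DiseaseModel(), seed = 2L)
    expect_identical(genotypeCalls(co), genotypeCalls(co2))
    # an unreachable case count errors out
    sick <- DiseaseModel(intercept = -60)
    expect_error(generateCohort(pool, 50L, 50L, sick, seed = 3L,
                                maxAttempts = 2L),
                 "generation error")
})

test_that("generated diplotype counts respect HWE", {
    pool <- smallPool()
    passes <- 0L
    nSeeds <- 8L
    h <- which.max(poolFreqs(pool))
    for (s in seq_len(nSeeds)) {
        co <- nullCohort(n = 10000L, seed = 200L + s, pool = pool)
        tp <- truePairs(co)
        c1 <- tp[, 1] == h; c2 <- tp[, 2] == h
        nHH <- sum(c1 & c2); nH1 <- sum(xor(c1, c2))
        nOO <- sum(!c1 & !c2)
        if (hweExactTest(nHH, nH1, nOO) > 0.001) passes <- passes + 1L
    }
    expect_gte(passes, nSeeds - 1L)
})

test_that("E-M mean dosages recover the pool frequencies", {
    pool <- smallPool()
    n <- 5000L
    co <- nullCohort(n = n, seed = 210L, pool = pool)
    gm <- cohortGenotypes(co)
    hs <- emFitCohort(gm)
    f <- hapFreqs(hs)
    for (j in seq_along(poolHaplotypes(pool))) {
        truth <- poolFreqs(pool)[j]
        if (truth < 0.02) next
        est <- mean(hapDosages(hs)[, poolHaplotypes(pool)[j]]) / 2
        se <- sqrt(truth * (1 - truth) / (2 * n))
        expect_lt(abs(est - truth), 3 * se)
    }
})

test_that("admixed cohorts produce coherent ancestry tracks", {
    pA <- generateHaplotypePool(6L, 6L, seed = 300L)
    pB <- new("HaplotypePool", nSnps = 6L, alleles = pA@alleles,
              haplotypes = rev(poolHaplotypes(pA)),
              bits = pA@bits[rev(seq_len(nrow(pA@bits))), ],
              poolFreqs = poolFreqs(pA))
    pos <- c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5)
    # switchRate = 0: each chromosome copy keeps one ancestry throughout,
    # so the European-copy dosage is constant along every sample
    co0 <- generateAdmixedCohort(pA, pB, switchRate = 0,
                                 admixtureProp = 0.5, positions = pos,
                                 nCases = 40L, nControls = 40L, seed = 301L)
    tr <- localAncestry(co0)
    eur <- tr@p1 + 2 * tr@p2
    expect_true(all(apply(eur, 1L, function(r) length(unique(r)) == 1L)))
    # admixtureProp = 1: everything is pool-A ancestry, zero B dosage
    co1 <- generateAdmixedCohort(pA, pB, switchRate = 2,
                                 admixtureProp = 1, positions = pos,
                                 nCases = 40L, nControls = 40L, seed = 302L)
    tr1 <- localAncestry(co1)
    expect_true(all(tr1@p0 == 1))
    expect_true(all(covariateTable(co1)$globalB == 0))
    # mismatched pools are a parameter error
    pC <- generateHaplotypePool(5L, 6L, seed = 303L)
    expect_error(generateAdmixedCohort(pA, pC, 1, 0.5, pos,
                                       nCases = 5L, nControls = 5L,
                                       seed = 304L),
                 "share")
    # posterior triples always sum to one
    expect_true(all(abs(tr@p0 + tr@p1 + tr@p2 - 1) < 1e-12))
})

test_that("ancestry confounding inflates the unadjusted test and the
           local-ancestry covariate restores calibration", {
    # pools with a large allele-frequency difference at every SNP and a
    # disease driven by global ancestry only (through the covariate
    # effect on the realized B fraction), no haplotype effect
    alle <- matrix(rep(c("A", "G"), 4), nrow = 2)
    pA <- new("HaplotypePool", nSnps = 4L, alleles = alle,
              haplotypes = c("AAAA", "GGGG"),
              bits = rbind(rep(1L, 4), rep(0L, 4)),
              poolFreqs = c(0.8, 0.2))
    pB <- new("HaplotypePool", nSnps = 4L, alleles = alle,
              haplotypes = c("AAAA", "GGGG"),
              bits = rbind(rep(1L, 4), rep(0L, 4)),
              poolFreqs = c(0.4, 0.6))
    model <- DiseaseModel(covariateEffects = c(globalB = 2))
    pos <- c(1e5, 1.5e5, 2e5, 2.5e5)
    nRep <- 60L
    pUn <- pAdj <- numeric(nRep)
    for (r in seq_len(nRep)) {
        co <- generateAdmixedCohort(pA, pB, switchRate = 0.5,
                                    admixtureProp = 0.8, positions = pos,
                                    model = model, nCases = 150L,
                                    nControls = 150L, seed = 400L + r)
        gm <- cohortGenotypes(co)
        hs <- emFitCohort(gm)
        j <- which.max(hapFreqs(hs))
        lab <- phenotype(gm)
        pUn[r] <- haplotypeSpecificTest(hapDosages(hs)[, j], NULL,
                                        lab)@p
        la <- localAncestryCovariate(localAncestry(co), snpInfo(gm)$id)
        pAdj[r] <- haplotypeSpecificTest(hapDosages(hs)[, j],
                                         data.frame(la = la), lab)@p
    }
    expect_gt(mean(pUn < 0.05), 0.25)          # clearly inflated
    binom99 <- qbinom(c(0.005, 0.995), nRep, 0.05) / nRep
    expect_lte(mean(pAdj < 0.05), max(binom99[2], 3 / nRep))
})

test_that("the QC fixture is deterministic with the printed exclusion counts", {
    co <- generateQcFixture(seed = 42L)
    gm <- cohortGenotypes(co)
    flags <- SummarizedExperiment::colData(gm)$exclusion_flag
    expect_identical(sum(flags == "low_dna"), 52L)
    expect_identical(sum(flags == "related"), 29L)
    expect_identical(sum(flags == "low_ancestry"), 36L)
    expect_identical(sum(flags == "ambiguous_sex"), 6L)
    callRate <- rowMeans(!is.na(genotypeCalls(gm)))
    expect_identical(sum(callRate < 0.95 & flags == "none"), 100L)
    co2 <- generateQcFixture(seed = 42L)
    expect_identical(SummarizedExperiment::colData(cohortGenotypes(co2))$exclusion_flag,
                     flags)
    expect_identical(genotypeCalls(co2), genotypeCalls(co))
})
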