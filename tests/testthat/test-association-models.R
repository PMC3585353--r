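# Logistic fitting engine and the expectation-substitution tests:
# closed-form checks, a generic-optimizer cross-check, degeneracies, and
# the null distribution of the haplotype-specific test.

test_that("intercept-only and 2x2 fits match closed forms", {
    y <- rep(c(1, 0), each = 50)
    f <- fitLogistic(y, matrix(1, 100, 1,
                               dimnames = list(NULL, "(Intercept)")))
    expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
    expect_equal(f$loglik, 100 * log(0.5), tolerance = 1e-10)
    # exposure table (30,20)/(15,35): beta = log(30*35/(20*15)) = log(3.5)
    y2 <- c(rep(1, 30), rep(0, 15), rep(1, 20), rep(0, 35))
    x2 <- c(rep(1, 45), rep(0, 55))
    f2 <- fitLogistic(y2, cbind("(Intercept)" = 1, exposure = x2))
    expect_equal(unname(f2$coefficients["exposure"]), log(3.5),
                 tolerance = 1e-6)
})

test_that("quasi-complete separation is flagged, not silently reported", {
    y <- rep(c(1, 0), each = 20)
    x <- as.numeric(y)                       # perfect separation
    f <- fitLogistic(y, cbind("(Intercept)" = 1, x = x))
    expect_false(f$converged)
})

test_that("rank-deficient designs raise a collinearity error naming the term", {
    y <- rep(c(1, 0), each = 20)
    X <- cbind("(Intercept)" = 1, a = rnorm(40))
    X <- cbind(X, b = X[, "a"] * 2)
    expect_error(fitLogistic(y, X), "collinear.*b")
    # constant dosage duplicates the intercept
    expect_error(haplotypeSpecificTest(rep(0, 40), NULL, y), "collinear")
})

test_that("IRLS matches a generic numerical optimizer on random designs", {
    set.seed(31)
    for (r in 1:20) {
        n <- sample(60:120, 1)
        p <- sample(1:3, 1)
        X <- cbind(1, matrix(rnorm(n * p), n))
        colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
        beta <- rnorm(p + 1, sd = 0.7)
        y <- rbinom(n, 1, plogis(X %*% beta))
        if (sum(y) == 0 || sum(y) == n) next
        f <- fitLogistic(y, X)
        if (!f$converged) next
        nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
        opt <- optim(rep(0, p + 1), nll, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 500))
        expect_lt(max(abs(f$coefficients - opt$par)), 1e-5)
    }
})

test_that("global test df follows the common-haplotype count", {
    pool <- smallPool()
    co <- nullCohort(n = 400L, seed = 41L, pool = pool)
    gm <- cohortGenotypes(co)
    hs <- emFit(genotypeCalls(gm))
    labels <- phenotype(gm)
    cov <- covariateTable(gm)
    g <- globalHaplotypeTest(hs, cov, labels)
    expect_identical(g@df, sum(hapFreqs(hs) > 0.01) - 1L)
    # raising the threshold to keep exactly two haplotypes gives a 1-df
    # test equal to the LR haplotype-specific test of the non-reference
    fr <- sort(hapFreqs(hs), decreasing = TRUE)
    thr <- (fr[2] + fr[3]) / 2
    g2 <- globalHaplotypeTest(hs, cov, labels, freqThreshold = thr)
    expect_identical(g2@df, 1L)
    nonref <- names(fr)[2]
    h <- haplotypeSpecificTest(hapDosages(hs)[, nonref], cov, labels,
                               test = "lr")
    expect_equal(g2@p, h@p, tolerance = 1e-9)
    # one common haplotype: df0 signal
    g3 <- globalHaplotypeTest(hs, cov, labels, freqThreshold = 0.99)
    expect_identical(g3@df, 0L)
    expect_identical(g3@note, "df0")
})

test_that("SNP-adjusted LR test handles collinearity and degenerate adjustment", {
    pool <- smallPool()
    co <- nullCohort(n = 300L, seed = 43L, pool = pool)
    gm <- cohortGenotypes(co)
    labels <- phenotype(gm)
    cov <- covariateTable(gm)
    calls <- genotypeCalls(gm)
    hs <- emFit(calls)
    j <- which.max(hapFreqs(hs))
    dosage <- hapDosages(hs)[, j]
    # dosage identical to the adjustment SNP: nested models coincide
    res <- snpAdjustedLrTest(calls[, 1], cbind(snp1 = calls[, 1]), cov,
                             labels)
    expect_identical(res@note, "collinear")
    expect_identical(res@lrStat, 0)
    # empty adjustment set reduces to the haplotype-specific LR test
    r0 <- snpAdjustedLrTest(dosage, NULL, cov, labels)
    r1 <- haplotypeSpecificTest(dosage, cov, labels, test = "lr")
    expect_equal(r0@lrStat, r1@lrStat, tolerance = 1e-9)
})

test_that("LR statistics are invariant to affine covariate recoding", {
    pool <- smallPool()
    co <- nullCohort(n = 300L, seed = 47L, pool = pool)
    gm <- cohortGenotypes(co)
    labels <- phenotype(gm)
    cov <- covariateTable(gm)
    hs <- emFit(genotypeCalls(gm))
    cov2 <- cov
    cov2$age <- (cov2$age - 50) / 10
    cov2$pc1 <- 3 * cov2$pc1 + 1
    g1 <- globalHaplotypeTest(hs, cov, labels)
    g2 <- globalHaplotypeTest(hs, cov2, labels)
    expect_equal(g1@lrStat, g2@lrStat, tolerance = 1e-6)
    expect_gte(g1@lrStat, 0)
})

test_that("haplotype-specific p-values are uniform under label permutation", {
    pool <- smallPool()
    co <- nullCohort(n = 200L, seed = 53L, pool = pool)
    gm <- cohortGenotypes(co)
    hs <- emFit(genotypeCalls(gm))
    j <- which.max(hapFreqs(hs))
    dosage <- hapDosages(hs)[, j]
    labels <- phenotype(gm)
    set.seed(54)
    ps <- vapply(1:500, function(b) {
        haplotypeSpecificTest(dosage, NULL, sample(labels))@p
    }, numeric(1))
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Wald and LR agree to within 20% at moderate n and effects", {
    pool <- smallPool()
    rh <- poolHaplotypes(pool)[which.max(poolFreqs(pool))]
    model <- DiseaseModel(riskHaplotype = rh, riskStart = 1,
                          betaH = log(1.3))
    co <- generateCohort(pool, 1000L, 1000L, model, seed = 55L)
    gm <- cohortGenotypes(co)
    hs <- emFitCohort(gm)
    dosage <- hapDosages(hs)[, rh]
    w <- haplotypeSpecificTest(dosage, covariateTable(gm), phenotype(gm))
    l <- haplotypeSpecificTest(dosage, covariateTable(gm), phenotype(gm),
                               test = "lr")
    expect_lt(abs(log(w@p) - log(l@p)) / abs(log(l@p)), 0.2)
})
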