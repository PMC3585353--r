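# Region extension arithmetic, exhaustive search combinatorics,
# verification against SNP effects, and the local-ancestry covariate.

test_that("region extension adds half the width on each side", {
    r <- GenomicRanges::GRanges("1", IRanges::IRanges(8309317, 8318147))
    e <- extendRegion(r)
    expect_identical(GenomicRanges::start(e), 8304902L)
    expect_identical(GenomicRanges::end(e), 8322562L)
    # factor 0 is the identity
    e0 <- extendRegion(r, factor = 0)
    expect_identical(GenomicRanges::start(e0), 8309317L)
    # starts are clamped at 1
    r2 <- GenomicRanges::GRanges("2", IRanges::IRanges(100, 1100))
    expect_identical(GenomicRanges::start(extendRegion(r2)), 1L)
})

test_that("the exhaustive search evaluates every contiguous run once", {
    pool <- generateHaplotypePool(12L, 16L, seed = 120L)
    co <- nullCohort(n = 200L, seed = 121L, pool = pool)
    gm <- cohortGenotypes(co)
    info <- snpInfo(gm)
    # R = 5 SNPs: 4 + 3 + 2 + 1 = 10 runs
    r5 <- GenomicRanges::GRanges("1", IRanges::IRanges(info$bp[1],
                                                       info$bp[5]))
    hits5 <- exhaustiveHaplotypeSearch(gm, r5)
    runs5 <- unique(paste(hits5$snp_index_start, hits5$length))
    expect_identical(length(runs5), 10L)
    # R = 12, lenMax = 10: sum over L = 2..10 of (13 - L) = 63 runs
    r12 <- GenomicRanges::GRanges("1", IRanges::IRanges(info$bp[1],
                                                        info$bp[12]))
    hits12 <- exhaustiveHaplotypeSearch(gm, r12)
    runs12 <- unique(paste(hits12$snp_index_start, hits12$length))
    expect_identical(length(runs12), 63L)
    # ranking is total: p ascending, ties by longer run then allele string
    expect_true(!is.unsorted(hits12$p))
    # every reported haplotype clears the frequency threshold
    expect_true(all(hits12$frequency > 0.01))
})

test_that("the 5-SNP window haplotype set is contained in the search candidates", {
    pool <- smallPool()
    co <- nullCohort(n = 300L, seed = 123L, pool = pool)
    gm <- cohortGenotypes(co)
    info <- snpInfo(gm)
    region <- GenomicRanges::GRanges("1", IRanges::IRanges(info$bp[1],
                                                           info$bp[5]))
    hits <- exhaustiveHaplotypeSearch(gm, region, lenMax = 5L)
    hs <- emFitCohort(gm)
    common <- names(hapFreqs(hs))[hapFreqs(hs) > 0.01]
    fromSearch <- hits$haplotype[hits$length == 5L]
    expect_true(all(common %in% fromSearch))
})

test_that("verification flags a haplotype identical to its constituent SNP", {
    # two haplotypes differing at SNP1 only: the 2-SNP haplotype dosage
    # is exactly the SNP1 genotype, so the adjusted test is degenerate
    alle <- matrix(c("A", "G", "C", "C"), nrow = 2)
    pool <- new("HaplotypePool", nSnps = 2L, alleles = alle,
                haplotypes = c("AC", "GC"),
                bits = rbind(c(1L, 1L), c(0L, 1L)),
                poolFreqs = c(0.3, 0.7))
    co <- nullCohort(n = 200L, seed = 131L, pool = pool)
    gm <- cohortGenotypes(co)
    info <- snpInfo(gm)
    region <- GenomicRanges::GRanges("1", IRanges::IRanges(info$bp[1],
                                                           info$bp[2]))
    hits <- exhaustiveHaplotypeSearch(gm, region)
    top <- verifyTopHit(hits[hits$haplotype == "AC", ][1, ], gm)
    expect_identical(top$adj_note, "collinear")
    expect_equal(top$adj_p, 1)
})

test_that("a haplotype effect not expressible by one SNP survives adjustment", {
    # risk haplotype AG among {AG, Ag, aG, ag} at equal-ish frequencies:
    # neither SNP alone captures the AG-specific effect
    alle <- matrix(c("A", "a", "G", "g"), nrow = 2)
    pool <- new("HaplotypePool", nSnps = 2L, alleles = alle,
                haplotypes = c("AG", "Ag", "aG", "ag"),
                bits = rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L)),
                poolFreqs = c(0.25, 0.25, 0.25, 0.25))
    model <- DiseaseModel(riskHaplotype = "AG", riskStart = 1L,
                          betaH = log(1.9))
    co <- generateCohort(pool, 1250L, 1250L, model, seed = 133L)
    gm <- cohortGenotypes(co)
    info <- snpInfo(gm)
    region <- GenomicRanges::GRanges("1", IRanges::IRanges(info$bp[1],
                                                           info$bp[2]))
    hits <- exhaustiveHaplotypeSearch(gm, region)
    expect_identical(hits$haplotype[1], "AG")
    top <- verifyTopHit(hits[1, ], gm)
    expect_lt(top$adj_p, 0.01)
})

test_that("the local-ancestry covariate is the mean expected European dosage", {
    n <- 4L
    mk <- function(p0, p1, p2)
        new("LocalAncestryTrack",
            p0 = matrix(p0, n, 3), p1 = matrix(p1, n, 3),
            p2 = matrix(p2, n, 3),
            snpIds = paste0("s", 1:3), sampleIds = paste0("i", 1:n))
    expect_equal(localAncestryCovariate(mk(0.25, 0.5, 0.25),
                                        paste0("s", 1:3)),
                 rep(1, n))
    expect_equal(localAncestryCovariate(mk(1, 0, 0), paste0("s", 1:3)),
                 rep(0, n))
    # per-SNP dosages 0, 1, 2 average to 1
    tr <- new("LocalAncestryTrack",
              p0 = cbind(rep(1, n), 0, 0), p1 = cbind(0, rep(1, n), 0),
              p2 = cbind(0, 0, rep(1, n)),
              snpIds = paste0("s", 1:3), sampleIds = paste0("i", 1:n))
    expect_equal(localAncestryCovariate(tr, paste0("s", 1:3)), rep(1, n))
    expect_error(localAncestryCovariate(tr, "s9"), "missing")
})

test_that("known-region scan builds the flanked regions with overrides", {
    pool <- generateHaplotypePool(12L, 16L, seed = 140L)
    co <- nullCohort(n = 200L, seed = 141L, pool = pool)
    gm <- cohortGenotypes(co)
    info <- snpInfo(gm)
    idx <- data.frame(snp_id = c(info$id[6], "rs_missing"),
                      chrom = c(NA, NA), bp = c(NA, NA),
                      stringsAsFactors = FALSE)
    expect_message(
        out <- knownRegionScan(gm, idx, flank = 3000,
                               wideFlank = setNames(5000, info$id[6])),
        "skipped")
    reg <- out[[info$id[6]]]$region
    expect_identical(GenomicRanges::start(reg),
                     as.integer(max(1, info$bp[6] - 5000)))
    expect_identical(GenomicRanges::end(reg), as.integer(info$bp[6] + 5000))
    expect_false("rs_missing" %in% names(out))
    expect_true(!is.null(out[[info$id[6]]]$top))
})

test_that("an irrelevant local-ancestry covariate leaves the adjusted test alone", {
    pool <- smallPool()
    rh <- poolHaplotypes(pool)[which.max(poolFreqs(pool))]
    model <- DiseaseModel(riskHaplotype = rh, riskStart = 1L,
                          betaH = log(1.6))
    co <- generateCohort(pool, 600L, 600L, model, seed = 151L)
    gm <- cohortGenotypes(co)
    info <- snpInfo(gm)
    region <- GenomicRanges::GRanges("1", IRanges::IRanges(info$bp[1],
                                                           info$bp[5]))
    hits <- exhaustiveHaplotypeSearch(gm, region, lenMax = 5L)
    set.seed(152)
    # pure-noise degenerate posteriors, independent of everything
    n <- length(phenotype(gm))
    eur <- matrix(sample(0:2, n * 5, replace = TRUE), n, 5)
    tr <- new("LocalAncestryTrack",
              p0 = (eur == 0) * 1, p1 = (eur == 1) * 1, p2 = (eur == 2) * 1,
              snpIds = info$id, sampleIds = rownames(genotypeCalls(gm)))
    top <- verifyTopHit(hits[1, ], gm, track = tr)
    expect_lt(abs(log(top$la_adj_p) - log(top$adj_p)),
              abs(log(top$adj_p)) * 0.5 + 1)
})
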