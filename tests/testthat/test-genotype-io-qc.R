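# Genotype input/output round trips, the QC filters, and the
# Hardy-Weinberg exact test against a brute-force enumeration oracle.

test_that("PLINK and VCF round trips preserve the call matrix", {
    co <- nullCohort(n = 10L, seed = 3L,
                     pool = generateHaplotypePool(20L, 12L, seed = 4L))
    gm <- cohortGenotypes(co)
    calls <- genotypeCalls(gm)
    calls[2, 5] <- NA; calls[7, 1] <- NA        # missingness survives too
    gm <- GenotypeMatrix(calls, snpInfo(gm),
                         data.frame(sample_id = rownames(calls),
                                    phenotype = phenotype(gm)))
    tmp <- file.path(tempdir(), "rt")
    writePlink(gm, tmp)
    back <- readGenotypes(tmp, "plink")
    expect_equal(unname(genotypeCalls(back)), unname(genotypeCalls(gm)))
    expect_identical(snpInfo(back)$bp, snpInfo(gm)$bp)
    expect_identical(phenotype(back), phenotype(gm))

    vcf <- file.path(tempdir(), "rt.vcf")
    writeVcfFile(gm, vcf)
    backV <- readGenotypes(vcf, "vcf")
    expect_equal(unname(genotypeCalls(backV)), unname(genotypeCalls(gm)))
})

test_that("multiallelic and non-autosomal VCF records are skipped with a count", {
    vcf <- file.path(tempdir(), "tri.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "s1", "s2", sep = "\t"),
        paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
              "0/1", "1/1", sep = "\t"),
        paste("1", "200", "rs2", "A", "G,T", ".", "PASS", ".", "GT",
              "0/1", "0/2", sep = "\t"),
        paste("1", "300", "rs3", "C", "T", ".", "PASS", ".", "GT",
              "0/0", "./.", sep = "\t")), vcf)
    expect_message(gm <- readGenotypes(vcf, "vcf"), "skipped 1")
    expect_identical(attr(gm, "skipped"), 1L)
    expect_identical(snpInfo(gm)$id, c("rs1", "rs3"))
    expect_identical(unname(genotypeCalls(gm)[, "rs3"]), c(0L, NA))
})

test_that("sample QC removes by flag and call rate in the reporting order", {
    pool <- smallPool()
    co <- nullCohort(n = 100L, seed = 5L, pool = pool)
    gm <- cohortGenotypes(co)
    # clean input: nothing removed
    res <- sampleQC(gm)
    expect_identical(unname(res$report@samplesRemoved),
                     rep(0L, 5L))
    expect_identical(unname(res$report@survivors[["samples"]]), 100L)
    # a sample missing 6% of SNPs falls below the 95% call-rate bar
    pool20 <- generateHaplotypePool(50L, 16L, seed = 6L)
    co2 <- nullCohort(n = 40L, seed = 7L, pool = pool20)
    gm2 <- cohortGenotypes(co2)
    calls <- genotypeCalls(gm2)
    calls[3, 1:3] <- NA                         # 3/50 = 6% missing
    gm2 <- GenotypeMatrix(calls, snpInfo(gm2),
                          data.frame(sample_id = rownames(calls),
                                     phenotype = phenotype(gm2)))
    res2 <- sampleQC(gm2)
    expect_identical(res2$report@samplesRemoved[["call_rate"]], 1L)
    expect_identical(res2$report@survivors[["samples"]], 39L)
    # flags rank before / after call rate per the reporting order
    flags <- rep("none", 40L); flags[3] <- "low_dna"; flags[5] <- "ambiguous_sex"
    res3 <- sampleQC(gm2, exclusionFlags = flags)
    expect_identical(res3$report@samplesRemoved[["low_dna"]], 1L)
    expect_identical(res3$report@samplesRemoved[["call_rate"]], 0L)
    expect_identical(res3$report@samplesRemoved[["sex"]], 1L)
})

test_that("SNP QC removes low call rate, low MAF and monomorphic SNPs", {
    # 200 samples, allele1 count 3 -> MAF 0.0075 < 0.01
    calls <- matrix(0L, nrow = 200, ncol = 4)
    calls[1:3, 1] <- 1L                         # MAF 0.0075 at snp1
    calls[, 2] <- rep(c(0L, 1L, 2L), length.out = 200)   # common snp
    calls[1:20, 3] <- NA                        # call rate 0.90 at snp3
    calls[101:200, 3] <- 1L
    calls[, 4] <- 0L                            # monomorphic snp4
    calls[seq(1, 200, 2), 2] <- 1L
    gm <- GenotypeMatrix(calls,
        data.frame(id = paste0("s", 1:4), chrom = "1", bp = 1:4 * 100,
                   allele1 = "A", allele2 = "G"),
        data.frame(phenotype = rep(c(0L, 1L), 100)))
    res <- snpQC(gm)
    expect_identical(res$report@snpsRemoved[["call_rate"]], 1L)
    expect_identical(res$report@snpsRemoved[["maf"]], 2L)
    expect_identical(snpInfo(res$genotypes)$id, "s2")
})

test_that("HWE exact test matches closed forms and the enumeration oracle", {
    expect_equal(hweExactTest(25, 50, 25), 1)
    expect_equal(hweExactTest(100, 0, 0), 1)      # monomorphic
    expect_equal(hweExactTest(0, 2, 98), bruteHweExact(0, 2, 98))
    # exhaustive check on all tables with small totals
    for (n in c(1:25, 37, 60)) {
        for (n1 in 0:n) for (nh in 0:(n - n1)) {
            n2 <- n - n1 - nh
            expect_equal(hweExactTest(n1, nh, n2),
                         bruteHweExact(n1, nh, n2), tolerance = 1e-12)
        }
    }
    # random larger tables up to total 200
    set.seed(8)
    for (r in 1:200) {
        n <- sample(61:200, 1)
        n1 <- sample(0:n, 1); nh <- sample(0:(n - n1), 1)
        expect_equal(hweExactTest(n1, nh, n - n1 - nh),
                     bruteHweExact(n1, nh, n - n1 - nh), tolerance = 1e-12)
    }
})

test_that("sample QC before SNP QC reproduces a naive double-loop recomputation", {
    pool <- generateHaplotypePool(30L, 16L, seed = 10L)
    co <- nullCohort(n = 120L, seed = 11L, pool = pool)
    gm <- cohortGenotypes(co)
    calls <- genotypeCalls(gm)
    set.seed(12)
    calls[sample(length(calls), 400L)] <- NA     # scattered missingness
    flags <- rep("none", 120L); flags[sample(120L, 5L)] <- "low_dna"
    gm <- GenotypeMatrix(calls, snpInfo(gm),
                         data.frame(sample_id = rownames(calls),
                                    phenotype = phenotype(gm),
                                    exclusion_flag = flags))
    s <- sampleQC(gm)
    v <- snpQC(s$genotypes)
    # naive recomputation
    keepS <- flags == "none" & rowMeans(!is.na(calls)) >= 0.95
    sub <- calls[keepS, , drop = FALSE]
    keepV <- logical(ncol(sub))
    for (j in seq_len(ncol(sub))) {
        cr <- mean(!is.na(sub[, j]))
        p <- mean(sub[, j], na.rm = TRUE) / 2
        keepV[j] <- cr >= 0.95 && min(p, 1 - p) >= 0.01
    }
    expect_identical(nrow(genotypeCalls(v$genotypes)), sum(keepS))
    expect_identical(ncol(genotypeCalls(v$genotypes)), sum(keepV))
    expect_equal(unname(genotypeCalls(v$genotypes)),
                 unname(sub[, keepV, drop = FALSE]))
})
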