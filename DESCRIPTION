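Package: hapslide
Title: Sliding-Window Haplotype Association Scans for Case-Control GWAS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide sliding-window haplotype association analysis for
    unphased case-control genotype data. Haplotype frequencies and
    per-individual expected haplotype dosages within each window are
    estimated by an expectation-maximization algorithm under
    Hardy-Weinberg equilibrium; expectation-substitution logistic
    regression provides covariate-adjusted global (multi-haplotype) and
    haplotype-specific tests, with likelihood-ratio tests of haplotype
    effects conditional on single-SNP effects for follow-up of hit
    regions. Permutation analysis of minimum global-test p-values and
    beta-distribution fitting estimate the effective number of
    independent tests and chromosome- or genome-wide significance
    thresholds. Includes genotype input/quality control (PLINK and VCF,
    call-rate and minor-allele-frequency filters, Hardy-Weinberg exact
    test), exhaustive variable-length haplotype search with
    local-ancestry adjustment, and a synthetic-cohort generator with
    known haplotype structure, planted effects and two-way admixture for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
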