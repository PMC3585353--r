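# Genotype file input/output (PLINK bed/bim/fam, VCF 4.2) and the sample
# and SNP quality-control filters, plus the Hardy-Weinberg exact test used
# as a screen (never as a removal criterion).

#' Read genotypes from PLINK or VCF files
#'
#' Reads biallelic autosomal SNPs into a \linkS4class{GenotypeMatrix}.
#' PLINK input is the \code{prefix.bed/.bim/.fam} triple (variant-major
#' bed); calls count copies of the bim A1 allele, and fam phenotypes 1/2
#' are recoded to control = 0 / case = 1. VCF input (via \pkg{vcfR}) uses
#' the GT field; calls count copies of the ALT allele. Multiallelic or
#' non-SNP records and non-autosomal chromosomes are skipped with a
#' message (the skip count is available as \code{attr(x, "skipped")}).
#' SNPs are sorted by (chromosome, position).
#'
#' @param path PLINK file prefix or VCF file path.
#' @param format "plink" or "vcf".
#' @return a \linkS4class{GenotypeMatrix}.
#' @seealso \code{\link{writePlink}}, \code{\link{writeVcfFile}}
#' @export
readGenotypes <- function(path, format = c("plink", "vcf")) {
    format <- match.arg(format)
    if (format == "plink") readPlink(path) else readVcfFile(path)
}

autosomes <- as.character(1:22)

readPlink <- function(prefix) {
    bimF <- paste0(prefix, ".bim"); famF <- paste0(prefix, ".fam")
    bedF <- paste0(prefix, ".bed")
    for (f in c(bimF, famF, bedF))
        if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)
    bim <- read.table(bimF, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("chrom", "id", "cm", "bp", "a1", "a2"))
    fam <- read.table(famF, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("fid", "iid", "pid", "mid", "sex",
                                    "pheno"))
    nS <- nrow(fam); nV <- nrow(bim)
    con <- file(bedF, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 3L)
    if (!identical(as.integer(magic), c(108L, 27L, 1L)))
        stop("not a variant-major PLINK bed file", call. = FALSE)
    bytesPerVar <- ceiling(nS / 4)
    raw <- readBin(con, "raw", bytesPerVar * nV)
    if (length(raw) < bytesPerVar * nV)
        stop("truncated PLINK bed file", call. = FALSE)
    bits <- matrix(as.integer(rawToBits(raw)), nrow = 8L)
    # per byte, 4 samples x 2 bits, little-endian within byte
    twoBit <- bits[c(TRUE, FALSE), ] + 2L * bits[c(FALSE, TRUE), ]
    codes <- matrix(twoBit, nrow = bytesPerVar * 4L)[seq_len(nS), ,
                                                     drop = FALSE]
    # PLINK: 0 = hom A1, 1 = missing, 2 = het, 3 = hom A2 -> copies of A1
    calls <- matrix(NA_integer_, nrow = nS, ncol = nV)
    calls[codes == 0L] <- 2L
    calls[codes == 2L] <- 1L
    calls[codes == 3L] <- 0L
    isSnp <- nchar(bim$a1) == 1L & nchar(bim$a2) == 1L &
        bim$a1 %in% c("A", "C", "G", "T", "1", "2") &
        bim$a2 %in% c("A", "C", "G", "T", "1", "2")
    keep <- as.character(bim$chrom) %in% autosomes & isSnp
    nSkip <- sum(!keep)
    if (nSkip > 0)
        message("readGenotypes: skipped ", nSkip,
                " non-autosomal/non-SNP record(s)")
    ph <- ifelse(fam$pheno %in% c(1, 2), fam$pheno - 1L, NA_integer_)
    gm <- GenotypeMatrix(
        calls[, keep, drop = FALSE],
        data.frame(id = bim$id[keep], chrom = as.character(bim$chrom[keep]),
                   bp = bim$bp[keep], allele1 = bim$a1[keep],
                   allele2 = bim$a2[keep], stringsAsFactors = FALSE),
        data.frame(sample_id = fam$iid, phenotype = ph,
                   stringsAsFactors = FALSE))
    attr(gm, "skipped") <- nSkip
    gm
}

readVcfFile <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    isSnp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
        !grepl(",", fix$ALT, fixed = TRUE)
    keep <- as.character(fix$CHROM) %in% autosomes & isSnp & !is.na(fix$ALT)
    nSkip <- sum(!keep)
    if (nSkip > 0)
        message("readGenotypes: skipped ", nSkip,
                " multiallelic/non-SNP/non-autosomal record(s)")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    alt <- function(x) {
        a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
        vapply(a, function(z) {
            if (any(z == "." | is.na(z))) NA_integer_
            else sum(as.integer(z) > 0L)
        }, integer(1))
    }
    calls <- t(apply(gt, 1L, alt))            # SNPs x samples
    ids <- fix$ID[keep]
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[keep], ":",
                                           fix$POS[keep])[is.na(ids) | ids == "."]
    gm <- GenotypeMatrix(
        t(calls),
        data.frame(id = ids, chrom = as.character(fix$CHROM[keep]),
                   bp = as.integer(fix$POS[keep]),
                   allele1 = fix$ALT[keep], allele2 = fix$REF[keep],
                   stringsAsFactors = FALSE),
        data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE))
    attr(gm, "skipped") <- nSkip
    gm
}

#' Write genotypes as a PLINK bed/bim/fam triple
#'
#' Variant-major bed; bim A1 = \code{allele1} (the counted allele),
#' A2 = \code{allele2}; fam phenotype coded 1 = control, 2 = case,
#' -9 = missing.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{SyntheticCohort}.
#' @param prefix output file prefix.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(x, prefix) {
    gm <- if (is(x, "SyntheticCohort")) cohortGenotypes(x) else x
    calls <- genotypeCalls(gm)
    info <- snpInfo(gm)
    ph <- phenotype(gm)
    nS <- nrow(calls)
    write.table(
        data.frame(info$chrom, info$id, 0L, info$bp, info$allele1,
                   info$allele2),
        paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    famPh <- ifelse(is.na(ph), -9L, ph + 1L)
    write.table(
        data.frame(rownames(calls), rownames(calls), 0L, 0L, 0L, famPh),
        paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    pad <- (4L - nS %% 4L) %% 4L
    codeOf <- c(`2` = 0L, `1` = 2L, `0` = 3L)   # copies of A1 -> 2-bit code
    for (j in seq_len(ncol(calls))) {
        cj <- calls[, j]
        code <- ifelse(is.na(cj), 1L, codeOf[as.character(cj)])
        code <- c(code, rep(0L, pad))
        m <- matrix(code, nrow = 4L)
        bytes <- as.raw(m[1L, ] + 4L * m[2L, ] + 16L * m[3L, ] +
                        64L * m[4L, ])
        writeBin(bytes, con)
    }
    invisible(prefix)
}

#' Write genotypes as an uncompressed VCF 4.2 file
#'
#' GT-only records with unphased genotypes ("0/1"); REF = \code{allele2},
#' ALT = \code{allele1} so that ALT copies match the stored calls.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{SyntheticCohort}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeVcfFile <- function(x, path) {
    gm <- if (is(x, "SyntheticCohort")) cohortGenotypes(x) else x
    calls <- genotypeCalls(gm)
    info <- snpInfo(gm)
    gtOf <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(calls)),
                       collapse = "\t")), con)
    for (j in seq_len(ncol(calls))) {
        cj <- calls[, j]
        gt <- ifelse(is.na(cj), "./.", gtOf[as.character(cj)])
        writeLines(paste(c(info$chrom[j], info$bp[j], info$id[j],
                           info$allele2[j], info$allele1[j], ".", "PASS",
                           ".", "GT", gt), collapse = "\t"), con)
    }
    invisible(path)
}

#' Write the covariate table as tab-separated text
#'
#' Columns: \code{sample_id}, then every covariate column.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{SyntheticCohort}.
#' @param path output path.
#' @export
writeCovariates <- function(x, path) {
    gm <- if (is(x, "SyntheticCohort")) cohortGenotypes(x) else x
    cov <- covariateTable(gm)
    out <- cbind(sample_id = rownames(genotypeCalls(gm)), cov)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write/read local-ancestry posteriors as long-format TSV
#'
#' Columns: \code{sample_id}, \code{snp_id}, \code{p0}, \code{p1},
#' \code{p2} (posterior probabilities of 0/1/2 European-allele copies).
#'
#' @param track a \linkS4class{LocalAncestryTrack}.
#' @param path file path.
#' @return \code{writeLocalAncestry}: the path; \code{readLocalAncestry}:
#'   a \linkS4class{LocalAncestryTrack}.
#' @export
writeLocalAncestry <- function(track, path) {
    long <- data.frame(
        sample_id = rep(track@sampleIds, times = length(track@snpIds)),
        snp_id = rep(track@snpIds, each = length(track@sampleIds)),
        p0 = as.vector(track@p0), p1 = as.vector(track@p1),
        p2 = as.vector(track@p2))
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLocalAncestry
#' @export
readLocalAncestry <- function(path) {
    long <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
    sids <- unique(long$sample_id); vids <- unique(long$snp_id)
    shape <- function(col) {
        m <- matrix(NA_real_, length(sids), length(vids),
                    dimnames = list(sids, vids))
        m[cbind(match(long$sample_id, sids), match(long$snp_id, vids))] <- col
        m
    }
    new("LocalAncestryTrack", p0 = shape(long$p0), p1 = shape(long$p1),
        p2 = shape(long$p2), snpIds = vids, sampleIds = sids)
}

#' Sample-level quality control
#'
#' Removes samples in the order low DNA concentration, unexpected
#' relatedness, call rate below \code{minCallRate} (strict "<"; ties are
#' kept), low African ancestry, ambiguous sex. The first, second, fourth
#' and fifth reasons are consumed as input exclusion flags (they require
#' external metadata); the call-rate filter is computed from the genotype
#' missingness.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param exclusionFlags per-sample character flags among \code{"none"},
#'   \code{"low_dna"}, \code{"related"}, \code{"low_ancestry"},
#'   \code{"ambiguous_sex"}; defaults to the \code{exclusion_flag} column
#'   of the sample metadata, else all "none".
#' @param minCallRate minimum non-missing fraction (default 0.95).
#' @return list with the filtered \code{genotypes} and a
#'   \linkS4class{QcReport}.
#' @export
sampleQC <- function(gm, exclusionFlags = NULL, minCallRate = 0.95) {
    calls <- genotypeCalls(gm)
    n <- nrow(calls)
    if (is.null(exclusionFlags)) {
        cd <- SummarizedExperiment::colData(gm)
        exclusionFlags <- if ("exclusion_flag" %in% colnames(cd))
            as.character(cd$exclusion_flag) else rep("none", n)
    }
    stopifnot(length(exclusionFlags) == n)
    valid <- c("none", "low_dna", "related", "low_ancestry", "ambiguous_sex")
    if (!all(exclusionFlags %in% valid))
        stop("unknown exclusion flag(s): ",
             paste(setdiff(exclusionFlags, valid), collapse = ", "),
             call. = FALSE)
    removed <- rep(NA_character_, n)
    removed[exclusionFlags == "low_dna"] <- "low_dna"
    removed[is.na(removed) & exclusionFlags == "related"] <- "related"
    callRate <- rowMeans(!is.na(calls))
    removed[is.na(removed) & callRate < minCallRate] <- "call_rate"
    removed[is.na(removed) & exclusionFlags == "low_ancestry"] <- "ancestry"
    removed[is.na(removed) & exclusionFlags == "ambiguous_sex"] <- "sex"
    reasons <- c("low_dna", "related", "call_rate", "ancestry", "sex")
    counts <- vapply(reasons, function(r) sum(removed == r, na.rm = TRUE),
                     integer(1))
    keep <- is.na(removed)
    gmOut <- gm[, keep]
    report <- new("QcReport",
                  samplesRemoved = counts,
                  snpsRemoved = integer(0),
                  survivors = c(samples = sum(keep),
                                snps = ncol(calls)),
                  hweFlagged = character(0))
    list(genotypes = gmOut, report = report)
}

#' SNP-level quality control
#'
#' Removes SNPs with call rate below \code{minCallRate}, then SNPs whose
#' minor allele frequency -- computed on the remaining samples' non-missing
#' calls, cases and controls pooled -- is below \code{minMaf}.
#' Hardy-Weinberg deviation is flagged (exact test p-value below
#' \code{hweFlagThreshold}) but never used for removal.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (after sample QC).
#' @param minCallRate minimum non-missing fraction per SNP (default 0.95).
#' @param minMaf minimum minor allele frequency (default 0.01, strict "<"
#'   removal).
#' @param hweFlagThreshold HWE flagging p-value threshold (default 1e-6).
#' @return list with the filtered \code{genotypes} and a
#'   \linkS4class{QcReport} (flagged SNP ids in its \code{hweFlagged}
#'   slot).
#' @export
snpQC <- function(gm, minCallRate = 0.95, minMaf = 0.01,
                  hweFlagThreshold = 1e-6) {
    calls <- genotypeCalls(gm)
    info <- snpInfo(gm)
    callRate <- colMeans(!is.na(calls))
    lowCall <- callRate < minCallRate
    p1 <- colMeans(calls, na.rm = TRUE) / 2
    maf <- pmin(p1, 1 - p1)
    maf[is.nan(maf)] <- 0
    lowMaf <- !lowCall & maf < minMaf
    keep <- !(lowCall | lowMaf)
    hweP <- vapply(which(keep), function(j) {
        x <- calls[, j]
        hweExactTest(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                     sum(x == 0L, na.rm = TRUE))
    }, numeric(1))
    flagged <- info$id[keep][hweP < hweFlagThreshold]
    gmOut <- gm[keep, ]
    report <- new("QcReport",
                  samplesRemoved = integer(0),
                  snpsRemoved = c(call_rate = sum(lowCall),
                                  maf = sum(lowMaf)),
                  survivors = c(samples = nrow(calls), snps = sum(keep)),
                  hweFlagged = flagged)
    list(genotypes = gmOut, report = report)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditioning on the observed allele counts: over
#' all heterozygote counts compatible with the fixed allele counts, the
#' conditional probabilities no greater than that of the observed table
#' are summed. Monomorphic input returns 1.
#'
#' @param nHom1 count of allele1 homozygotes.
#' @param nHet heterozygote count.
#' @param nHom2 count of allele2 homozygotes.
#' @return the exact two-sided p-value.
#' @examples
#' hweExactTest(25, 50, 25)   # observed het count is the conditional mode
#' @export
hweExactTest <- function(nHom1, nHet, nHom2) {
    stopifnot(nHom1 >= 0, nHet >= 0, nHom2 >= 0)
    n <- nHom1 + nHet + nHom2
    stopifnot(n >= 1)
    nA <- 2L * nHom1 + nHet
    nB <- 2L * nHom2 + nHet
    if (nA == 0L || nB == 0L) return(1)
    nMinor <- min(nA, nB)
    hets <- seq(nMinor %% 2L, nMinor, by = 2L)
    # conditional log-probability of each heterozygote count
    logP <- vapply(hets, function(h) {
        h1 <- (nA - h) / 2; h2 <- (nB - h) / 2
        lgamma(n + 1) - lgamma(h1 + 1) - lgamma(h + 1) - lgamma(h2 + 1) +
            h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
    }, numeric(1))
    pr <- exp(logP - max(logP))
    pr <- pr / sum(pr)
    obs <- pr[match(nHet, hets)]
    min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}
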