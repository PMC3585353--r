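# Hit-region follow-up: region extension, exhaustive variable-length
# haplotype search, SNP-adjusted verification of top hits, and
# local-ancestry adjustment.

#' Extend a region by a fraction of its width on both sides
#'
#' With width W = end - start, the region becomes
#' [start - factor * W, end + factor * W] (floored at 1), so the default
#' factor 1/2 makes the extended region twice as long.
#'
#' @param region a \code{GRanges} of length 1 (or anything coercible).
#' @param factor extension fraction per side (default 0.5).
#' @return the extended \code{GRanges}.
#' @examples
#' r <- GenomicRanges::GRanges("1", IRanges::IRanges(8309317, 8318147))
#' extendRegion(r)   # 1:8304902-8322562
#' @export
extendRegion <- function(region, factor = 0.5) {
    region <- methods::as(region, "GRanges")
    stopifnot(length(region) == 1L)
    W <- GenomicRanges::end(region) - GenomicRanges::start(region)
    pad <- round(factor * W)
    newStart <- max(1L, GenomicRanges::start(region) - pad)
    GenomicRanges::GRanges(
        GenomicRanges::seqnames(region),
        IRanges::IRanges(newStart, GenomicRanges::end(region) + pad))
}

# SNP indices of gm falling inside a region. Internal.
regionSnpIndices <- function(gm, region) {
    region <- methods::as(region, "GRanges")
    info <- snpInfo(gm)
    which(info$chrom == as.character(GenomicRanges::seqnames(region))[1L] &
          info$bp >= GenomicRanges::start(region)[1L] &
          info$bp <= GenomicRanges::end(region)[1L])
}

#' Exhaustive variable-length haplotype search in a region
#'
#' Evaluates every contiguous run of \code{lenMin} to
#' \code{min(lenMax, R)} SNPs inside the region (R = number of genotyped
#' SNPs it contains): the run's haplotypes are inferred by E-M and every
#' haplotype with frequency strictly above \code{freqThreshold} receives a
#' covariate-adjusted haplotype-specific test. Results are ranked by
#' unadjusted p ascending, ties broken by longer haplotype, then by
#' allele string.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param region a \code{GRanges} of length 1.
#' @param covariates covariate data.frame (default from \code{gm}).
#' @param labels 0/1 phenotype (default from \code{gm}).
#' @param lenMin,lenMax haplotype length range in SNPs (defaults 2 and 10).
#' @param freqThreshold frequency cutoff (strict ">", default 0.01).
#' @return data.frame, one row per (run, haplotype): \code{chrom},
#'   \code{snp_index_start}, \code{snp_index_end}, \code{bp_start},
#'   \code{bp_end}, \code{snp_ids}, \code{haplotype}, \code{frequency},
#'   \code{or}, \code{ci_low}, \code{ci_high}, \code{p}, \code{length}.
#' @export
exhaustiveHaplotypeSearch <- function(gm, region,
                                      covariates = covariateTable(gm),
                                      labels = phenotype(gm),
                                      lenMin = 2L, lenMax = 10L,
                                      freqThreshold = 0.01) {
    idx <- regionSnpIndices(gm, region)
    if (length(idx) < 2L)
        stop("region contains fewer than two genotyped SNPs",
             call. = FALSE)
    info <- snpInfo(gm)
    calls <- genotypeCalls(gm)
    covX <- covariateDesign(covariates, n = length(labels))
    rows <- list()
    maxLen <- min(lenMax, length(idx))
    for (L in lenMin:maxLen) {
        for (s in seq_len(length(idx) - L + 1L)) {
            run <- idx[s:(s + L - 1L)]
            alle <- rbind(info$allele1[run], info$allele2[run])
            hs <- emFit(calls[, run, drop = FALSE], alleles = alle)
            common <- which(hs@freqs > freqThreshold)
            for (h in common) {
                res <- tryCatch(
                    haplotypeSpecificTest(hs@dosages[, h], covariates,
                                          labels,
                                          term = hs@haplotypes[h]),
                    error = function(e) NULL)
                if (is.null(res)) next
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = info$chrom[run[1L]],
                    snp_index_start = run[1L],
                    snp_index_end = run[L],
                    bp_start = info$bp[run[1L]],
                    bp_end = info$bp[run[L]],
                    snp_ids = paste(info$id[run], collapse = ","),
                    haplotype = hs@haplotypes[h],
                    frequency = hs@freqs[h],
                    or = res@oddsRatio, ci_low = res@ciLow,
                    ci_high = res@ciHigh, p = res@p,
                    length = L, stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out <- out[order(out$p, -out$length, out$haplotype), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Verify a top haplotype hit against single-SNP effects
#'
#' The best SNP is the constituent SNP with the smallest additive Wald
#' p-value (or the best SNP of a supplied wider set with
#' \code{bestFrom = "regional"}). The hit's dosage is then retested by the
#' 1-df likelihood-ratio test adjusted for that SNP plus any
#' \code{indexSnps}; if a local-ancestry track is given, the mean expected
#' European dosage over the hit's constituent SNPs is appended as an extra
#' covariate and the adjusted test rerun.
#'
#' @param hit one row of an \code{\link{exhaustiveHaplotypeSearch}} result.
#' @param gm the \linkS4class{GenotypeMatrix} the hit came from.
#' @param covariates covariate data.frame (default from \code{gm}).
#' @param labels 0/1 phenotype (default from \code{gm}).
#' @param indexSnps optional SNP ids always adjusted for (known risk
#'   variants).
#' @param bestFrom choose the best SNP among the hit's constituent SNPs
#'   ("contained", default) or among \code{regionalSnps} ("regional").
#' @param regionalSnps SNP ids of the surrounding region (needed for
#'   \code{bestFrom = "regional"}).
#' @param track optional \linkS4class{LocalAncestryTrack}.
#' @return the hit row with columns \code{best_snp}, \code{adjusted_for},
#'   \code{adj_or}, \code{adj_ci_low}, \code{adj_ci_high}, \code{adj_p},
#'   \code{adj_note} and, when a track is supplied, \code{la_adj_p} and
#'   \code{la_adj_or} appended.
#' @export
verifyTopHit <- function(hit, gm, covariates = covariateTable(gm),
                         labels = phenotype(gm), indexSnps = NULL,
                         bestFrom = c("contained", "regional"),
                         regionalSnps = NULL, track = NULL) {
    bestFrom <- match.arg(bestFrom)
    info <- snpInfo(gm)
    calls <- genotypeCalls(gm)
    run <- hit$snp_index_start:hit$snp_index_end
    alle <- rbind(info$allele1[run], info$allele2[run])
    hs <- emFit(calls[, run, drop = FALSE], alleles = alle)
    h <- match(hit$haplotype, hs@haplotypes)
    if (is.na(h))
        stop("hit haplotype not found in the refitted window",
             call. = FALSE)
    dosage <- hs@dosages[, h]
    candIds <- if (bestFrom == "contained") info$id[run] else {
        if (is.null(regionalSnps))
            stop("bestFrom = 'regional' needs regionalSnps", call. = FALSE)
        regionalSnps
    }
    snpWaldP <- vapply(candIds, function(id) {
        j <- match(id, info$id)
        g <- calls[, j]
        res <- tryCatch(
            haplotypeSpecificTest(pmin(pmax(g, 0), 2), covariates, labels,
                                  term = id),
            error = function(e) NULL)
        if (is.null(res)) NA_real_ else res@p
    }, numeric(1))
    bestSnp <- candIds[which.min(snpWaldP)]
    adjustIds <- unique(c(bestSnp, indexSnps))
    A <- calls[, match(adjustIds, info$id), drop = FALSE]
    colnames(A) <- adjustIds
    res <- snpAdjustedLrTest(dosage, A, covariates, labels,
                             term = hit$haplotype)
    hit$best_snp <- bestSnp
    hit$adjusted_for <- paste(adjustIds, collapse = ",")
    hit$adj_or <- res@oddsRatio
    hit$adj_ci_low <- res@ciLow
    hit$adj_ci_high <- res@ciHigh
    hit$adj_p <- res@p
    hit$adj_note <- res@note
    if (!is.null(track)) {
        la <- localAncestryCovariate(track,
                                     strsplit(hit$snp_ids, ",")[[1L]])
        cov2 <- cbind(as.data.frame(covariates), local_ancestry = la)
        res2 <- snpAdjustedLrTest(dosage, A, cov2, labels,
                                  term = hit$haplotype)
        hit$la_adj_or <- res2@oddsRatio
        hit$la_adj_p <- res2@p
    }
    hit
}

#' Local-ancestry covariate for a haplotype's constituent SNPs
#'
#' Per SNP, the expected number of European-allele copies is
#' \code{p1 + 2 p2}; the covariate is the mean of this expectation over
#' the haplotype's constituent SNPs.
#'
#' @param track a \linkS4class{LocalAncestryTrack}.
#' @param snpIds constituent SNP ids (all must be present in the track).
#' @return per-sample numeric covariate.
#' @examples
#' # posteriors (0.25, 0.5, 0.25) at every SNP give covariate 1
#' @export
localAncestryCovariate <- function(track, snpIds) {
    j <- match(snpIds, track@snpIds)
    if (anyNA(j))
        stop("SNP(s) missing from the local-ancestry track: ",
             paste(snpIds[is.na(j)], collapse = ", "), call. = FALSE)
    expEur <- track@p1[, j, drop = FALSE] + 2 * track@p2[, j, drop = FALSE]
    rowMeans(expEur)
}

#' Exhaustive haplotype scan around known risk SNPs
#'
#' Builds a region of \code{flank} bp on each side of every index SNP
#' (overridable per SNP through \code{wideFlank}, e.g. a 2 Mb flank for
#' 8q24-like regions), runs \code{\link{exhaustiveHaplotypeSearch}}, and
#' verifies each region's top hit with the index SNP in the adjustment
#' set. Index SNPs absent from the map and without a usable position are
#' skipped with a message.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param indexSnps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{bp} (\code{chrom}/\code{bp} may be NA for SNPs present in the
#'   map).
#' @param flank flank size in bp (default 250000).
#' @param wideFlank named numeric: per-snp_id flank overrides.
#' @param covariates,labels as elsewhere.
#' @param lenMin,lenMax,freqThreshold passed to the search.
#' @param track optional \linkS4class{LocalAncestryTrack}.
#' @return named list (by snp_id); each element has the ranked \code{hits}
#'   table, the \code{region} used, and the verified \code{top} row.
#' @export
knownRegionScan <- function(gm, indexSnps, flank = 250000,
                            wideFlank = numeric(0),
                            covariates = covariateTable(gm),
                            labels = phenotype(gm), lenMin = 2L,
                            lenMax = 10L, freqThreshold = 0.01,
                            track = NULL) {
    info <- snpInfo(gm)
    out <- list()
    for (r in seq_len(nrow(indexSnps))) {
        id <- indexSnps$snp_id[r]
        j <- match(id, info$id)
        chrom <- if (!is.na(j)) info$chrom[j] else indexSnps$chrom[r]
        bp <- if (!is.na(j)) info$bp[j] else indexSnps$bp[r]
        if (is.na(chrom) || is.na(bp)) {
            message("knownRegionScan: index SNP ", id,
                    " absent and unpositioned; skipped")
            next
        }
        fl <- if (id %in% names(wideFlank)) wideFlank[[id]] else flank
        region <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(max(1, bp - fl), bp + fl))
        hits <- tryCatch(
            exhaustiveHaplotypeSearch(gm, region, covariates, labels,
                                      lenMin, lenMax, freqThreshold),
            error = function(e) NULL)
        if (is.null(hits) || nrow(hits) == 0L) {
            out[[id]] <- list(region = region, hits = NULL, top = NULL)
            next
        }
        idxAdj <- if (!is.na(j)) id else NULL
        top <- verifyTopHit(hits[1L, ], gm, covariates, labels,
                            indexSnps = idxAdj, track = track)
        out[[id]] <- list(region = region, hits = hits, top = top)
    }
    out
}
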