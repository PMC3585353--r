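# Fixed-width sliding windows along each chromosome and the per-window
# E-M + global-test scan.

#' Enumerate sliding windows
#'
#' Per chromosome with n SNPs, emits max(0, n - w + 1) windows of w
#' consecutive SNPs advancing one SNP at a time; windows never span
#' chromosomes.
#'
#' @param snpCounts named integer vector of SNP counts per chromosome
#'   (names are chromosome labels; unnamed input is labelled 1, 2, ...).
#' @param w window size in SNPs (>= 2, default 5).
#' @return data.frame with columns \code{chrom}, \code{snp_index_start},
#'   \code{snp_index_end} (1-based inclusive indices into the
#'   chromosome's SNP order); the total window count is
#'   \code{attr(x, "total")}.
#' @examples
#' nrow(makeWindows(c(chr22 = 15649)))   # 15645
#' @export
makeWindows <- function(snpCounts, w = 5L) {
    w <- as.integer(w)
    stopifnot(w >= 2L)
    if (is.null(names(snpCounts)))
        names(snpCounts) <- as.character(seq_along(snpCounts))
    out <- do.call(rbind, lapply(names(snpCounts), function(ch) {
        n <- as.integer(snpCounts[[ch]])
        k <- max(0L, n - w + 1L)
        if (k == 0L) return(NULL)
        data.frame(chrom = ch, snp_index_start = seq_len(k),
                   snp_index_end = seq_len(k) + w - 1L,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(out))
        out <- data.frame(chrom = character(0),
                          snp_index_start = integer(0),
                          snp_index_end = integer(0))
    attr(out, "total") <- nrow(out)
    out
}

# Per-window E-M fits and global-test design blocks, computed once and
# shared between the observed scan and the permutation scan. Internal.
windowDesigns <- function(gm, w = 5L, freqThreshold = 0.01,
                          excludeSnps = NULL) {
    info <- snpInfo(gm)
    if (!is.null(excludeSnps)) {
        keep <- !(info$id %in% excludeSnps)
        gm <- gm[keep, ]
        info <- info[keep, , drop = FALSE]
    }
    calls <- genotypeCalls(gm)
    wins <- makeWindows(table(factor(info$chrom, levels = unique(info$chrom))),
                        w = w)
    chromOffset <- c(0L, cumsum(table(factor(info$chrom,
                                             levels = unique(info$chrom)))))
    names(chromOffset) <- c(unique(info$chrom), "_end")
    n <- nrow(wins)
    dosage <- vector("list", n)
    kCommon <- integer(n); df <- integer(n)
    status <- character(n)
    bpStart <- integer(n); bpEnd <- integer(n); snpIds <- character(n)
    for (i in seq_len(n)) {
        off <- chromOffset[[wins$chrom[i]]]
        idx <- (off + wins$snp_index_start[i]):(off + wins$snp_index_end[i])
        bpStart[i] <- info$bp[idx[1L]]
        bpEnd[i] <- info$bp[idx[length(idx)]]
        snpIds[i] <- paste(info$id[idx], collapse = ",")
        sub <- calls[, idx, drop = FALSE]
        mono <- all(vapply(seq_len(ncol(sub)), function(j) {
            v <- sub[, j]; length(unique(v[!is.na(v)])) <= 1L
        }, logical(1)))
        if (mono) {
            status[i] <- "skipped_monomorphic"
            kCommon[i] <- 1L
            next
        }
        alle <- rbind(info$allele1[idx], info$allele2[idx])
        hs <- emFit(sub, alleles = alle)
        if (!hs@converged) {
            status[i] <- "skipped_unconverged"
            next
        }
        ch <- commonHapIndices(hs, freqThreshold)
        kCommon[i] <- length(ch$common)
        if (length(ch$common) <= 1L) {
            status[i] <- "skipped_df0"
            next
        }
        D <- hs@dosages[, ch$nonref, drop = FALSE]
        colnames(D) <- paste0("hap_", hs@haplotypes[ch$nonref])
        if (anyNA(D)) {
            status[i] <- "skipped_unconverged"
            next
        }
        dosage[[i]] <- D
        df[i] <- length(ch$common) - 1L
        status[i] <- "ok"
    }
    wins$bp_start <- bpStart; wins$bp_end <- bpEnd
    wins$snp_ids <- snpIds
    wins$k_common <- kCommon
    wins$df <- df
    wins$status <- status
    list(windows = wins, dosage = dosage)
}

#' Sliding-window global haplotype scan
#'
#' For every window of \code{w} consecutive SNPs: fit the window's
#' haplotype frequencies and dosages by E-M (cases and controls pooled),
#' drop haplotypes at or below \code{freqThreshold}, and run the
#' covariate-adjusted global likelihood-ratio test of the remaining
#' haplotype dosages. Windows that cannot be tested are reported with a
#' status flag instead of aborting the scan: \code{skipped_monomorphic}
#' (no variation), \code{skipped_unconverged} (E-M or fit failure),
#' \code{skipped_df0} (fewer than two common haplotypes).
#'
#' @param gm a \linkS4class{GenotypeMatrix} that already passed QC, with
#'   phenotype in its sample metadata.
#' @param covariates covariate data.frame (default: the covariate columns
#'   of \code{gm}'s sample metadata).
#' @param w window size in SNPs (default 5).
#' @param freqThreshold common-haplotype frequency cutoff (strict ">",
#'   default 0.01).
#' @param excludeSnps optional SNP ids to drop before windowing.
#' @return data.frame with one row per window: \code{chrom},
#'   \code{snp_index_start}, \code{snp_index_end}, \code{bp_start},
#'   \code{bp_end}, \code{snp_ids}, \code{k_common}, \code{df},
#'   \code{p_global}, \code{status}.
#' @export
scanChromosome <- function(gm, covariates = covariateTable(gm), w = 5L,
                           freqThreshold = 0.01, excludeSnps = NULL) {
    labels <- phenotype(gm)
    if (anyNA(labels))
        stop("scanChromosome: missing phenotypes", call. = FALSE)
    wd <- windowDesigns(gm, w = w, freqThreshold = freqThreshold,
                        excludeSnps = excludeSnps)
    wins <- wd$windows
    covX <- covariateDesign(covariates, n = length(labels))
    assertFullRank(covX, "covariate design")
    p <- rep(NA_real_, nrow(wins))
    ok <- which(wins$status == "ok")
    if (length(ok)) {
        # same code path as the permutation scan, with the observed labels
        # as the single "replicate"
        P <- cpp_perm_scan(covX, wd$dosage[ok],
                           matrix(as.numeric(labels), ncol = 1L),
                           wins$df[ok])
        p[ok] <- pmax(as.numeric(P[1L, ]), .Machine$double.xmin)
        failed <- ok[is.na(P[1L, ])]
        wins$status[failed] <- "skipped_unconverged"
        p[failed] <- NA_real_
    }
    wins$p_global <- p
    wins[, c("chrom", "snp_index_start", "snp_index_end", "bp_start",
             "bp_end", "snp_ids", "k_common", "df", "p_global", "status")]
}

#' Manhattan-style plot of a sliding-window scan
#'
#' @param scan result of \code{\link{scanChromosome}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the plotted data.
#' @importFrom graphics plot abline
#' @export
plotScan <- function(scan, ...) {
    ok <- scan$status == "ok"
    x <- (scan$bp_start + scan$bp_end) / 2
    y <- -log10(scan$p_global)
    plot(x[ok], y[ok], pch = 20, cex = 0.5,
         xlab = "position (bp)",
         ylab = expression(-log[10](italic(p))), ...)
    invisible(data.frame(bp = x[ok], neglog10p = y[ok]))
}
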