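#' Analysis window around an inversion
#'
#' The bins the inversion overlaps extended by `sideBins` on each side
#' (default 62, i.e. ~2.5 Mb at 40 kb), clipped to the chromosome.
#'
#' @param inv a single-row inversion `GRanges`.
#' @param binsize bin width in bp.
#' @param sideBins margin in bins.
#' @param nBinsTotal number of bins on the chromosome.
#' @return integer vector of 0-based bin indices.
#' @export
inversionWindow <- function(inv, binsize = 40000L, sideBins = 62L,
                            nBinsTotal = Inf) {
    stopifnot(S4Vectors::mcols(inv)$svtype == "INV")
    b <- svToBins(inv, binsize)
    seq(max(0, min(b) - sideBins), min(nBinsTotal - 1, max(b) + sideBins))
}

#' Per-bin-pair Pearson correlation of contacts with inversion genotype
#'
#' For every bin pair in the window, the Pearson correlation between
#' per-sample contact values and inversion dosage. Samples with missing
#' dosage are dropped; pairs with a missing contact in some sample drop
#' those samples pairwise. Zero-variance cells are flagged missing.
#'
#' @param cohort a normalized [HiCCohort-class].
#' @param inv a single-row inversion `GRanges` with dosages for the
#'   cohort samples.
#' @param window 0-based bin indices from [inversionWindow()].
#' @return an `InversionCorrelationMap` list: `r` (window x window
#'   matrix, `NA` where undefined), `bins`, `breakpointBins` (first and
#'   last inversion bin), `n`.
#' @export
genotypeCorrelationMap <- function(cohort, inv, window = NULL) {
    dos <- svDosage(inv)[1, sampleIds(cohort)]
    use <- which(!is.na(dos))
    if (length(use) < 3) {
        stop("need >= 3 samples with non-missing inversion dosage")
    }
    if (var(dos[use]) == 0) {
        stop("inversion dosage is constant in tested samples")
    }
    if (is.null(window)) {
        window <- inversionWindow(inv, binSize(cohort),
                                  nBinsTotal = nBins(cohort))
    }
    vals <- lapply(sampleIds(cohort)[use], function(s) {
        contactValues(cohort[[s]], na = TRUE)
    })
    d <- dos[use]
    W <- length(window)
    r <- matrix(NA_real_, W, W)
    for (a in seq_len(W)) {
        for (b in a:W) {
            y <- vapply(vals, function(v) {
                v[window[a] + 1L, window[b] + 1L]
            }, numeric(1))
            ok <- !is.na(y)
            if (sum(ok) < 3 || var(y[ok]) == 0 || var(d[ok]) == 0) next
            r[a, b] <- r[b, a] <- cor(y[ok], d[ok])
        }
    }
    invBins <- svToBins(inv, binSize(cohort))
    structure(list(
        r = r, bins = as.integer(window),
        breakpointBins = c(min(invBins), max(invBins)),
        n = length(use)),
        class = "InversionCorrelationMap")
}

#' @export
print.InversionCorrelationMap <- function(x, ...) {
    cat("InversionCorrelationMap:", length(x$bins), "bins,",
        sum(!is.na(x$r[upper.tri(x$r, diag = TRUE)])), "defined pairs,",
        "n =", x$n, "\n")
    invisible(x)
}

#' Top correlated bin pairs of an inversion correlation map, BEDPE-style
#'
#' @param map an `InversionCorrelationMap`.
#' @param chrom chromosome name.
#' @param binsize bin width in bp.
#' @param topFrac fraction of defined pairs to keep, ranked by `|r|`.
#' @return data.frame in BEDPE column order with an `r` score column.
#' @export
topCorrelatedPairs <- function(map, chrom = "chr1", binsize = 40000L,
                               topFrac = 0.1) {
    ut <- which(upper.tri(map$r, diag = TRUE) & !is.na(map$r),
                arr.ind = TRUE)
    if (!nrow(ut)) {
        return(data.frame())
    }
    rv <- map$r[ut]
    keep <- order(abs(rv), decreasing = TRUE)
    keep <- keep[seq_len(max(1, floor(length(keep) * topFrac)))]
    b1 <- map$bins[ut[keep, 1]]
    b2 <- map$bins[ut[keep, 2]]
    data.frame(
        chrom1 = chrom, start1 = b1 * binsize, end1 = (b1 + 1) * binsize,
        chrom2 = chrom, start2 = b2 * binsize, end2 = (b2 + 1) * binsize,
        r = rv[keep])
}

#' Mirror contacts inside an inversion for visual comparison
#'
#' Reverses the bin order inside the inverted interval and re-indexes the
#' contact matrix accordingly, so a carrier matrix can be compared
#' bin-for-bin with a reference-orientation matrix. Applying the mirror
#' twice restores the original matrix.
#'
#' @param m a [ContactMatrix-class].
#' @param inv a single-row inversion `GRanges`.
#' @param binsize bin width in bp (default from `m`).
#' @return the mirrored [ContactMatrix-class].
#' @export
mirrorInversionContacts <- function(m, inv, binsize = binSize(m)) {
    b <- svToBins(inv, binsize)
    nb <- nBins(m)
    if (max(b) >= nb) {
        stop("inversion extends beyond the matrix")
    }
    perm <- seq_len(nb)
    idx <- (min(b):max(b)) + 1L
    perm[idx] <- rev(idx)
    v <- contactValues(m)[perm, perm]
    ContactMatrix(v, chrom = chromName(m), binsize = binSize(m),
                  missingBins = missingBins(m)[perm],
                  sampleId = sampleId(m))
}
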