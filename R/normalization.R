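#' Per-bin covariates for count normalization
#'
#' @param effLength per-bin effective (restriction-fragment) length.
#' @param gc per-bin GC fraction, in `[0, 1]`.
#' @param mappability per-bin mappability score.
#' @return a `BinCovariates` data.frame.
#' @export
binCovariates <- function(effLength, gc, mappability) {
    stopifnot(length(effLength) == length(gc),
              length(gc) == length(mappability))
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
        stop("gc must lie in [0, 1]")
    }
    structure(
        data.frame(effLength = effLength, gc = gc,
                   mappability = mappability),
        class = c("BinCovariates", "data.frame"))
}

#' Remove per-bin coverage bias by Poisson regression on bin covariates
#'
#' Regresses raw cis counts on the log pairwise products of effective
#' length, GC content and mappability (Poisson GLM, log link) and divides
#' each count by its fitted bias, rescaled so the overall mean is
#' preserved. Bins with a non-positive covariate cannot be modelled and
#' are flagged missing with a warning.
#'
#' @param m a [ContactMatrix-class] of raw counts.
#' @param cov a [binCovariates()] table with one row per bin.
#' @return a bias-corrected [ContactMatrix-class].
#' @export
hicnormNormalize <- function(m, cov) {
    nb <- nBins(m)
    if (nrow(cov) != nb) {
        stop("covariate rows (", nrow(cov), ") must equal bins (", nb, ")")
    }
    bad <- cov$effLength <= 0 | cov$gc <= 0 | cov$mappability <= 0
    bad[is.na(bad)] <- TRUE
    newBad <- bad & !missingBins(m)
    if (any(newBad)) {
        warning(sum(newBad), " bin(s) with non-positive covariates ",
                "flagged missing")
    }
    miss <- missingBins(m) | bad
    good <- which(!miss)
    v <- contactValues(m)
    out <- matrix(0, nb, nb)
    if (length(good) >= 2) {
        ut <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
        ut <- ut[ut[, 1] %in% good & ut[, 2] %in% good, , drop = FALSE]
        y <- v[ut]
        X <- data.frame(
            y = y,
            llen = log(cov$effLength[ut[, 1]] * cov$effLength[ut[, 2]]),
            lgc = log(cov$gc[ut[, 1]] * cov$gc[ut[, 2]]),
            lmap = log(cov$mappability[ut[, 1]] * cov$mappability[ut[, 2]]))
        # drop constant covariate columns (e.g. identical bins) to keep the
        # design full rank; with no informative column the bias is flat
        keep <- vapply(X[-1], function(z) var(z) > 1e-12, logical(1))
        form <- if (any(keep)) {
            stats::as.formula(paste("y ~", paste(names(X)[-1][keep],
                                                 collapse = " + ")))
        } else {
            y ~ 1
        }
        # suppress the non-integer warning: normalized inputs are legal
        fit <- suppressWarnings(
            stats::glm(form, family = stats::poisson(), data = X))
        bias <- stats::fitted(fit)
        norm <- y * mean(bias) / bias
        out[cbind(ut[, 1], ut[, 2])] <- norm
        out[cbind(ut[, 2], ut[, 1])] <- norm
    }
    ContactMatrix(out, chrom = chromName(m), binsize = binSize(m),
                  missingBins = miss, sampleId = sampleId(m))
}

# entries of band d (distance |i - j| = d) as a (nBins - d) x nSamples matrix
.bandEntries <- function(mats, d) {
    nb <- nrow(mats[[1]])
    i <- seq_len(nb - d)
    j <- i + d
    out <- vapply(mats, function(v) v[cbind(i, j)], numeric(nb - d))
    matrix(out, nrow = nb - d)  # keep matrix shape for 1-entry bands
}

# NA-aware mean-quantile normalization of the columns of a matrix;
# with equal non-missing counts this is classical quantile normalization
.quantileNormalizeBand <- function(x) {
    ns <- ncol(x)
    k <- colSums(!is.na(x))
    K <- max(k)
    grid <- seq(0, 1, length.out = max(K, 2L))
    qs <- vapply(seq_len(ns), function(s) {
        quantile(x[, s], probs = grid, na.rm = TRUE, names = FALSE, type = 7)
    }, numeric(length(grid)))
    ref <- rowMeans(qs)
    out <- x
    for (s in seq_len(ns)) {
        obs <- which(!is.na(x[, s]))
        if (!length(obs)) next
        # ties broken by position so the post-normalization multiset is
        # exactly equal across samples
        r <- rank(x[obs, s], ties.method = "first")
        p <- if (length(obs) == 1L) 0.5 else (r - 1) / (length(obs) - 1)
        out[obs, s] <- approx(grid, ref, xout = p, rule = 2)$y
    }
    out
}

#' Band-wise quantile normalization across a Hi-C cohort
#'
#' For each genomic distance `d`, the entries at `|i - j| = d` form one
#' vector per sample; these are quantile-normalized across samples to the
#' mean quantile profile, so that after normalization every sample has the
#' same distribution of contacts at each distance. Bands where any sample
#' has fewer than `minBandEntries` non-missing entries are left unchanged.
#' Entries touching a missing bin do not participate.
#'
#' @param cohort a [HiCCohort-class] (>= 2 samples).
#' @param minBandEntries minimum non-missing entries per sample per band.
#' @return a normalized [HiCCohort-class].
#' @export
bandQuantileNormalize <- function(cohort, minBandEntries = 10L) {
    ns <- nSamples(cohort)
    if (ns < 2) {
        stop("band-wise quantile normalization needs >= 2 samples")
    }
    nb <- nBins(cohort)
    mats <- lapply(cohort@matrices, contactValues, na = TRUE)
    for (d in 0:(nb - 1)) {
        x <- .bandEntries(mats, d)
        if (min(colSums(!is.na(x))) < minBandEntries) next
        xn <- .quantileNormalizeBand(x)
        i <- seq_len(nb - d)
        j <- i + d
        for (s in seq_len(ns)) {
            mats[[s]][cbind(i, j)] <- xn[, s]
            mats[[s]][cbind(j, i)] <- xn[, s]
        }
    }
    .rebuildCohort(cohort, mats)
}

.rebuildCohort <- function(cohort, mats) {
    newMats <- lapply(seq_along(mats), function(s) {
        old <- cohort@matrices[[s]]
        v <- mats[[s]]
        v[is.na(v)] <- 0
        v <- pmax(v, 0)
        ContactMatrix(v, chrom = chromName(old), binsize = binSize(old),
                      missingBins = missingBins(old),
                      sampleId = sampleId(old))
    })
    HiCCohort(newMats, sampleIds = sampleIds(cohort),
              batch = batches(cohort))
}

#' Remove per-band batch location/scale shifts across a cohort
#'
#' For every genomic-distance band, entries of each batch are centered and
#' rescaled to the pooled cross-batch band mean and standard deviation,
#' removing location and scale differences attributable to processing
#' batch while preserving the grand band mean. A batch with a single
#' sample only receives the location adjustment (warning).
#'
#' @param cohort a [HiCCohort-class] with >= 2 batches.
#' @return a batch-corrected [HiCCohort-class].
#' @export
batchCorrectBands <- function(cohort) {
    bt <- batches(cohort)
    ub <- unique(bt)
    if (length(ub) < 2) {
        stop("batch correction needs >= 2 batches")
    }
    single <- ub[vapply(ub, function(b) sum(bt == b) == 1L, logical(1))]
    if (length(single)) {
        warning("batch(es) with a single sample: scale step skipped for ",
                paste(single, collapse = ", "))
    }
    nb <- nBins(cohort)
    mats <- lapply(cohort@matrices, contactValues, na = TRUE)
    for (d in 0:(nb - 1)) {
        x <- .bandEntries(mats, d)
        all.v <- x[!is.na(x)]
        if (length(all.v) < 2) next
        gm <- mean(all.v)
        gs <- sd(all.v)
        for (b in ub) {
            cols <- which(bt == b)
            xb <- x[, cols, drop = FALSE]
            bv <- xb[!is.na(xb)]
            if (!length(bv)) next
            mb <- mean(bv)
            sb <- sd(bv)
            scale.ok <- length(cols) > 1L && !is.na(sb) && sb > 0 &&
                !is.na(gs) && gs > 0
            xb <- if (scale.ok) (xb - mb) / sb * gs + gm else xb - mb + gm
            x[, cols] <- xb
        }
        i <- seq_len(nb - d)
        j <- i + d
        for (s in seq_len(ncol(x))) {
            mats[[s]][cbind(i, j)] <- x[, s]
            mats[[s]][cbind(j, i)] <- x[, s]
        }
    }
    .rebuildCohort(cohort, mats)
}

#' Element-wise average contact matrix over a subset of samples
#'
#' Each element is the mean over samples where it is non-missing; it is
#' missing only when missing in every selected sample.
#'
#' @param cohort a [HiCCohort-class].
#' @param samples sample ids to average.
#' @return a [ContactMatrix-class] with sampleId `"group_mean"`.
#' @export
averageGroupMatrix <- function(cohort, samples) {
    if (!length(samples)) {
        stop("sample subset is empty")
    }
    unknown <- setdiff(samples, sampleIds(cohort))
    if (length(unknown)) {
        stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    }
    mats <- lapply(samples, function(s) contactValues(cohort[[s]], na = TRUE))
    nb <- nBins(cohort)
    sum.v <- matrix(0, nb, nb)
    cnt <- matrix(0, nb, nb)
    for (v in mats) {
        p <- !is.na(v)
        v[!p] <- 0
        sum.v <- sum.v + v
        cnt <- cnt + p
    }
    avg <- ifelse(cnt > 0, sum.v / pmax(cnt, 1), 0)
    missAll <- Reduce(`&`, lapply(samples, function(s) {
        missingBins(cohort[[s]])
    }))
    ContactMatrix(avg, chrom = chromName(cohort), binsize = binSize(cohort),
                  missingBins = missAll, sampleId = "group_mean")
}
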