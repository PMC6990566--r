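#' Ancestry principal components from a genotype matrix
#'
#' Column-centered PCA of a samples x variants dosage matrix.
#' Zero-variance variants are dropped. Signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param genotypes numeric matrix, samples in rows.
#' @param k number of components (default 2, the covariate model with the
#'   least genomic inflation; `k = 0` returns an empty block).
#' @return list with `scores` (samples x k), `propVar` (per-PC proportion
#'   of variance).
#' @export
ancestryPCs <- function(genotypes, k = 2L) {
    genotypes <- as.matrix(genotypes)
    if (k == 0) {
        return(list(scores = matrix(numeric(0), nrow(genotypes), 0),
                    propVar = numeric(0)))
    }
    v <- apply(genotypes, 2, var)
    keep <- which(!is.na(v) & v > 0)
    if (!length(keep)) {
        stop("genotype matrix has no variable columns")
    }
    pc <- prcomp(genotypes[, keep, drop = FALSE], center = TRUE,
                 scale. = FALSE)
    k <- min(k, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    for (c in seq_len(k)) {
        load <- pc$rotation[, c]
        if (load[which.max(abs(load))] < 0) {
            scores[, c] <- -scores[, c]
        }
    }
    propVar <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    rownames(scores) <- rownames(genotypes)
    list(scores = scores, propVar = propVar)
}

#' Surrogate-variable block from region statistics
#'
#' Top principal components of the samples x region-statistic table,
#' usable as an additional covariate block to absorb unmodelled
#' chromosome-wide variation. Off by default in the association model:
#' with 19 samples it saturates the design, and in the covariate
#' selection it does not reduce genomic inflation below the
#' two-ancestry-PCs-plus-sex model.
#'
#' @param valuesMat SVs x samples matrix of region statistics.
#' @param k number of surrogate components.
#' @return samples x k score matrix.
#' @export
surrogateVariables <- function(valuesMat, k = 2L) {
    ancestryPCs(t(valuesMat), k = k)$scores
}

#' Covariate set for association models
#'
#' @param pcs samples x k matrix of ancestry PC scores (or `NULL`).
#' @param sex 0/1 coded sex per sample (or `NULL`).
#' @param sva optional samples x m surrogate-variable matrix.
#' @return numeric covariate matrix (possibly zero columns).
#' @export
covariateSet <- function(pcs = NULL, sex = NULL, sva = NULL) {
    blocks <- list()
    if (!is.null(pcs) && NCOL(pcs) > 0) {
        pcs <- as.matrix(pcs)
        colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
        blocks$pcs <- pcs
    }
    if (!is.null(sex)) {
        blocks$sex <- matrix(as.numeric(sex), ncol = 1,
                             dimnames = list(NULL, "sex"))
    }
    if (!is.null(sva) && NCOL(sva) > 0) {
        sva <- as.matrix(sva)
        colnames(sva) <- paste0("SV", seq_len(ncol(sva)))
        blocks$sva <- sva
    }
    if (!length(blocks)) {
        return(matrix(numeric(0), 0, 0))
    }
    do.call(cbind, blocks)
}

#' Ordinary least squares association of a region statistic with dosage
#'
#' The default `"dosageOnStat"` orientation regresses dosage on the contact
#' statistic plus covariates and reports the statistic term; the
#' `"standard"` orientation regresses the statistic on dosage plus
#' covariates and reports the dosage term. The two give identical
#' p-values without covariates but differ (slightly) with them. Samples
#' with a missing statistic, dosage or covariate are dropped listwise.
#'
#' @param values per-sample region statistic.
#' @param dosage per-sample SV dosage (0/1/2).
#' @param covariates covariate matrix from [covariateSet()] or `NULL`.
#' @param orientation `"dosageOnStat"` or `"standard"`.
#' @return one-row data.frame: `beta`, `se`, `p`, `n`, `orientation`.
#' @export
regressRegion <- function(values, dosage, covariates = NULL,
                          orientation = c("dosageOnStat", "standard")) {
    orientation <- match.arg(orientation)
    n0 <- length(values)
    if (length(dosage) != n0) {
        stop("values and dosage lengths differ")
    }
    C <- if (is.null(covariates) || NCOL(covariates) == 0) {
        matrix(numeric(0), n0, 0)
    } else {
        as.matrix(covariates)
    }
    ok <- !is.na(values) & !is.na(dosage)
    if (ncol(C)) {
        ok <- ok & complete.cases(C)
    }
    y.stat <- values[ok]
    dos <- dosage[ok]
    C <- C[ok, , drop = FALSE]
    if (length(unique(dos)) < 2) {
        stop("monomorphic in tested samples")
    }
    if (var(y.stat) == 0) {
        stop("constant contact statistic in tested samples")
    }
    if (orientation == "dosageOnStat") {
        X <- cbind(`(Intercept)` = 1, stat = y.stat, C)
        y <- dos
        term <- "stat"
    } else {
        X <- cbind(`(Intercept)` = 1, dosage = dos, C)
        y <- y.stat
        term <- "dosage"
    }
    p.par <- ncol(X)
    if (length(y) < p.par + 1) {
        stop("too few samples (", length(y), ") for ", p.par,
             " model parameters")
    }
    qrX <- qr(X)
    if (qrX$rank < p.par) {
        drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p.par)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(drop, collapse = ", "))
    }
    fit <- lm(y ~ X - 1)
    cf <- summary(fit)$coefficients
    rownames(cf) <- colnames(X)
    data.frame(beta = cf[term, 1], se = cf[term, 2], p = cf[term, 4],
               n = length(y), orientation = orientation,
               stringsAsFactors = FALSE)
}

#' Permutation null for association statistics
#'
#' For each SV the dosage vector is shuffled across samples `nPerm` times
#' with a seeded generator and the full regression rerun, yielding an
#' empirical null distribution of coefficients and p-values.
#'
#' @param valuesMat SVs x samples matrix of region statistics.
#' @param dosageMat SVs x samples matrix of dosages.
#' @param covariates covariate matrix or `NULL`.
#' @param nPerm permutations per SV (default 100).
#' @param seed integer seed.
#' @param orientation passed to [regressRegion()].
#' @return data.frame with columns `sv`, `perm`, `beta`, `p`; SVs whose
#'   permuted regression fails are recorded in the `skipped` attribute.
#' @export
permutationNull <- function(valuesMat, dosageMat, covariates = NULL,
                            nPerm = 100L, seed = 1L,
                            orientation = c("dosageOnStat", "standard")) {
    orientation <- match.arg(orientation)
    if (nPerm < 1) {
        stop("nPerm must be >= 1")
    }
    valuesMat <- rbind(valuesMat)
    dosageMat <- rbind(dosageMat)
    set.seed(as.integer(seed))
    ns <- ncol(valuesMat)
    res <- vector("list", nrow(valuesMat) * nPerm)
    skipped <- character(0)
    svNames <- rownames(valuesMat)
    if (is.null(svNames)) {
        svNames <- paste0("sv", seq_len(nrow(valuesMat)))
    }
    k <- 0
    for (s in seq_len(nrow(valuesMat))) {
        for (r in seq_len(nPerm)) {
            perm <- sample(ns)
            k <- k + 1
            res[[k]] <- tryCatch({
                fit <- regressRegion(valuesMat[s, ], dosageMat[s, perm],
                                     covariates,
                                     orientation = orientation)
                data.frame(sv = svNames[s], perm = r, beta = fit$beta,
                           p = fit$p, stringsAsFactors = FALSE)
            }, error = function(e) {
                NULL
            })
            if (is.null(res[[k]])) {
                skipped <- c(skipped, svNames[s])
            }
        }
    }
    out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(out)) {
        out <- data.frame(sv = character(0), perm = integer(0),
                          beta = numeric(0), p = numeric(0))
    }
    attr(out, "skipped") <- unique(skipped)
    attr(out, "seed") <- as.integer(seed)
    out
}

#' Genomic inflation factor of a p-value set
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`; a
#' calibrated test yields `lambda` near 1.
#'
#' @param p p-values in `(0, 1]`.
#' @return list with `lambda` and `n`.
#' @export
genomicInflation <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) {
        stop("no p-values supplied")
    }
    if (any(p <= 0 | p > 1)) {
        stop("p-values must lie in (0, 1]")
    }
    chi <- qchisq(1 - p, df = 1)
    list(lambda = median(chi) / qchisq(0.5, df = 1), n = length(p))
}

#' Observed-vs-null QQ coordinates on the -log10 scale
#'
#' Sorted observed p-values are paired with matched empirical quantiles
#' of the null set (the sorted null itself when lengths agree).
#'
#' @param observed observed p-values.
#' @param null empirical-null p-values.
#' @return data.frame `expected`, `observed` (-log10, ascending).
#' @export
qqPoints <- function(observed, null) {
    observed <- sort(observed[!is.na(observed)])
    null <- null[!is.na(null)]
    if (!length(observed) || !length(null)) {
        stop("both p-value sets must be non-empty")
    }
    expected <- if (length(null) == length(observed)) {
        sort(null)
    } else {
        quantile(null, probs = ppoints(length(observed)), names = FALSE,
                 type = 7)
    }
    data.frame(expected = -log10(expected), observed = -log10(observed))
}

#' Kolmogorov-Smirnov comparison of two p-value strata
#'
#' Two-sample KS test, e.g. span p-values of large (> 10 kb) versus small
#' deletions.
#'
#' @param pLarge,pSmall p-value vectors.
#' @return list with `statistic` (KS D) and `p`.
#' @export
compareSizeStrata <- function(pLarge, pSmall) {
    if (!length(pLarge) || !length(pSmall)) {
        stop("both strata must be non-empty")
    }
    ks <- suppressWarnings(ks.test(pLarge, pSmall))
    list(statistic = unname(ks$statistic), p = unname(ks$p.value))
}

#' Wilcoxon rank-sum test of a coefficient group against a null set
#'
#' Two-sided Mann-Whitney test of group coefficients against pooled
#' permutation-null coefficients. When both groups have at most 8 values
#' the null distribution of the rank sum is enumerated exhaustively
#' (ties handled exactly); otherwise the normal approximation with tie
#' correction is used.
#'
#' @param group coefficient values for the group.
#' @param null null coefficient values.
#' @return list with `statistic` (rank sum of `group`), `p`, `method`.
#' @export
groupVsNullWilcoxon <- function(group, null) {
    group <- group[!is.na(group)]
    null <- null[!is.na(null)]
    n1 <- length(group)
    n2 <- length(null)
    if (!n1 || !n2) {
        stop("both groups must be non-empty")
    }
    pooled <- c(group, null)
    r <- rank(pooled, ties.method = "average")
    W <- sum(r[seq_len(n1)])
    if (n1 <= 8 && n2 <= 8) {
        combs <- combn(n1 + n2, n1)
        Wall <- colSums(matrix(r[combs], nrow = n1))
        EW <- n1 * (n1 + n2 + 1) / 2
        p <- mean(abs(Wall - EW) >= abs(W - EW) - 1e-9)
        return(list(statistic = W, p = p, method = "exact enumeration"))
    }
    wt <- suppressWarnings(wilcox.test(group, null, exact = FALSE,
                                       correct = TRUE))
    list(statistic = W, p = wt$p.value, method = "normal approximation")
}

#' Choose the covariate model with the least genomic inflation
#'
#' Candidate covariate blocks are added one at a time (nested models,
#' starting from none); for each model the association is rerun for every
#' SV on the span and flank statistics, the genomic inflation factor is
#' computed for each region, and the model minimizing the mean of the two
#' lambdas is selected. Models whose parameter count saturates the sample
#' size are excluded with a warning.
#'
#' @param blocks ordered named list of covariate blocks (matrices or
#'   vectors, samples in rows).
#' @param spanValues,flankValues SVs x samples statistic matrices.
#' @param dosageMat SVs x samples dosage matrix.
#' @param orientation passed to [regressRegion()].
#' @return list with `chosen` (model name), `covariates` (matrix of the
#'   chosen model), `table` (per-model lambdas).
#' @export
selectCovariates <- function(blocks, spanValues, flankValues, dosageMat,
                             orientation = c("dosageOnStat", "standard")) {
    orientation <- match.arg(orientation)
    if (!length(blocks)) {
        stop("at least one candidate block is required")
    }
    ns <- ncol(dosageMat)
    models <- list(none = NULL)
    acc <- NULL
    for (b in seq_along(blocks)) {
        blk <- as.matrix(blocks[[b]])
        acc <- if (is.null(acc)) blk else cbind(acc, blk)
        models[[paste(names(blocks)[seq_len(b)], collapse = "+")]] <- acc
    }
    rows <- list()
    fits <- list()
    for (mn in names(models)) {
        C <- models[[mn]]
        nPar <- 2 + NCOL(C)
        if (nPar >= ns - 1) {
            warning("model `", mn, "` (", nPar,
                    " parameters) saturates n = ", ns, "; excluded")
            next
        }
        pv <- function(valuesMat) {
            ps <- vapply(seq_len(nrow(valuesMat)), function(s) {
                tryCatch(regressRegion(valuesMat[s, ], dosageMat[s, ], C,
                                       orientation = orientation)$p,
                         error = function(e) NA_real_)
            }, numeric(1))
            ps[!is.na(ps)]
        }
        ls <- genomicInflation(pv(spanValues))$lambda
        lf <- genomicInflation(pv(flankValues))$lambda
        rows[[mn]] <- data.frame(model = mn, lambdaSpan = ls,
                                 lambdaFlank = lf,
                                 lambdaMean = (ls + lf) / 2,
                                 stringsAsFactors = FALSE)
        fits[[mn]] <- C
    }
    if (!length(rows)) {
        stop("no candidate model fits the sample size")
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    best <- tab$model[which.min(tab$lambdaMean)]
    list(chosen = best, covariates = fits[[best]], table = tab)
}

#' Flank-width parameter sweep
#'
#' Re-derives span/flank regions and reruns the association at each
#' candidate flank width, summarizing per width the median absolute
#' coefficient and the genomic inflation factor for both regions. The
#' width maximizing the flank median absolute coefficient is flagged.
#'
#' @param widths integer vector of flank widths (bins).
#' @param cohort a normalized [HiCCohort-class].
#' @param svs SV `GRanges` (deletions).
#' @param covariates covariate matrix or `NULL`.
#' @param stat region statistic, `"mean"` or `"median"`.
#' @param orientation passed to [regressRegion()].
#' @return data.frame, one row per width, with attribute `bestWidth`.
#' @export
flankSweep <- function(widths, cohort, svs, covariates = NULL,
                       stat = "mean",
                       orientation = c("dosageOnStat", "standard")) {
    orientation <- match.arg(orientation)
    if (!length(widths)) {
        stop("at least one width is required")
    }
    rows <- lapply(widths, function(w) {
        res <- associateDeletions(cohort, svs, nFlank = w,
                                  covariates = covariates, stat = stat,
                                  orientation = orientation)
        sp <- res[res$region == "span", ]
        fl <- res[res$region == "flank", ]
        data.frame(
            width = w,
            medianAbsBetaSpan = median(abs(sp$beta)),
            medianAbsBetaFlank = median(abs(fl$beta)),
            lambdaSpan = if (nrow(sp)) {
                genomicInflation(sp$p)$lambda
            } else NA_real_,
            lambdaFlank = if (nrow(fl)) {
                genomicInflation(fl$p)$lambda
            } else NA_real_,
            nTested = length(unique(res$svId)),
            nSkipped = attr(res, "nSkipped"))
    })
    out <- do.call(rbind, rows)
    attr(out, "bestWidth") <- out$width[which.max(out$medianAbsBetaFlank)]
    out
}

#' Span/flank association for a set of deletions
#'
#' For each deletion: build the region specification, compute the
#' per-sample span and flank contact statistics, and regress against
#' dosage with the given covariates. Deletions that are untestable
#' (edge loci, monomorphic genotypes, all-missing regions) are skipped
#' and counted.
#'
#' @param cohort a normalized [HiCCohort-class].
#' @param svs SV `GRanges` (deletions) with dosage columns matching the
#'   cohort samples.
#' @param nFlank flank width in bins (default 6).
#' @param covariates covariate matrix or `NULL`.
#' @param extraMask extra 0-based bins to mask (e.g. segmental
#'   duplications).
#' @param stat `"mean"` or `"median"`.
#' @param orientation passed to [regressRegion()].
#' @return data.frame with one row per SV x region: `svId`, `region`,
#'   `beta`, `se`, `p`, `n`, `flankWidth`; attributes `nSkipped`,
#'   `skipReasons`, and `values_span` / `values_flank` (tested-SV x
#'   sample matrices of the region statistics, for permutation reuse).
#' @export
associateDeletions <- function(cohort, svs, nFlank = 6L,
                               covariates = NULL, extraMask = integer(0),
                               stat = "mean",
                               orientation = c("dosageOnStat", "standard")) {
    orientation <- match.arg(orientation)
    sampleOrder <- sampleIds(cohort)
    if (!length(svs)) {
        out <- data.frame(svId = character(0), region = character(0),
                          beta = numeric(0), se = numeric(0),
                          p = numeric(0), n = integer(0),
                          flankWidth = integer(0))
        attr(out, "nSkipped") <- 0L
        attr(out, "skipReasons") <- character(0)
        return(out)
    }
    dos <- svDosage(svs)
    if (!all(sampleOrder %in% colnames(dos))) {
        stop("cohort samples missing from SV dosage columns")
    }
    dos <- dos[, sampleOrder, drop = FALSE]
    nb <- nBins(cohort)
    # per-sample value matrices extracted once: the per-SV loop only indexes
    vals <- lapply(sampleOrder, function(s) {
        contactValues(cohort[[s]], na = TRUE)
    })
    statFun <- if (stat == "mean") {
        function(z) mean(z, na.rm = TRUE)
    } else {
        function(z) median(z, na.rm = TRUE)
    }
    pairStat <- function(pairs) {
        idx <- cbind(pairs[, 1] + 1L, pairs[, 2] + 1L)
        vapply(vals, function(v) {
            z <- v[idx]
            if (all(is.na(z))) NA_real_ else statFun(z)
        }, numeric(1))
    }
    rows <- list()
    reasons <- character(0)
    valStore <- list(span = list(), flank = list())
    for (k in seq_along(svs)) {
        id <- S4Vectors::mcols(svs)$svId[k]
        spec <- tryCatch(
            defineRegions(svs[k], binsize = binSize(cohort),
                          nFlank = nFlank, extraMask = extraMask,
                          nBinsTotal = nb),
            error = function(e) conditionMessage(e))
        if (is.character(spec)) {
            reasons <- c(reasons, setNames(spec, id))
            next
        }
        for (region in c("span", "flank")) {
            pairs <- if (region == "span") spec$spanPairs else {
                spec$flankPairs
            }
            if (!nrow(pairs)) {
                reasons <- c(reasons,
                             setNames(paste("empty", region, "set"), id))
                next
            }
            y <- pairStat(pairs)
            fit <- tryCatch(
                regressRegion(y, dos[k, ], covariates,
                              orientation = orientation),
                error = function(e) conditionMessage(e))
            if (is.character(fit)) {
                reasons <- c(reasons, setNames(fit, id))
                next
            }
            valStore[[region]][[id]] <- y
            rows[[length(rows) + 1]] <- data.frame(
                svId = id, region = region, beta = fit$beta, se = fit$se,
                p = fit$p, n = fit$n, flankWidth = as.integer(nFlank),
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) {
        do.call(rbind, rows)
    } else {
        data.frame(svId = character(0), region = character(0),
                   beta = numeric(0), se = numeric(0), p = numeric(0),
                   n = integer(0), flankWidth = integer(0))
    }
    attr(out, "nSkipped") <- length(unique(names(reasons)))
    attr(out, "skipReasons") <- reasons
    for (region in c("span", "flank")) {
        vm <- valStore[[region]]
        if (length(vm)) {
            attr(out, paste0("values_", region)) <-
                do.call(rbind, vm)
        }
    }
    out
}

#' Per-bin-pair regression coefficients around one SV
#'
#' Applies the association regression independently to every unmasked bin
#' pair inside a window around the SV (the blue-red heatmap of effect
#' sizes). Cells overlapping the SV are masked; cells whose regression
#' fails (e.g. constant contacts) are flagged invalid rather than fatal.
#'
#' @param cohort a normalized [HiCCohort-class].
#' @param sv a single-row SV `GRanges`.
#' @param windowBins margin in bins on each side of the SV.
#' @param covariates covariate matrix or `NULL`.
#' @param orientation passed to [regressRegion()].
#' @return a [CoefficientMap-class].
#' @export
perBinCoefficients <- function(cohort, sv, windowBins = 6L,
                               covariates = NULL,
                               orientation = c("dosageOnStat", "standard")) {
    orientation <- match.arg(orientation)
    dos <- svDosage(sv)[1, sampleIds(cohort)]
    svBins <- svToBins(sv, binSize(cohort))
    nb <- nBins(cohort)
    win <- seq(max(0, min(svBins) - windowBins),
               min(nb - 1, max(svBins) + windowBins))
    W <- length(win)
    inSv <- win %in% svBins
    offsets <- integer(W)
    offsets[win < min(svBins)] <- win[win < min(svBins)] - min(svBins)
    offsets[win > max(svBins)] <- win[win > max(svBins)] - max(svBins)
    vals <- lapply(sampleIds(cohort), function(s) {
        contactValues(cohort[[s]], na = TRUE)
    })
    beta <- pval <- matrix(NA_real_, W, W)
    valid <- matrix(FALSE, W, W)
    for (a in seq_len(W)) {
        for (b in a:W) {
            if (inSv[a] || inSv[b]) next
            y <- vapply(vals, function(v) {
                v[win[a] + 1L, win[b] + 1L]
            }, numeric(1))
            fit <- tryCatch(
                regressRegion(y, dos, covariates,
                              orientation = orientation),
                error = function(e) NULL)
            if (is.null(fit)) next
            beta[a, b] <- beta[b, a] <- fit$beta
            pval[a, b] <- pval[b, a] <- fit$p
            valid[a, b] <- valid[b, a] <- TRUE
        }
    }
    new("CoefficientMap", beta = beta, pval = pval, valid = valid,
        bins = as.integer(win), offsets = offsets,
        svId = as.character(S4Vectors::mcols(sv)$svId))
}

#' Aggregate coefficient maps across loci
#'
#' Maps are aligned on the left/right SV boundaries via their offset
#' coordinates (negative offsets counted from the left boundary, positive
#' from the right), collapsing SVs of different sizes onto a common grid,
#' and the cellwise median (or mean) coefficient is taken over maps where
#' the cell is valid.
#'
#' @param maps list of [CoefficientMap-class] with a shared window margin.
#' @param aggregator `"median"` (default) or `"mean"`.
#' @return a [CoefficientMap-class] on the offset grid (`svId`
#'   `"aggregate"`).
#' @export
aggregateCoefficientMaps <- function(maps, aggregator = c("median",
                                                          "mean")) {
    aggregator <- match.arg(aggregator)
    if (!length(maps)) {
        stop("no maps to aggregate")
    }
    w <- max(abs(unlist(lapply(maps, function(m) m@offsets))))
    offGrid <- c(seq(-w, -1), seq(1, w))
    G <- length(offGrid)
    stack <- array(NA_real_, c(G, G, length(maps)))
    for (m in seq_along(maps)) {
        off <- maps[[m]]@offsets
        idx <- match(off, offGrid)  # SV-interior bins (offset 0) -> NA
        b <- coefficientGrid(maps[[m]])
        for (a in seq_along(off)) {
            if (is.na(idx[a])) next
            for (c in seq_along(off)) {
                if (is.na(idx[c])) next
                stack[idx[a], idx[c], m] <- b[a, c]
            }
        }
    }
    agg <- apply(stack, c(1, 2), function(z) {
        z <- z[!is.na(z)]
        if (!length(z)) {
            return(NA_real_)
        }
        if (aggregator == "median") median(z) else mean(z)
    })
    valid <- !is.na(agg)
    beta <- agg
    beta[!valid] <- 0
    new("CoefficientMap", beta = beta, pval = matrix(NA_real_, G, G),
        valid = valid, bins = rep(NA_integer_, G),
        offsets = as.integer(offGrid), svId = "aggregate")
}
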