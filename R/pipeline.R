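#' Run the full deletion-association pipeline on a cohort
#'
#' Orchestrates: band-wise quantile normalization, batch correction
#' (when >= 2 batches), TAD boundary calling on the cohort-average
#' matrix, common-deletion filtering, span/flank association with
#' covariates, permutation nulls with genomic inflation, TAD-boundary
#' classification with group-level Wilcoxon tests, and (optionally)
#' per-SV summary TSV / QQ table / run-manifest JSON outputs.
#'
#' @param cohort a raw-count [HiCCohort-class].
#' @param svs SV `GRanges` with dosages for the cohort samples.
#' @param covariates covariate matrix from [covariateSet()] or `NULL`.
#' @param binCov optional [binCovariates()] for per-bin bias removal;
#'   when absent that stage is skipped with a notice.
#' @param minCarriers common-deletion carrier threshold (default 3).
#' @param nFlank flank width in bins (default 6).
#' @param largeSize length threshold (bp) separating large deletions
#'   (default 10 kb, strict `>`).
#' @param nPerm permutations per SV for the null (default 100).
#' @param seed top-level integer seed; per-stage streams are derived
#'   from it and recorded in the manifest.
#' @param stat region statistic (`"mean"` or `"median"`).
#' @param orientation regression orientation (see [regressRegion()]).
#' @param tadWindowBins DI window (default 50 bins).
#' @param extraMask extra 0-based bins to mask at every locus.
#' @param outDir output directory, or `NULL` to skip writing files.
#' @return list with `results` (per-SV association table including TB
#'   class and SV length), `null` (permutation-null table), `lambda`
#'   (per region), `qq` (per region), `groupTests` (TB/NonTB Wilcoxon
#'   vs null), `boundaries`, `cohortNorm`, `manifest`.
#' @export
runPipeline <- function(cohort, svs, covariates = NULL, binCov = NULL,
                        minCarriers = 3L, nFlank = 6L, largeSize = 10000,
                        nPerm = 100L, seed = 1L, stat = "mean",
                        orientation = c("dosageOnStat", "standard"),
                        tadWindowBins = 50L, extraMask = integer(0),
                        outDir = NULL) {
    orientation <- match.arg(orientation)
    stage <- function(...) message("[svhic] ", ...)

    if (!is.null(binCov)) {
        stage("per-bin bias removal")
        cohort <- HiCCohort(lapply(sampleIds(cohort), function(s) {
            hicnormNormalize(cohort[[s]], binCov)
        }), sampleIds = sampleIds(cohort), batch = batches(cohort))
    } else {
        stage("no bin covariates supplied: bias-removal stage skipped")
    }

    stage("band-wise quantile normalization")
    cohort <- bandQuantileNormalize(cohort)
    if (length(unique(batches(cohort))) >= 2) {
        stage("band-wise batch correction")
        cohort <- batchCorrectBands(cohort)
    } else {
        stage("single batch: batch correction skipped")
    }

    stage("TAD boundary calling on cohort-average matrix")
    avg <- averageGroupMatrix(cohort, sampleIds(cohort))
    di <- directionalityIndex(avg, windowBins = tadWindowBins)
    hmm <- fitDIHMM(di, seed = seed)
    boundaries <- callBoundaries(hmm, binsize = binSize(cohort),
                                 chrom = chromName(cohort))

    stage("common-deletion filtering")
    dels <- filterCommonDeletions(svs, minCarriers = minCarriers)

    stage("span/flank association (", length(dels), " deletions)")
    res <- associateDeletions(cohort, dels, nFlank = nFlank,
                              covariates = covariates,
                              extraMask = extraMask, stat = stat,
                              orientation = orientation)

    stage("permutation null (", nPerm, " per SV)")
    sampleOrder <- sampleIds(cohort)
    tested <- unique(res$svId)
    null <- NULL
    lambda <- list()
    qq <- list()
    if (length(tested)) {
        dos <- svDosage(dels)[match(tested, S4Vectors::mcols(dels)$svId),
                              sampleOrder, drop = FALSE]
        nullByRegion <- lapply(c("span", "flank"), function(region) {
            valuesMat <- attr(res, paste0("values_", region))
            if (is.null(valuesMat) || !nrow(valuesMat)) {
                return(NULL)
            }
            nl <- permutationNull(
                valuesMat,
                dos[match(rownames(valuesMat), tested), , drop = FALSE],
                covariates, nPerm = nPerm,
                seed = as.integer(seed) + match(region,
                                                c("span", "flank")),
                orientation = orientation)
            nl$region <- region
            nl
        })
        null <- do.call(rbind, nullByRegion)
        for (region in c("span", "flank")) {
            pv <- res$p[res$region == region]
            if (length(pv)) {
                lambda[[region]] <- genomicInflation(pv)$lambda
                np <- null$p[null$region == region]
                if (length(np)) {
                    qq[[region]] <- qqPoints(pv, np)
                }
            }
        }
    }

    stage("TAD-boundary classification and group tests")
    if (nrow(res)) {
        tb <- vapply(res$svId, function(id) {
            classifyTadBoundary(
                dels[match(id, S4Vectors::mcols(dels)$svId)], boundaries)
        }, character(1))
        res$tbClass <- tb
        at <- match(res$svId, S4Vectors::mcols(dels)$svId)
        res$chrom <- as.character(GenomicRanges::seqnames(dels))[at]
        res$start <- GenomicRanges::start(dels)[at]
        res$end <- GenomicRanges::end(dels)[at]
        res$svLen <- GenomicRanges::width(dels)[at]
        res$large <- res$svLen > largeSize
        eq <- S4Vectors::mcols(dels)$eqtlGenes
        if (!is.null(eq)) {
            res$eqtlGenes <- vapply(eq[at], paste, character(1),
                                    collapse = ",")
        }
    }
    groupTests <- list()
    if (!is.null(null) && nrow(res)) {
        for (region in c("span", "flank")) {
            for (cls in c("TB", "NonTB")) {
                obs <- res$beta[res$region == region & res$large &
                                    res$tbClass == cls]
                ids <- res$svId[res$region == region & res$large &
                                    res$tbClass == cls]
                nb <- null$beta[null$region == region & null$sv %in% ids]
                if (length(obs) && length(nb)) {
                    groupTests[[paste(region, cls, sep = "_")]] <-
                        groupVsNullWilcoxon(obs, nb)
                }
            }
        }
    }

    manifest <- list(
        seed = as.integer(seed), nPerm = as.integer(nPerm),
        nFlank = as.integer(nFlank), minCarriers = as.integer(minCarriers),
        stat = stat, orientation = orientation,
        nSamples = nSamples(cohort), nBins = nBins(cohort),
        binsize = binSize(cohort),
        nDeletionsTested = length(tested),
        packageVersion = as.character(utils::packageVersion("svhic")))

    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) {
            dir.create(outDir, recursive = TRUE)
        }
        data.table::fwrite(res, file.path(outDir, "association.tsv"),
                           sep = "\t")
        if (!is.null(null)) {
            data.table::fwrite(null, file.path(outDir, "null.tsv"),
                               sep = "\t")
        }
        for (region in names(qq)) {
            data.table::fwrite(qq[[region]],
                               file.path(outDir,
                                         paste0("qq_", region, ".tsv")),
                               sep = "\t")
        }
        writeBoundariesBed(boundaries,
                           file.path(outDir, "boundaries.bed"))
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }

    list(results = res, null = null, lambda = lambda, qq = qq,
         groupTests = groupTests, boundaries = boundaries,
         cohortNorm = cohort, manifest = manifest)
}

#' Summarize an SV association table
#'
#' Cohort-level descriptive statistics of a per-deletion summary table:
#' row count, mean deletion length, counts of large (> `largeSize`)
#' deletions, of TAD-boundary deletions among them, and of eQTL-annotated
#' deletions with their mean length.
#'
#' @param tab data.frame or TSV path with one row per deletion and
#'   columns `svLen` (bp), optionally `tbClass` (`"TB"`/`"NonTB"`) and
#'   `eqtlGenes` (empty string for no annotation).
#' @param largeSize large-deletion threshold in bp (strict `>`).
#' @return list of summary counts and means.
#' @export
summarizeSvTable <- function(tab, largeSize = 10000) {
    if (is.character(tab)) {
        tab <- as.data.frame(data.table::fread(tab))
    }
    if (!("svLen" %in% names(tab))) {
        stop("table must contain an `svLen` column")
    }
    large <- tab$svLen > largeSize
    out <- list(
        nDeletions = nrow(tab),
        meanLength = mean(tab$svLen),
        nLarge = sum(large))
    if ("tbClass" %in% names(tab)) {
        out$nLargeTB <- sum(large & tab$tbClass == "TB")
    }
    if ("eqtlGenes" %in% names(tab)) {
        hasEqtl <- !is.na(tab$eqtlGenes) & nzchar(as.character(tab$eqtlGenes))
        out$nEqtl <- sum(hasEqtl)
        out$meanLengthEqtl <- if (any(hasEqtl)) {
            mean(tab$svLen[hasEqtl])
        } else NA_real_
    }
    out
}
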