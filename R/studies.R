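#' Null-calibration study of the association pipeline
#'
#' Simulates several independent effect-free cohorts (19 samples each,
#' default geometry), runs the full pipeline (normalization, batch
#' correction, TAD calling, association with two ancestry PCs and sex,
#' permutation null) on each, and pools the p-values. A calibrated
#' pipeline yields genomic inflation near 1 for both regions and
#' uniform permutation-null p-values.
#'
#' Many small cohorts are used rather than one large one because
#' association p-values share the cohort's sample-level quirks
#' (sequencing depth draws, covariate configurations), which pooling
#' across independent cohorts averages out.
#'
#' @param nCohorts number of independent cohorts.
#' @param lociPerCohort effect-free deletion loci per cohort.
#' @param nBinsTotal chromosome size per cohort (bins).
#' @param nSamples samples per cohort (default 19).
#' @param nPerm permutations per locus for the pooled null.
#' @param seed integer seed.
#' @return list with `lambdaSpan`, `lambdaFlank`, `ksNull` (KS distance
#'   of pooled null p-values from uniform), `nReplicates`, `nNull`.
#' @export
calibrationStudy <- function(nCohorts = 18L, lociPerCohort = 90L,
                             nBinsTotal = 250L, nSamples = 19L,
                             nPerm = 2L, seed = 1L) {
    spanP <- flankP <- nullP <- numeric(0)
    nTested <- 0L
    for (k in seq_len(nCohorts)) {
        cseed <- .deriveSeed(seed, 613, k)
        set.seed(cseed)
        svs <- lapply(seq_len(lociPerCohort), function(j) {
            svSpec("DEL",
                   startBin = sample(10:(nBinsTotal - 14), 1),
                   lengthBins = sample(1:3, 1),
                   freq = runif(1, 0.3, 0.6), mode = "none",
                   id = sprintf("null_%02d_%03d", k, j))
        })
        bd <- as.integer(round(nBinsTotal * c(0.25, 0.5, 0.75)))
        cfg <- simConfig(nSamples = nSamples, nBinsTotal = nBinsTotal,
                         tadBoundaryBins = bd, svs = svs)
        sim <- simulateDataset(cfg, seed = cseed)
        pcs <- ancestryPCs(sim$snpGenotypes, 2)
        cov <- covariateSet(pcs = pcs$scores, sex = sim$samples$sex)
        res <- suppressMessages(
            runPipeline(sim$cohort, sim$svs, covariates = cov,
                        nPerm = nPerm, seed = cseed))
        spanP <- c(spanP, res$results$p[res$results$region == "span"])
        flankP <- c(flankP, res$results$p[res$results$region == "flank"])
        nullP <- c(nullP, res$null$p)
        nTested <- nTested + length(unique(res$results$svId))
    }
    ks <- suppressWarnings(ks.test(nullP, "punif"))
    list(lambdaSpan = genomicInflation(spanP)$lambda,
         lambdaFlank = genomicInflation(flankP)$lambda,
         ksNull = unname(ks$statistic),
         nReplicates = nTested, nNull = length(nullP))
}

#' Power study for direct deletion effects on spanning contacts
#'
#' Simulates cohorts each carrying one direct-mode deletion (spanning
#' contacts gain with dosage as flanking sequence is drawn together) and
#' measures how often the span association is detected with a positive
#' coefficient at the 0.05 level, and how often the flank association
#' rejects (which should stay at the nominal rate: the direct effect
#' does not touch same-side contacts).
#'
#' @param nSeeds number of simulated cohorts.
#' @param effectSize direct-mode effect scale (fraction of the deleted
#'   length removed from spanning-pair distances at homozygous dosage).
#' @param nBinsTotal chromosome size (bins). The default of 200 keeps a
#'   single locus from dominating its distance bands: on very short
#'   chromosomes band-wise quantile normalization redistributes a
#'   localized true gain across the band's other entries, which real
#'   chromosomes (thousands of bins per band) do not suffer from.
#' @param nSamples samples per cohort.
#' @param seed integer seed.
#' @return list with `powerSpan`, `flankRejectionRate`, `meanSpanBeta`,
#'   `standardizedEffect` (mean span-stat shift per dosage copy in
#'   residual-sd units), `nSeeds`.
#' @export
powerStudy <- function(nSeeds = 50L, effectSize = 1, nBinsTotal = 200L,
                       nSamples = 19L, seed = 1L) {
    spanHit <- flankHit <- logical(0)
    spanBeta <- stdEff <- numeric(0)
    for (k in seq_len(nSeeds)) {
        cseed <- .deriveSeed(seed, 331, k)
        cfg <- simConfig(nSamples = nSamples, nBinsTotal = nBinsTotal,
                         tadBoundaryBins = as.integer(nBinsTotal / 2),
                         svs = list(svSpec("DEL",
                                           startBin = as.integer(
                                               nBinsTotal / 4),
                                           lengthBins = 3L, freq = 0.4,
                                           mode = "direct",
                                           effectSize = effectSize,
                                           id = "del")))
        sim <- simulateDataset(cfg, seed = cseed)
        pcs <- ancestryPCs(sim$snpGenotypes, 2)
        cov <- covariateSet(pcs = pcs$scores, sex = sim$samples$sex)
        norm <- batchCorrectBands(bandQuantileNormalize(sim$cohort))
        res <- associateDeletions(norm, sim$svs, covariates = cov)
        sp <- res[res$region == "span", ]
        fl <- res[res$region == "flank", ]
        if (nrow(sp)) {
            spanHit <- c(spanHit, sp$p < 0.05 & sp$beta > 0)
            spanBeta <- c(spanBeta, sp$beta)
            vs <- attr(res, "values_span")["del", ]
            dos <- svDosage(sim$svs)["del", ]
            f <- lm(vs ~ dos)
            stdEff <- c(stdEff,
                        unname(coef(f)["dos"]) / sd(residuals(f)))
        }
        if (nrow(fl)) {
            flankHit <- c(flankHit, fl$p < 0.05)
        }
    }
    list(powerSpan = mean(spanHit),
         flankRejectionRate = mean(flankHit),
         meanSpanBeta = mean(spanBeta),
         standardizedEffect = mean(stdEff),
         nSeeds = as.integer(nSeeds))
}

#' Aggregated coefficient wedge for boundary (fusion) deletions
#'
#' Simulates cohorts carrying a fusion-mode deletion on a TAD boundary,
#' builds the per-bin coefficient map around the deletion for each, and
#' aggregates them by the cellwise median. With insulation loss the
#' inter-TAD block (pairs straddling the deletion) shows a positive
#' median coefficient wedge.
#'
#' @param nSeeds number of simulated cohorts.
#' @param windowBins coefficient-map margin (default 6).
#' @param nBinsTotal chromosome size (bins).
#' @param seed integer seed.
#' @return list with `medianSpanCellBeta` (median aggregated coefficient
#'   over inter-TAD cells), `medianSameSideBeta`, `map` (the aggregated
#'   [CoefficientMap-class]), `nSeeds`.
#' @export
fusionWedgeStudy <- function(nSeeds = 8L, windowBins = 6L,
                             nBinsTotal = 120L, seed = 1L) {
    maps <- list()
    for (k in seq_len(nSeeds)) {
        cseed <- .deriveSeed(seed, 499, k)
        half <- as.integer(nBinsTotal / 2)
        cfg <- simConfig(nSamples = 19L, nBinsTotal = nBinsTotal,
                         tadBoundaryBins = half,
                         svs = list(svSpec("DEL", startBin = half - 1L,
                                           lengthBins = 2L, freq = 0.4,
                                           mode = "fusion",
                                           id = "fus")))
        sim <- simulateDataset(cfg, seed = cseed)
        pcs <- ancestryPCs(sim$snpGenotypes, 2)
        cov <- covariateSet(pcs = pcs$scores, sex = sim$samples$sex)
        norm <- batchCorrectBands(bandQuantileNormalize(sim$cohort))
        maps[[k]] <- perBinCoefficients(norm, sim$svs["fus"],
                                        windowBins = windowBins,
                                        covariates = cov,
                                        orientation = "standard")
    }
    agg <- aggregateCoefficientMaps(maps, "median")
    b <- coefficientGrid(agg)
    spanCells <- outer(agg@offsets < 0, agg@offsets > 0) |
        outer(agg@offsets > 0, agg@offsets < 0)
    sameSide <- outer(agg@offsets < 0, agg@offsets < 0) |
        outer(agg@offsets > 0, agg@offsets > 0)
    list(medianSpanCellBeta = median(b[spanCells & agg@valid],
                                     na.rm = TRUE),
         medianSameSideBeta = median(b[sameSide & agg@valid],
                                     na.rm = TRUE),
         map = agg, nSeeds = as.integer(nSeeds))
}

#' Breakpoint concentration of inversion genotype correlations
#'
#' Simulates cohorts carrying a polymorphic inversion, computes the
#' per-pair Pearson correlation of contacts with inversion dosage over
#' the standard analysis window, and measures how strongly the top
#' decile of |r| concentrates on breakpoint-spanning pairs (one bin
#' inside the inversion, one outside), as a fold enrichment over the
#' window-wide fraction of such pairs.
#'
#' @param nSeeds number of simulated cohorts.
#' @param nSamples genotyped samples (default 9).
#' @param invLengthBins inversion length in bins (default 30).
#' @param sideBins window margin (default 62).
#' @param nBinsTotal chromosome size (bins).
#' @param seed integer seed.
#' @return list with `enrichment` (mean fold enrichment across seeds),
#'   `perSeed`, `spanningFraction`, `nSeeds`.
#' @export
inversionEnrichmentStudy <- function(nSeeds = 5L, nSamples = 9L,
                                     invLengthBins = 30L, sideBins = 62L,
                                     nBinsTotal = 200L, seed = 1L) {
    per <- numeric(0)
    fracs <- numeric(0)
    for (k in seq_len(nSeeds)) {
        cseed <- .deriveSeed(seed, 953, k)
        startBin <- as.integer(nBinsTotal * 0.3)
        cfg <- simConfig(nSamples = nSamples, nBinsTotal = nBinsTotal,
                         tadBoundaryBins = as.integer(
                             round(nBinsTotal * c(0.25, 0.5, 0.75))),
                         svs = list(svSpec("INV", startBin = startBin,
                                           lengthBins = invLengthBins,
                                           freq = 0.5, mode = "none",
                                           id = "inv")))
        sim <- simulateDataset(cfg, seed = cseed)
        norm <- bandQuantileNormalize(sim$cohort)
        inv <- sim$svs["inv"]
        cm <- genotypeCorrelationMap(
            norm, inv, inversionWindow(inv, binSize(norm), sideBins,
                                       nBins(norm)))
        inside <- cm$bins >= cm$breakpointBins[1] &
            cm$bins <= cm$breakpointBins[2]
        ut <- which(upper.tri(cm$r, diag = TRUE) & !is.na(cm$r),
                    arr.ind = TRUE)
        spanning <- xor(inside[ut[, 1]], inside[ut[, 2]])
        rv <- abs(cm$r[ut])
        top <- rv >= quantile(rv, 0.9)
        per <- c(per, mean(spanning[top]) / mean(spanning))
        fracs <- c(fracs, mean(spanning))
    }
    list(enrichment = mean(per), perSeed = per,
         spanningFraction = mean(fracs), nSeeds = as.integer(nSeeds))
}

#' TAD-boundary recovery study
#'
#' Simulates small cohorts with known TAD boundaries, calls boundaries
#' with the directionality-index HMM on the cohort-average matrix, and
#' reports the fraction of true boundaries recovered within one bin of
#' a called boundary midpoint.
#'
#' @param nSeeds number of simulated cohorts.
#' @param nBinsTotal chromosome size (bins).
#' @param nSamples samples per cohort (small: boundary calling uses the
#'   cohort average).
#' @param windowBins DI window in bins.
#' @param seed integer seed.
#' @return list with `recovery` (fraction of true boundaries recovered),
#'   `meanCalled` (mean called boundary count), `nSeeds`.
#' @export
boundaryRecoveryStudy <- function(nSeeds = 20L, nBinsTotal = 100L,
                                  nSamples = 3L, windowBins = 10L,
                                  seed = 1L) {
    hits <- 0L
    total <- 0L
    called <- integer(0)
    truthBd <- as.integer(round(nBinsTotal * c(0.25, 0.5, 0.75)))
    for (k in seq_len(nSeeds)) {
        cseed <- .deriveSeed(seed, 761, k)
        cfg <- simConfig(nSamples = nSamples, nBinsTotal = nBinsTotal,
                         tadBoundaryBins = truthBd, svs = list(),
                         nBatches = 1L)
        sim <- simulateDataset(cfg, seed = cseed)
        avg <- averageGroupMatrix(sim$cohort, sampleIds(sim$cohort))
        di <- directionalityIndex(avg, windowBins = windowBins)
        fit <- fitDIHMM(di, seed = cseed)
        bs <- callBoundaries(fit, binsize = binSize(avg))
        mids <- rowMeans(bs$boundaryBins)
        called <- c(called, nrow(bs$boundaryBins))
        for (b in truthBd) {
            total <- total + 1L
            if (length(mids) && any(abs(mids - (b + 0.5)) <= 1)) {
                hits <- hits + 1L
            }
        }
    }
    list(recovery = hits / total, meanCalled = mean(called),
         nSeeds = as.integer(nSeeds))
}
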