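#' Specification of one simulated structural variant
#'
#' @param type `"DEL"` or `"INV"`.
#' @param startBin first 0-based bin the SV covers.
#' @param lengthBins SV length in bins.
#' @param freq alternate-allele frequency, strictly inside (0, 1).
#' @param mode effect mode: `"direct"` (breakpoint-spanning contact gain
#'   plus loss of deleted bins), `"fusion"` (insulation loss across a
#'   deleted TAD boundary), or `"none"`. Ignored for inversions, whose
#'   effect is the coordinate rearrangement itself.
#' @param effectSize effect scale in `[0, 1]`-ish units: for `"direct"`,
#'   the fraction of the deleted length removed from the effective
#'   genomic distance of spanning pairs at homozygous dosage; for
#'   `"fusion"`, the fraction of full TAD-level insulation loss at
#'   homozygous dosage.
#' @param id SV identifier.
#' @return an `svSpec` list.
#' @export
svSpec <- function(type = c("DEL", "INV"), startBin, lengthBins, freq,
                   mode = c("direct", "fusion", "none"), effectSize = 1,
                   id = NULL) {
    type <- match.arg(type)
    mode <- match.arg(mode)
    if (freq <= 0 || freq >= 1) {
        stop("allele frequency must lie strictly in (0, 1)")
    }
    if (lengthBins < 1) {
        stop("lengthBins must be >= 1")
    }
    structure(list(type = type, startBin = as.integer(startBin),
                   lengthBins = as.integer(lengthBins), freq = freq,
                   mode = mode, effectSize = effectSize,
                   id = if (is.null(id)) {
                       paste0("sim_", type, "_", startBin)
                   } else id),
              class = "svSpec")
}

#' Configuration of a synthetic Hi-C cohort
#'
#' The generative model: expected contacts decay with genomic distance as
#' `depth * max(|i - j|, 1)^(-alpha)`, multiplied by `betaTad` when both
#' bins share a TAD; SV carriers modify the expectation according to each
#' variant's mode (see [expectedContacts()]); counts are drawn per pair
#' from a Poisson or negative binomial around the expectation; samples in
#' later batches are scaled by a multiplicative batch factor.
#'
#' @param nSamples cohort size (default 19).
#' @param nBinsTotal chromosome length in bins (default 400).
#' @param binsize bin width in bp (default 40 kb).
#' @param alpha distance-decay exponent (default 1).
#' @param tadBoundaryBins 0-based bins at which TADs start (internal
#'   boundaries; default 100/200/300, i.e. four equal TADs).
#' @param betaTad intra-TAD contact enrichment factor (default 3).
#' @param depth sequencing-depth scale; default `100 / betaTad` so the
#'   main-diagonal band averages ~100 counts.
#' @param noise `"poisson"` or `"nb"` (negative binomial).
#' @param dispersion NB size parameter (larger = closer to Poisson).
#' @param nBatches number of processing batches (round-robin assignment).
#' @param batchFactor multiplicative scale applied to batch 2, 3, ...
#'   relative to batch 1 (default 1.25, a modest processing-date effect).
#' @param svs list of [svSpec()] variants. Defaults to the demo design:
#'   one 3-bin mid-TAD deletion (direct mode), one 2-bin deletion on a
#'   TAD boundary (fusion mode), one 30-bin inversion.
#' @param nSnps number of background SNPs used to derive ancestry PCs.
#' @param popDelta mean allele-frequency separation between the two
#'   simulated ancestral populations.
#' @param chrom chromosome name.
#' @return a `SimulationConfig` list.
#' @export
simConfig <- function(nSamples = 19L, nBinsTotal = 400L, binsize = 40000L,
                      alpha = 1, tadBoundaryBins = c(100L, 200L, 300L),
                      betaTad = 3, depth = NULL,
                      noise = c("poisson", "nb"), dispersion = 10,
                      nBatches = 2L, batchFactor = 1.25,
                      svs = NULL, nSnps = 200L, popDelta = 0.3,
                      chrom = "chr1") {
    noise <- match.arg(noise)
    if (is.null(depth)) {
        depth <- 100 / betaTad
    }
    if (is.unsorted(tadBoundaryBins, strictly = TRUE)) {
        stop("tadBoundaryBins must be strictly increasing")
    }
    if (betaTad < 1 || alpha <= 0 || depth <= 0 || batchFactor <= 0) {
        stop("alpha, depth and batchFactor must be positive; betaTad >= 1")
    }
    if (is.null(svs)) {
        # demo design scaled to the geometry: a mid-TAD direct deletion,
        # a boundary-straddling fusion deletion, and a large inversion
        nb <- as.integer(nBinsTotal)
        bd <- as.integer(tadBoundaryBins)
        delStart <- if (length(bd) >= 2) {
            as.integer(floor((bd[1] + bd[2]) / 2)) - 1L
        } else {
            as.integer(floor(nb / 3))
        }
        fuseBd <- bd[ceiling(length(bd) / 2)]
        invLen <- min(30L, as.integer(floor(nb / 8)))
        invStart <- min(nb - invLen - 5L, as.integer(floor(nb * 0.8)))
        svs <- list(
            svSpec("DEL", startBin = delStart, lengthBins = 3L,
                   freq = 0.4, mode = "direct", id = "demo_del_direct"),
            svSpec("DEL", startBin = fuseBd - 1L, lengthBins = 2L,
                   freq = 0.4, mode = "fusion", id = "demo_del_fusion"),
            svSpec("INV", startBin = invStart, lengthBins = invLen,
                   freq = 0.4, mode = "none", id = "demo_inv"))
    }
    bad <- vapply(svs, function(sv) {
        sv$startBin < 0 || sv$startBin + sv$lengthBins > nBinsTotal
    }, logical(1))
    if (any(bad)) {
        stop("SV(s) outside the chromosome: ",
             paste(vapply(svs[bad], `[[`, character(1), "id"),
                   collapse = ", "))
    }
    structure(list(
        nSamples = as.integer(nSamples),
        nBinsTotal = as.integer(nBinsTotal),
        binsize = as.integer(binsize), alpha = alpha,
        tadBoundaryBins = as.integer(tadBoundaryBins), betaTad = betaTad,
        depth = depth, noise = noise, dispersion = dispersion,
        nBatches = as.integer(nBatches), batchFactor = batchFactor,
        svs = svs, nSnps = as.integer(nSnps), popDelta = popDelta,
        chrom = chrom),
        class = "SimulationConfig")
}

# derive a valid 32-bit seed from a user seed and a stream index
.deriveSeed <- function(seed, mult, k) {
    as.integer((as.numeric(seed) * mult + k) %% 2147483647)
}

# 0-based TAD id per bin
.tadId <- function(config) {
    findInterval(seq_len(config$nBinsTotal) - 1L, config$tadBoundaryBins)
}

#' Draw cohort genotypes, metadata and ground truth
#'
#' SV genotypes are Hardy-Weinberg draws (`Binomial(2, freq)` per
#' sample), sex is Bernoulli(0.5), samples are split between two
#' ancestral populations whose background SNP frequencies differ by
#' `popDelta` on average, and batches are assigned round-robin.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return list with `samples` (data.frame: `sampleId`, `sex`, `batch`,
#'   `population`), `svs` (SV `GRanges` with dosage matrix),
#'   `snpGenotypes` (samples x SNPs), and `truth` (dosages, true boundary
#'   bins, per-SV mode/effect, batch labels).
#' @export
simulateCohort <- function(config, seed = 1L) {
    set.seed(as.integer(seed))
    n <- config$nSamples
    ids <- sprintf("S%02d", seq_len(n))
    sex <- rbinom(n, 1, 0.5)
    pop <- rbinom(n, 1, 0.5)
    batch <- paste0("batch", (seq_len(n) - 1L) %% config$nBatches + 1L)
    # background SNPs for ancestry PCs: two populations with shifted
    # allele frequencies
    f0 <- runif(config$nSnps, 0.1, 0.9)
    shift <- ifelse(runif(config$nSnps) < 0.5, 1, -1) * config$popDelta / 2
    f1 <- pmin(0.95, pmax(0.05, f0 + shift))
    f2 <- pmin(0.95, pmax(0.05, f0 - shift))
    snp <- t(vapply(seq_len(n), function(s) {
        f <- if (pop[s] == 1) f1 else f2
        rbinom(config$nSnps, 2, f)
    }, integer(config$nSnps)))
    rownames(snp) <- ids
    dosage <- if (length(config$svs)) {
        matrix(t(vapply(config$svs, function(sv) {
            rbinom(n, 2, sv$freq)
        }, integer(n))), nrow = length(config$svs))
    } else {
        matrix(integer(0), 0, n)
    }
    dimnames(dosage) <- list(vapply(config$svs, `[[`, character(1), "id"),
                             ids)
    svGr <- .svSpecToGRanges(config)
    S4Vectors::mcols(svGr)$dosage <- dosage
    samples <- data.frame(sampleId = ids, sex = sex, batch = batch,
                          population = pop, stringsAsFactors = FALSE)
    truth <- list(
        dosage = dosage,
        boundaryBins = config$tadBoundaryBins,
        svModes = vapply(config$svs, `[[`, character(1), "mode"),
        svEffects = vapply(config$svs, `[[`, numeric(1), "effectSize"),
        svIds = vapply(config$svs, `[[`, character(1), "id"),
        batch = batch, seed = as.integer(seed))
    list(samples = samples, svs = svGr, snpGenotypes = snp, truth = truth)
}

.svSpecToGRanges <- function(config) {
    bs <- config$binsize
    if (!length(config$svs)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$svId <- character(0)
        S4Vectors::mcols(gr)$svtype <- character(0)
        S4Vectors::mcols(gr)$svLen <- integer(0)
        return(gr)
    }
    starts <- vapply(config$svs, function(sv) {
        sv$startBin * bs + 1L  # 1-based inclusive
    }, numeric(1))
    ends <- vapply(config$svs, function(sv) {
        (sv$startBin + sv$lengthBins) * bs
    }, numeric(1))
    gr <- GenomicRanges::GRanges(
        config$chrom, IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr)$svId <- vapply(config$svs, `[[`, character(1),
                                        "id")
    S4Vectors::mcols(gr)$svtype <- vapply(config$svs, `[[`, character(1),
                                          "type")
    S4Vectors::mcols(gr)$svLen <- GenomicRanges::width(gr)
    names(gr) <- S4Vectors::mcols(gr)$svId
    gr
}

# expectation matrix for one sample given its SV dosages (named by sv id)
.expectedMatrix <- function(config, dosages = NULL) {
    nb <- config$nBinsTotal
    idx <- seq_len(nb) - 1L
    D <- abs(outer(idx, idx, `-`))
    tad <- .tadId(config)
    sameTad <- outer(tad, tad, `==`)
    base <- function(Dmat, tadFac) {
        config$depth * pmax(Dmat, 1)^(-config$alpha) * tadFac
    }
    tadFac <- ifelse(sameTad, config$betaTad, 1)
    Deff <- D
    for (sv in config$svs) {
        d <- if (is.null(dosages)) 0 else dosages[[sv$id]]
        if (is.null(d) || is.na(d) || d == 0) next
        bins <- sv$startBin + seq_len(sv$lengthBins) - 1L
        if (sv$type == "DEL" && sv$mode == "direct") {
            # spanning pairs sit closer on the deleted haplotype
            left <- idx < min(bins)
            right <- idx > max(bins)
            spanning <- outer(left, right, `&`) | outer(right, left, `&`)
            shrink <- sv$effectSize * (d / 2) * sv$lengthBins
            Deff[spanning] <- pmax(D[spanning] - shrink, 1)
        }
        if (sv$type == "DEL" && sv$mode == "fusion") {
            # insulation loss between the TADs flanking the deleted
            # boundary; if the deletion does not straddle one, the
            # nearest boundary is taken
            lTad <- tad[min(bins) + 1L]
            rTad <- tad[max(bins) + 1L]
            fusedLeft <- if (rTad > lTad) {
                seq(lTad, rTad - 1L)
            } else {
                nearest <- config$tadBoundaryBins[
                    which.min(abs(config$tadBoundaryBins -
                                      mean(bins)))]
                tad[nearest]  # TAD left of the nearest boundary
            }
            fuse <- 1 + (config$betaTad - 1) *
                min(1, (d / 2) * sv$effectSize)
            for (t in fusedLeft) {
                cross <- outer(tad == t, tad == t + 1L, `&`)
                cross <- cross | t(cross)
                tadFac[cross & !sameTad] <- fuse
            }
        }
    }
    mu <- base(Deff, tadFac)
    # directly deleted bins lose coverage in proportion to dosage
    for (sv in config$svs) {
        d <- if (is.null(dosages)) 0 else dosages[[sv$id]]
        if (is.null(d) || is.na(d) || d == 0 || sv$type != "DEL") next
        if (sv$mode != "direct") next
        bins <- sv$startBin + seq_len(sv$lengthBins) - 1L + 1L
        fac <- 1 - d / 2
        mu[bins, ] <- mu[bins, ] * fac
        mu[, bins] <- mu[, bins] * fac
    }
    # inversions: blend reference-orientation and inverted-orientation
    # expectations by dosage
    for (sv in config$svs) {
        d <- if (is.null(dosages)) 0 else dosages[[sv$id]]
        if (is.null(d) || is.na(d) || d == 0 || sv$type != "INV") next
        bins <- sv$startBin + seq_len(sv$lengthBins) - 1L + 1L
        perm <- seq_len(nb)
        perm[bins] <- rev(bins)
        mu <- (1 - d / 2) * mu + (d / 2) * mu[perm, perm]
    }
    mu
}

#' Expected contact intensity under the generative model
#'
#' @param config a [simConfig()].
#' @param i,j 0-based bin indices.
#' @param dosages named list/vector of SV dosages for the sample
#'   (default: all zero).
#' @return expected contact value(s) at `(i, j)`.
#' @export
expectedContacts <- function(config, i, j, dosages = NULL) {
    mu <- .expectedMatrix(config, dosages)
    mu[cbind(i + 1L, j + 1L)]
}

#' Simulate one sample's contact matrix
#'
#' Counts are drawn per upper-triangle pair from the configured noise
#' model around the sample's expectation matrix (after the batch factor)
#' and mirrored to keep the matrix symmetric.
#'
#' @param sampleIdx sample index in the cohort.
#' @param config a [simConfig()].
#' @param cohort output of [simulateCohort()].
#' @param seed integer seed (a per-sample stream is derived from it).
#' @return a [ContactMatrix-class] of counts.
#' @export
simulateContactMatrix <- function(sampleIdx, config, cohort, seed = 1L) {
    set.seed(.deriveSeed(seed, 7919, sampleIdx))
    dos <- cohort$truth$dosage[, sampleIdx]
    names(dos) <- cohort$truth$svIds
    mu <- .expectedMatrix(config, as.list(dos))
    batchIdx <- as.integer(sub("batch", "", cohort$samples$batch[sampleIdx]))
    if (batchIdx > 1) {
        mu <- mu * config$batchFactor
    }
    nb <- config$nBinsTotal
    ut <- upper.tri(mu, diag = TRUE)
    lam <- mu[ut]
    cnt <- if (config$noise == "poisson") {
        rpois(length(lam), lam)
    } else {
        rnbinom(length(lam), mu = lam, size = config$dispersion)
    }
    v <- matrix(0, nb, nb)
    v[ut] <- cnt
    v <- v + t(v) - diag(diag(v))
    ContactMatrix(v, chrom = config$chrom, binsize = config$binsize,
                  sampleId = cohort$samples$sampleId[sampleIdx])
}

#' Simulate a full dataset, optionally writing it to disk
#'
#' Generates the cohort genotypes and per-sample contact matrices and,
#' when `dir` is given, writes triplet TSV matrices, an SV VCF, a sample
#' metadata TSV and a ground-truth JSON that round-trip through the
#' package readers.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @param dir output directory or `NULL` (no files written).
#' @return list with `cohort` ([HiCCohort-class]), `svs` (GRanges),
#'   `samples`, `snpGenotypes`, `truth`, and `paths` (when written).
#' @export
simulateDataset <- function(config, seed = 1L, dir = NULL) {
    ch <- simulateCohort(config, seed = seed)
    mats <- lapply(seq_len(config$nSamples), function(s) {
        simulateContactMatrix(s, config, ch, seed = seed)
    })
    cohort <- HiCCohort(mats, sampleIds = ch$samples$sampleId,
                        batch = ch$samples$batch)
    paths <- NULL
    if (!is.null(dir)) {
        if (!dir.exists(dir)) {
            dir.create(dir, recursive = TRUE)
        }
        matPaths <- vapply(seq_len(config$nSamples), function(s) {
            p <- file.path(dir, paste0(ch$samples$sampleId[s],
                                       "_", config$chrom, ".triplet.tsv"))
            writeContactTriplets(mats[[s]], p)
            p
        }, character(1))
        vcfPath <- file.path(dir, "svs.vcf")
        .writeSvVcf(ch$svs, ch$samples$sampleId, vcfPath)
        metaPath <- file.path(dir, "samples.tsv")
        data.table::fwrite(ch$samples, metaPath, sep = "\t")
        truthPath <- file.path(dir, "truth.json")
        jsonlite::write_json(list(
            seed = ch$truth$seed,
            boundaryBins = ch$truth$boundaryBins,
            svIds = ch$truth$svIds, svModes = ch$truth$svModes,
            svEffects = ch$truth$svEffects,
            dosage = ch$truth$dosage, batch = ch$truth$batch),
            truthPath, auto_unbox = TRUE, digits = NA)
        paths <- list(matrices = matPaths, vcf = vcfPath,
                      samples = metaPath, truth = truthPath)
    }
    list(cohort = cohort, svs = ch$svs, samples = ch$samples,
         snpGenotypes = ch$snpGenotypes, truth = ch$truth, paths = paths)
}

# minimal VCF 4.2 writer for simulated symbolic SV records
.writeSvVcf <- function(svs, samples, path) {
    dos <- svDosage(svs)[, samples, drop = FALSE]
    gtOf <- function(d) {
        if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1]
    }
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
        "##ALT=<ID=DEL,Description=\"Deletion\">",
        "##ALT=<ID=INV,Description=\"Inversion\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    rows <- vapply(seq_along(svs), function(k) {
        gt <- vapply(dos[k, ], gtOf, character(1))
        paste(c(as.character(GenomicRanges::seqnames(svs)[k]),
                GenomicRanges::start(svs)[k],
                S4Vectors::mcols(svs)$svId[k], "N",
                paste0("<", S4Vectors::mcols(svs)$svtype[k], ">"),
                ".", "PASS",
                paste0("SVTYPE=", S4Vectors::mcols(svs)$svtype[k],
                       ";END=", GenomicRanges::end(svs)[k],
                       ";SVLEN=", GenomicRanges::width(svs)[k]),
                "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, rows), path)
    invisible(path)
}
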