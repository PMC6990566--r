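#' Read structural-variant genotypes from a VCF
#'
#' Records are returned as a [GenomicRanges::GRanges] (1-based inclusive,
#' VCF convention) with metadata columns `svId`, `svtype`, `svLen` and a
#' `dosage` matrix (samples in columns): dosage is the count of alternate
#' alleles in the GT field (0/1/2), `NA` for `./.`.
#'
#' @param path VCF file.
#' @param samples ordered sample ids to extract; default all VCF samples.
#' @param svtypes SV types to keep (from the `SVTYPE` INFO field).
#' @return a `GRanges` of SV records.
#' @export
readSVGenotypes <- function(path, samples = NULL,
                            svtypes = c("DEL", "INV")) {
    vcf <- VariantAnnotation::readVcf(path)
    have <- colnames(vcf)
    if (is.null(samples)) {
        samples <- have
    }
    missing <- setdiff(samples, have)
    if (length(missing)) {
        stop("sample(s) absent from VCF header: ",
             paste(missing, collapse = ", "))
    }
    info <- VariantAnnotation::info(vcf)
    svtype <- as.character(info$SVTYPE)
    keep <- svtype %in% svtypes
    gr <- SummarizedExperiment::rowRanges(vcf)[keep]
    svtype <- svtype[keep]
    end <- GenomicRanges::end(gr)
    if ("END" %in% colnames(info)) {
        e <- info$END[keep]
        e <- suppressWarnings(as.numeric(unlist(lapply(e, function(z) {
            if (length(z)) z[1] else NA
        }))))
        end <- ifelse(is.na(e), end, e)
    }
    gt <- VariantAnnotation::geno(vcf)$GT[keep, samples, drop = FALSE]
    dosage <- apply(gt, c(1, 2), .gtDosage)
    dosage <- matrix(dosage, nrow = sum(keep),
                     dimnames = list(names(gr), samples))
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr),
        IRanges::IRanges(GenomicRanges::start(gr), end))
    S4Vectors::mcols(out)$svId <- names(gr)
    S4Vectors::mcols(out)$svtype <- svtype
    S4Vectors::mcols(out)$svLen <- GenomicRanges::width(out)
    S4Vectors::mcols(out)$dosage <- dosage
    names(out) <- names(gr)
    out
}

.gtDosage <- function(gt) {
    al <- strsplit(gt, "[/|]")[[1]]
    if (any(al == ".")) {
        return(NA_integer_)
    }
    sum(al != "0")
}

#' Dosage matrix of an SV GRanges
#' @param svs SV `GRanges` from [readSVGenotypes()] or [simulateCohort()].
#' @return integer matrix, SVs x samples.
#' @export
svDosage <- function(svs) {
    S4Vectors::mcols(svs)$dosage
}

#' Filter deletions to those common in the cohort
#'
#' Keeps deletions carried (dosage >= 1) by at least `minCarriers` samples
#' and, optionally, within a length window (`length = end - start + 1`).
#'
#' @param svs SV `GRanges`.
#' @param minCarriers minimum number of carrier samples (default 3, as for
#'   a 19-sample cohort at >= 3/19).
#' @param sizeMin,sizeMax optional inclusive length bounds in bp.
#' @return the filtered `GRanges`, order preserved.
#' @export
filterCommonDeletions <- function(svs, minCarriers = 3L, sizeMin = NULL,
                                  sizeMax = NULL) {
    dos <- svDosage(svs)
    if (minCarriers > ncol(dos)) {
        warning("minCarriers (", minCarriers, ") exceeds sample count (",
                ncol(dos), "): no deletion can qualify")
    }
    carriers <- rowSums(dos >= 1, na.rm = TRUE)
    keep <- S4Vectors::mcols(svs)$svtype == "DEL" & carriers >= minCarriers
    len <- GenomicRanges::width(svs)
    if (!is.null(sizeMin)) {
        keep <- keep & len >= sizeMin
    }
    if (!is.null(sizeMax)) {
        keep <- keep & len <= sizeMax
    }
    svs[keep]
}

#' Map an SV to the 0-based bins it overlaps
#'
#' Bins are 0-based half-open of width `binsize`; an SV at 1-based
#' inclusive `[start, end]` covers bins
#' `floor((start - 1) / binsize) .. floor((end - 1) / binsize)`.
#'
#' @param sv a single-row SV `GRanges`.
#' @param binsize bin width in bp.
#' @return integer vector of 0-based bin indices.
#' @export
svToBins <- function(sv, binsize = 40000L) {
    stopifnot(length(sv) == 1)
    s <- GenomicRanges::start(sv)
    e <- GenomicRanges::end(sv)
    seq(floor((s - 1) / binsize), floor((e - 1) / binsize))
}

#' Span and flank region specification around a deletion
#'
#' Masks the bins the deletion overlaps (plus any extra mask, e.g.
#' segmental duplications), takes the `nFlank` nearest unmasked bins on
#' each side (skipping masked bins so masking does not shrink the flank),
#' and enumerates the bin pairs: the span set is all left x right pairs
#' (contacts crossing the deletion), the flank set all same-side pairs
#' excluding the diagonal (contacts that do not cross it).
#'
#' @param sv a single-row SV `GRanges`.
#' @param binsize bin width in bp.
#' @param nFlank flank width in bins (default 6, i.e. 240 kb at 40 kb).
#' @param extraMask additional 0-based bin indices to mask.
#' @param nBinsTotal number of bins on the chromosome (for truncation).
#' @return a `RegionSpec` list: `svId`, `maskedBins`, `leftFlank`,
#'   `rightFlank`, `spanPairs`, `flankPairs` (two-column 0-based bin
#'   matrices), `flankWidth`.
#' @export
defineRegions <- function(sv, binsize = 40000L, nFlank = 6L,
                          extraMask = integer(0), nBinsTotal = Inf) {
    if (nFlank < 1) {
        stop("nFlank must be >= 1")
    }
    svBins <- svToBins(sv, binsize)
    masked <- sort(unique(c(svBins, as.integer(extraMask))))
    pickSide <- function(from, step) {
        out <- integer(0)
        b <- from
        while (length(out) < nFlank && b >= 0 && b < nBinsTotal) {
            if (!(b %in% masked)) {
                out <- c(out, b)
            }
            b <- b + step
        }
        sort(out)
    }
    left <- pickSide(min(svBins) - 1L, -1L)
    right <- pickSide(max(svBins) + 1L, 1L)
    if (!length(left) && !length(right)) {
        stop("untestable locus: no unmasked flank bins on either side of ",
             if (!is.null(S4Vectors::mcols(sv)$svId)) {
                 S4Vectors::mcols(sv)$svId
             } else "SV")
    }
    spanPairs <- if (length(left) && length(right)) {
        as.matrix(expand.grid(i = left, j = right))
    } else {
        matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    }
    sidePairs <- function(b) {
        if (length(b) < 2) {
            return(matrix(integer(0), 0, 2))
        }
        t(combn(b, 2))
    }
    flankPairs <- rbind(sidePairs(left), sidePairs(right))
    colnames(flankPairs) <- c("i", "j")
    structure(list(
        svId = if (!is.null(S4Vectors::mcols(sv)$svId)) {
            S4Vectors::mcols(sv)$svId
        } else NA_character_,
        maskedBins = masked, leftFlank = left, rightFlank = right,
        spanPairs = spanPairs, flankPairs = flankPairs,
        flankWidth = as.integer(nFlank)),
        class = "RegionSpec")
}

#' @export
print.RegionSpec <- function(x, ...) {
    cat("RegionSpec:", x$svId, "\n",
        " masked bins:", length(x$maskedBins),
        " left flank:", paste(x$leftFlank, collapse = ","),
        " right flank:", paste(x$rightFlank, collapse = ","), "\n",
        " span pairs:", nrow(x$spanPairs),
        " flank pairs:", nrow(x$flankPairs), "\n")
    invisible(x)
}

#' Classify an SV as overlapping a TAD boundary or not
#'
#' `"TB"` if the SV and any boundary interval share at least 1 bp,
#' otherwise `"NonTB"`.
#'
#' @param sv a single-row SV `GRanges`.
#' @param boundaries a `TADBoundarySet` from [callBoundaries()] or a
#'   `GRanges` of boundary intervals.
#' @return `"TB"` or `"NonTB"`.
#' @export
classifyTadBoundary <- function(sv, boundaries) {
    gr <- if (inherits(boundaries, "TADBoundarySet")) {
        boundaries$boundaries
    } else {
        boundaries
    }
    if (!length(gr)) {
        return("NonTB")
    }
    hits <- GenomicRanges::countOverlaps(sv, gr, minoverlap = 1L,
                                         ignore.strand = TRUE)
    if (hits > 0) "TB" else "NonTB"
}

#' Summary statistic of contacts over a span or flank region
#'
#' @param m a [ContactMatrix-class].
#' @param spec a `RegionSpec` from [defineRegions()].
#' @param which `"span"` or `"flank"`.
#' @param stat `"mean"` (default, main analysis) or `"median"`.
#' @return the statistic over non-missing pair values, or `NA` if every
#'   pair touches a missing bin.
#' @export
regionStat <- function(m, spec, which = c("span", "flank"),
                       stat = c("mean", "median")) {
    which <- match.arg(which)
    stat <- match.arg(stat)
    pairs <- if (which == "span") spec$spanPairs else spec$flankPairs
    if (!nrow(pairs)) {
        stop("empty ", which, " pair set for ", spec$svId)
    }
    nb <- nBins(m)
    if (any(pairs >= nb) || any(pairs < 0)) {
        stop("region bins outside matrix bounds")
    }
    v <- contactValues(m, na = TRUE)
    vals <- v[cbind(pairs[, 1] + 1L, pairs[, 2] + 1L)]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
        return(NA_real_)
    }
    if (stat == "mean") mean(vals) else median(vals)
}

#' Annotate SVs with SV-eQTL records
#'
#' Matches by SV id (column `sv_id`) or, failing that, by exact coordinate
#' identity (columns `chrom`, `start`, `end`). All matching eQTL genes are
#' retained; unmatched SVs get an empty annotation.
#'
#' @param svs SV `GRanges`.
#' @param eqtlTable data.frame or TSV path with columns `sv_id` and/or
#'   `chrom`, `start`, `end`, plus `gene`.
#' @return `svs` with an added `eqtlGenes` [IRanges::CharacterList] column.
#' @export
annotateEqtl <- function(svs, eqtlTable) {
    if (is.character(eqtlTable)) {
        eqtlTable <- tryCatch(
            as.data.frame(data.table::fread(eqtlTable)),
            error = function(e) stop("malformed eQTL table: ",
                                     conditionMessage(e)))
    }
    if (!("gene" %in% names(eqtlTable)) ||
        !(("sv_id" %in% names(eqtlTable)) ||
          all(c("chrom", "start", "end") %in% names(eqtlTable)))) {
        stop("malformed eQTL table: need `gene` plus `sv_id` or ",
             "`chrom`/`start`/`end` columns")
    }
    genes <- lapply(seq_along(svs), function(k) {
        hit <- rep(FALSE, nrow(eqtlTable))
        if ("sv_id" %in% names(eqtlTable) &&
            !is.null(S4Vectors::mcols(svs)$svId)) {
            hit <- hit | (eqtlTable$sv_id == S4Vectors::mcols(svs)$svId[k])
        }
        if (all(c("chrom", "start", "end") %in% names(eqtlTable))) {
            hit <- hit | (
                eqtlTable$chrom ==
                    as.character(GenomicRanges::seqnames(svs)[k]) &
                eqtlTable$start == GenomicRanges::start(svs)[k] &
                eqtlTable$end == GenomicRanges::end(svs)[k])
        }
        as.character(eqtlTable$gene[hit & !is.na(hit)])
    })
    names(genes) <- S4Vectors::mcols(svs)$svId
    S4Vectors::mcols(svs)$eqtlGenes <- IRanges::CharacterList(genes)
    svs
}
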