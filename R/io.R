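#' Read a binned contact matrix from a triplet or dense TSV file
#'
#' Triplet files have rows `bin_i  bin_j  value` with 0-based bin indices;
#' a header line and `#` comments are allowed and ignored. Unlisted pairs
#' are zero. Dense files hold the full `nBins x nBins` matrix. Bins whose
#' marginal sum is zero are flagged missing (they cannot be normalized).
#'
#' @param path file path.
#' @param format `"triplet"` or `"dense"`.
#' @param binsize bin width in bp.
#' @param chromLength chromosome length in bp; `nBins = ceiling(length / binsize)`.
#' @param chrom chromosome name.
#' @param sampleId sample label.
#' @return A [ContactMatrix-class].
#' @export
readContactMatrix <- function(path, format = c("triplet", "dense"),
                              binsize = 40000L, chromLength,
                              chrom = "chr1", sampleId = "sample") {
    format <- match.arg(format)
    if (!file.exists(path)) {
        stop("file not found: ", path)
    }
    nb <- as.integer(ceiling(chromLength / binsize))
    if (format == "triplet") {
        lines <- readLines(path)
        lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
        v <- matrix(0, nb, nb)
        if (length(lines)) {
            first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
            if (any(is.na(suppressWarnings(as.numeric(first))))) {
                lines <- lines[-1]  # header
            }
        }
        if (length(lines)) {
            parts <- strsplit(trimws(lines), "\\s+")
            bad <- which(lengths(parts) != 3L)
            if (length(bad)) {
                stop("malformed triplet row at line ", bad[1], ": ",
                     lines[bad[1]])
            }
            rec <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                          ncol = 3, byrow = TRUE)
            if (anyNA(rec)) {
                stop("malformed triplet row at line ",
                     which(rowSums(is.na(rec)) > 0)[1])
            }
            if (any(rec[, 1] < 0 | rec[, 2] < 0 |
                    rec[, 1] >= nb | rec[, 2] >= nb)) {
                stop("bin index out of range [0, ", nb - 1, "] in ", path)
            }
            i <- rec[, 1] + 1L
            j <- rec[, 2] + 1L
            v[cbind(i, j)] <- rec[, 3]
            v[cbind(j, i)] <- rec[, 3]
        }
    } else {
        v <- as.matrix(data.table::fread(path, header = FALSE))
        if (nrow(v) != nb || ncol(v) != nb) {
            stop("dense matrix is ", nrow(v), "x", ncol(v),
                 " but ", nb, " bins expected")
        }
        dimnames(v) <- NULL
        v <- (v + t(v)) / 2
    }
    ContactMatrix(v, chrom = chrom, binsize = binsize, sampleId = sampleId)
}

#' Write a contact matrix as a triplet TSV (upper triangle, nonzero entries)
#'
#' @param m a [ContactMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContactTriplets <- function(m, path) {
    v <- contactValues(m)
    idx <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    dt <- data.table::data.table(
        bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
        value = v[idx])
    data.table::setorder(dt, bin_i, bin_j)
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Read a BED file of masked regions into 0-based bin indices
#'
#' @param path BED file (0-based half-open intervals).
#' @param binsize bin width in bp.
#' @param chrom restrict to this chromosome (default: keep all).
#' @return sorted integer vector of 0-based bin indices overlapped by >= 1 bp.
#' @export
readBedMask <- function(path, binsize = 40000L, chrom = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(chrom)) {
        gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    }
    if (!length(gr)) {
        return(integer(0))
    }
    # GRanges are 1-based inclusive after import
    bins <- unlist(lapply(seq_along(gr), function(k) {
        seq(floor((GenomicRanges::start(gr)[k] - 1) / binsize),
            floor((GenomicRanges::end(gr)[k] - 1) / binsize))
    }))
    sort(unique(as.integer(bins)))
}

#' Export TAD boundaries as a BED file
#'
#' @param boundaries a `TADBoundarySet` (see [callBoundaries()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeBoundariesBed <- function(boundaries, path) {
    rtracklayer::export(boundaries$boundaries, path, format = "BED")
    invisible(path)
}
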