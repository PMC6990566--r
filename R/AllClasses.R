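#' @import methods
#' @importFrom stats median quantile var sd cor lm coef dnorm rnorm rpois
#'   rnbinom rbinom runif qchisq pchisq ks.test wilcox.test prcomp approx
#'   ppoints complete.cases setNames pnorm residuals integrate
#' @importFrom utils combn head
NULL

#' ContactMatrix: a binned Hi-C contact map for one chromosome of one sample
#'
#' Symmetric `nBins x nBins` matrix of non-negative contact intensities at a
#' fixed bin size, with a per-bin missingness mask. Bins flagged missing
#' (typically bins with zero marginal coverage, which cannot be normalized)
#' are excluded from all downstream averages; their stored values are zero.
#'
#' Bin indices in the user-facing API are 0-based and half-open: bin `b`
#' covers base pairs `[b * binsize, (b + 1) * binsize)`.
#'
#' @slot chrom chromosome name.
#' @slot binsize bin width in bp.
#' @slot values symmetric numeric matrix of contact intensities.
#' @slot missingBins logical vector, `TRUE` for bins excluded from analysis.
#' @slot sampleId sample label.
#' @export
setClass("ContactMatrix",
    representation(
        chrom = "character",
        binsize = "integer",
        values = "matrix",
        missingBins = "logical",
        sampleId = "character"
    )
)

setValidity("ContactMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) {
        return("values must be square")
    }
    if (length(object@missingBins) != nrow(v)) {
        return("missingBins length must equal nrow(values)")
    }
    keep <- !object@missingBins
    vv <- v[keep, keep, drop = FALSE]
    if (length(vv) && (any(!is.finite(vv)) || any(vv < 0))) {
        return("non-missing values must be finite and >= 0")
    }
    if (length(vv) && max(abs(vv - t(vv))) > 1e-8 * max(1, max(abs(vv)))) {
        return("values must be symmetric")
    }
    if (object@binsize <= 0L) {
        return("binsize must be positive")
    }
    TRUE
})

#' Construct a ContactMatrix
#'
#' @param values square symmetric numeric matrix.
#' @param chrom chromosome name.
#' @param binsize bin width (bp).
#' @param missingBins logical mask; defaults to bins with zero marginal sum.
#' @param sampleId sample label.
#' @return A [ContactMatrix-class] object.
#' @export
ContactMatrix <- function(values, chrom = "chr1", binsize = 40000L,
                          missingBins = NULL, sampleId = "sample") {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(missingBins)) {
        missingBins <- rowSums(values) == 0
    }
    values[missingBins, ] <- 0
    values[, missingBins] <- 0
    new("ContactMatrix",
        chrom = chrom, binsize = as.integer(binsize),
        values = values, missingBins = as.logical(missingBins),
        sampleId = sampleId)
}

#' @describeIn ContactMatrix number of bins
#' @param x,object a `ContactMatrix`.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setMethod("nBins", "ContactMatrix", function(x) nrow(x@values))

#' @describeIn ContactMatrix bin width in bp
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binsize)

#' @describeIn ContactMatrix chromosome name
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @export
setMethod("chromName", "ContactMatrix", function(x) x@chrom)

#' @describeIn ContactMatrix sample label
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setMethod("sampleId", "ContactMatrix", function(x) x@sampleId)

#' @describeIn ContactMatrix logical per-bin missingness mask
#' @export
setGeneric("missingBins", function(x) standardGeneric("missingBins"))

#' @export
setMethod("missingBins", "ContactMatrix", function(x) x@missingBins)

#' Contact values of a ContactMatrix
#'
#' @param x a `ContactMatrix`.
#' @param na if `TRUE`, entries touching a missing bin are returned as `NA`
#'   (the form every downstream average uses); if `FALSE`, the raw stored
#'   matrix (zeros at missing bins).
#' @return numeric matrix.
#' @export
setGeneric("contactValues", function(x, na = FALSE) {
    standardGeneric("contactValues")
})

#' @export
setMethod("contactValues", "ContactMatrix", function(x, na = FALSE) {
    v <- x@values
    if (na && any(x@missingBins)) {
        v[x@missingBins, ] <- NA_real_
        v[, x@missingBins] <- NA_real_
    }
    v
})

setMethod("show", "ContactMatrix", function(object) {
    cat("ContactMatrix:", object@sampleId, "\n",
        " chrom:", object@chrom,
        " bins:", nrow(object@values),
        " binsize:", object@binsize, "bp\n",
        " missing bins:", sum(object@missingBins), "\n")
})

#' HiCCohort: per-sample contact matrices sharing one chromosome and binning
#'
#' @slot sampleIds ordered unique sample labels.
#' @slot matrices list of [ContactMatrix-class], one per sample, shared
#'   chromosome / bin size / bin count.
#' @slot batch batch label per sample (processing date or library batch).
#' @export
setClass("HiCCohort",
    representation(
        sampleIds = "character",
        matrices = "list",
        batch = "character"
    )
)

setValidity("HiCCohort", function(object) {
    n <- length(object@sampleIds)
    if (length(object@matrices) != n || length(object@batch) != n) {
        return("sampleIds, matrices and batch must have equal length")
    }
    if (anyDuplicated(object@sampleIds)) {
        return("sample ids must be unique")
    }
    if (n == 0) {
        return("cohort must contain at least one sample")
    }
    ok <- vapply(object@matrices, is, logical(1), class2 = "ContactMatrix")
    if (!all(ok)) {
        return("all elements of matrices must be ContactMatrix")
    }
    ref <- object@matrices[[1]]
    same <- vapply(object@matrices, function(m) {
        m@chrom == ref@chrom && m@binsize == ref@binsize &&
            nrow(m@values) == nrow(ref@values)
    }, logical(1))
    if (!all(same)) {
        return("all matrices must share chrom, binsize and bin count")
    }
    TRUE
})

#' Construct a HiCCohort
#'
#' @param matrices list of [ContactMatrix-class] objects.
#' @param sampleIds sample labels; default taken from the matrices.
#' @param batch batch label per sample; default a single batch.
#' @return A [HiCCohort-class] object.
#' @export
HiCCohort <- function(matrices, sampleIds = NULL, batch = NULL) {
    if (is.null(sampleIds)) {
        sampleIds <- vapply(matrices, sampleId, character(1))
    }
    if (is.null(batch)) {
        batch <- rep("batch1", length(matrices))
    }
    names(matrices) <- sampleIds
    new("HiCCohort", sampleIds = sampleIds, matrices = matrices,
        batch = as.character(batch))
}

#' @describeIn HiCCohort number of samples
#' @param x,object a `HiCCohort`.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "HiCCohort", function(x) length(x@sampleIds))

#' @describeIn HiCCohort sample labels
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "HiCCohort", function(x) x@sampleIds)

#' @describeIn HiCCohort per-sample batch labels
#' @export
setGeneric("batches", function(x) standardGeneric("batches"))

#' @export
setMethod("batches", "HiCCohort", function(x) x@batch)

#' @export
setMethod("nBins", "HiCCohort", function(x) nBins(x@matrices[[1]]))

#' @export
setMethod("binSize", "HiCCohort", function(x) binSize(x@matrices[[1]]))

#' @export
setMethod("chromName", "HiCCohort", function(x) chromName(x@matrices[[1]]))

#' Extract one sample's ContactMatrix from a cohort
#' @param x a `HiCCohort`.
#' @param i sample id or index.
#' @param j,... unused.
#' @export
setMethod("[[", "HiCCohort", function(x, i, j, ...) x@matrices[[i]])

setMethod("show", "HiCCohort", function(object) {
    cat("HiCCohort:", length(object@sampleIds), "samples\n",
        " chrom:", chromName(object),
        " bins:", nBins(object),
        " binsize:", binSize(object), "bp\n",
        " batches:", paste(unique(object@batch), collapse = ", "), "\n")
})

#' CoefficientMap: per-bin-pair regression coefficients around an SV
#'
#' Square grid of regression coefficients (and p-values) for every testable
#' bin pair inside a window centered on a structural variant, as used for
#' blue-red effect heatmaps. Cells overlapping the variant, or where the
#' per-pair regression could not be fit, are flagged invalid.
#'
#' @slot beta numeric matrix of regression coefficients.
#' @slot pval numeric matrix of two-sided p-values.
#' @slot valid logical matrix, `FALSE` where the cell is masked or unfit.
#' @slot bins 0-based bin index per row/column (`NA` for aggregated maps).
#' @slot offsets signed offset of each row/column bin relative to the SV:
#'   negative counted from the left SV boundary, positive from the right,
#'   zero inside the SV.
#' @slot svId id of the variant (or "aggregate").
#' @export
setClass("CoefficientMap",
    representation(
        beta = "matrix",
        pval = "matrix",
        valid = "matrix",
        bins = "integer",
        offsets = "integer",
        svId = "character"
    )
)

setValidity("CoefficientMap", function(object) {
    d <- dim(object@beta)
    if (d[1] != d[2]) {
        return("beta must be square")
    }
    if (!identical(dim(object@pval), d) || !identical(dim(object@valid), d)) {
        return("beta, pval, valid must share dimensions")
    }
    if (length(object@offsets) != d[1]) {
        return("offsets length must match grid")
    }
    b <- object@beta[object@valid]
    if (length(b) && any(!is.finite(b))) {
        return("valid cells must hold finite coefficients")
    }
    TRUE
})

setMethod("show", "CoefficientMap", function(object) {
    cat("CoefficientMap:", object@svId, "\n",
        " grid:", nrow(object@beta), "x", ncol(object@beta),
        " valid cells:", sum(object@valid), "\n")
})

#' @describeIn CoefficientMap coefficient matrix with `NA` at invalid cells
#' @param x,object a `CoefficientMap`.
#' @export
setGeneric("coefficientGrid", function(x) standardGeneric("coefficientGrid"))

#' @export
setMethod("coefficientGrid", "CoefficientMap", function(x) {
    b <- x@beta
    b[!x@valid] <- NA_real_
    b
})
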