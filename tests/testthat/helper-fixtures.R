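# small in-code fixtures shared across test files

# symmetric ContactMatrix from an upper-triangle assignment list
cmFromPairs <- function(nb, pairs, values, binsize = 40000L,
                        sampleId = "toy", missing = NULL) {
    v <- matrix(0, nb, nb)
    for (k in seq_along(values)) {
        i <- pairs[k, 1] + 1L
        j <- pairs[k, 2] + 1L
        v[i, j] <- v[j, i] <- values[k]
    }
    ContactMatrix(v, binsize = binsize, sampleId = sampleId,
                  missingBins = if (is.null(missing)) {
                      rep(FALSE, nb)
                  } else missing)
}

# random symmetric integer count matrix (deterministic under seed)
randomContactMatrix <- function(nb, seed = 1, sampleId = "rnd",
                                binsize = 40000L) {
    set.seed(seed)
    v <- matrix(0L, nb, nb)
    ut <- upper.tri(v, diag = TRUE)
    v[ut] <- rpois(sum(ut), 20)
    v <- v + t(v) - diag(diag(v))
    ContactMatrix(v, binsize = binsize, sampleId = sampleId)
}

# a single-record deletion GRanges with per-sample dosages
delGRanges <- function(start, end, dosage, id = "del1", chrom = "chr1",
                       svtype = "DEL") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    S4Vectors::mcols(gr)$svId <- id
    S4Vectors::mcols(gr)$svtype <- svtype
    S4Vectors::mcols(gr)$svLen <- GenomicRanges::width(gr)
    dm <- matrix(dosage, nrow = 1)
    colnames(dm) <- if (!is.null(names(dosage))) {
        names(dosage)
    } else {
        sprintf("S%02d", seq_along(dosage))
    }
    S4Vectors::mcols(gr)$dosage <- dm
    names(gr) <- id
    gr
}

# HMMStates stub with a given decoded path
hmmStub <- function(states) {
    structure(list(states = states,
                   posterior = matrix(1 / 3, length(states), 3),
                   mean = c(-1, 0, 1), sd = rep(1, 3),
                   transition = diag(3), init = rep(1 / 3, 3),
                   logLik = numeric(0), converged = TRUE, seed = 1L,
                   decoding = "posterior"),
              class = "HMMStates")
}

# closed-form OLS oracle: solve the normal equations directly and return
# the Wald t-test for one column of the design
olsOracle <- function(y, X, term) {
    XtX <- crossprod(X)
    b <- solve(XtX, crossprod(X, y))
    resid <- y - X %*% b
    df <- length(y) - ncol(X)
    s2 <- sum(resid^2) / df
    se <- sqrt(diag(solve(XtX)) * s2)
    tt <- b[term, 1] / se[term]
    list(beta = unname(b[term, 1]), se = unname(se[term]),
         p = unname(2 * pt(abs(tt), df, lower.tail = FALSE)))
}
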