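#' Directionality index per bin
#'
#' For bin `i`, let `A` be the sum of contacts to the `window` upstream
#' bins and `B` the sum to the `window` downstream bins (windows truncated
#' at chromosome ends; contacts to missing bins are absent). With
#' `E = (A + B) / 2`, the DI is
#' `sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`, zero when `A == B` or
#' `E == 0`. Positive DI marks a downstream contact bias (typical of
#' domain starts), negative DI an upstream bias (domain ends).
#'
#' @param m a [ContactMatrix-class].
#' @param windowBins window width in bins (default 50, i.e. 2 Mb at 40 kb).
#' @return a `DIProfile` data.frame with columns `bin` (0-based), `di`
#'   (`NA` at missing bins), `A`, `B`; `windowBins` stored as an attribute.
#' @export
directionalityIndex <- function(m, windowBins = 50L) {
    if (windowBins < 1) {
        stop("windowBins must be >= 1")
    }
    nb <- nBins(m)
    v <- contactValues(m)  # zeros at missing bins: absent from sums
    di <- A <- B <- numeric(nb)
    for (i in seq_len(nb)) {
        up <- seq(max(1, i - windowBins), i - 1)
        dn <- seq(i + 1, min(nb, i + windowBins))
        a <- if (i > 1) sum(v[i, up]) else 0
        b <- if (i < nb) sum(v[i, dn]) else 0
        e <- (a + b) / 2
        di[i] <- if (e == 0 || a == b) {
            0
        } else {
            sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
        }
        A[i] <- a
        B[i] <- b
    }
    di[missingBins(m)] <- NA_real_
    out <- data.frame(bin = seq_len(nb) - 1L, di = di, A = A, B = B)
    attr(out, "windowBins") <- as.integer(windowBins)
    class(out) <- c("DIProfile", "data.frame")
    out
}

#' Fit a three-state Gaussian-emission HMM to a DI profile
#'
#' States are `upstream_bias`, `no_bias`, `downstream_bias`, labelled by
#' emission-mean order (lowest mean = upstream bias, i.e. most negative
#' DI). Fitting is expectation-maximization from a deterministic
#' tertile-based initialization, so results are reproducible without
#' random restarts; missing DI values are marginalized. Decoding is
#' per-bin posterior maximum by default, or Viterbi.
#'
#' @param di a `DIProfile` from [directionalityIndex()].
#' @param maxIter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer recorded in the result (the fit itself is
#'   deterministic).
#' @param decoding `"posterior"` (default) or `"viterbi"`.
#' @return an `HMMStates` list: `states` (character per bin), `posterior`
#'   (bins x 3), `mean`, `sd`, `transition`, `init`, `logLik` (trace),
#'   `converged`, `seed`, `decoding`.
#' @export
fitDIHMM <- function(di, maxIter = 100L, tol = 1e-6, seed = 1L,
                     decoding = c("posterior", "viterbi")) {
    decoding <- match.arg(decoding)
    x <- di$di
    n <- length(x)
    obs <- !is.na(x)
    labels <- c("upstream_bias", "no_bias", "downstream_bias")
    if (sum(obs) < 3 || sd(x[obs]) == 0) {
        # degenerate profile: no directional signal anywhere
        post <- matrix(rep(c(0, 1, 0), each = n), n, 3)
        colnames(post) <- labels
        return(structure(list(
            states = rep("no_bias", n), posterior = post,
            mean = c(0, 0, 0), sd = rep(1e-6, 3),
            transition = diag(3), init = c(0, 1, 0),
            logLik = numeric(0), converged = TRUE,
            seed = as.integer(seed), decoding = decoding),
            class = "HMMStates"))
    }
    xo <- x[obs]
    q <- quantile(xo, c(1 / 3, 2 / 3), names = FALSE)
    grp <- findInterval(xo, q) + 1L
    mu <- vapply(1:3, function(k) {
        if (any(grp == k)) mean(xo[grp == k]) else quantile(xo, (2 * k - 1) / 6)
    }, numeric(1))
    mu <- sort(mu)
    sdFloor <- max(sd(xo) * 1e-3, 1e-8)
    sg <- rep(max(sd(xo) / 2, sdFloor), 3)
    Tr <- matrix(0.05, 3, 3)
    diag(Tr) <- 0.9
    pi0 <- rep(1 / 3, 3)

    emis <- function(mu, sg) {
        e <- matrix(1, n, 3)
        for (k in 1:3) {
            e[obs, k] <- dnorm(x[obs], mu[k], sg[k])
        }
        pmax(e, 1e-300)
    }

    ll.trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        B <- emis(mu, sg)
        # scaled forward-backward
        alpha <- matrix(0, n, 3)
        beta <- matrix(0, n, 3)
        cs <- numeric(n)
        a <- pi0 * B[1, ]
        cs[1] <- sum(a)
        alpha[1, ] <- a / cs[1]
        for (t in 2:n) {
            a <- (alpha[t - 1, ] %*% Tr) * B[t, ]
            cs[t] <- sum(a)
            alpha[t, ] <- a / cs[t]
        }
        beta[n, ] <- 1
        for (t in (n - 1):1) {
            b <- Tr %*% (B[t + 1, ] * beta[t + 1, ])
            beta[t, ] <- b / cs[t + 1]
        }
        ll <- sum(log(cs))
        ll.trace <- c(ll.trace, ll)
        gamma <- alpha * beta
        gamma <- gamma / rowSums(gamma)
        # transition expectations
        xi <- matrix(0, 3, 3)
        for (t in seq_len(n - 1)) {
            num <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * Tr
            xi <- xi + num / sum(num)
        }
        pi0 <- gamma[1, ]
        Tr <- xi / pmax(rowSums(xi), 1e-300)
        go <- gamma[obs, , drop = FALSE]
        wk <- colSums(go)
        mu.new <- colSums(go * xo) / pmax(wk, 1e-300)
        sg.new <- sqrt(colSums(go * (xo - rep(mu.new, each = sum(obs)))^2) /
                           pmax(wk, 1e-300))
        mu <- mu.new
        sg <- pmax(sg.new, sdFloor)
        if (iter > 1 &&
            abs(ll - ll.trace[iter - 1]) < tol * (abs(ll) + 1e-12)) {
            converged <- TRUE
            break
        }
    }
    # relabel states by emission-mean order
    ord <- order(mu)
    mu <- mu[ord]
    sg <- sg[ord]
    Tr <- Tr[ord, ord]
    pi0 <- pi0[ord]
    B <- emis(mu, sg)
    alpha <- matrix(0, n, 3)
    beta <- matrix(0, n, 3)
    cs <- numeric(n)
    a <- pi0 * B[1, ]
    cs[1] <- sum(a)
    alpha[1, ] <- a / cs[1]
    for (t in 2:n) {
        a <- (alpha[t - 1, ] %*% Tr) * B[t, ]
        cs[t] <- sum(a)
        alpha[t, ] <- a / cs[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1) {
        b <- Tr %*% (B[t + 1, ] * beta[t + 1, ])
        beta[t, ] <- b / cs[t + 1]
    }
    post <- alpha * beta
    post <- post / rowSums(post)
    colnames(post) <- labels
    path <- if (decoding == "posterior") {
        max.col(post, ties.method = "first")
    } else {
        .viterbi(pi0, Tr, B)
    }
    structure(list(
        states = labels[path], posterior = post,
        mean = mu, sd = sg, transition = Tr, init = pi0,
        logLik = ll.trace, converged = converged,
        seed = as.integer(seed), decoding = decoding),
        class = "HMMStates")
}

.viterbi <- function(pi0, Tr, B) {
    n <- nrow(B)
    lT <- log(pmax(Tr, 1e-300))
    delta <- matrix(-Inf, n, 3)
    psi <- matrix(0L, n, 3)
    delta[1, ] <- log(pmax(pi0, 1e-300)) + log(B[1, ])
    for (t in 2:n) {
        for (k in 1:3) {
            cand <- delta[t - 1, ] + lT[, k]
            psi[t, k] <- which.max(cand)
            delta[t, k] <- cand[psi[t, k]] + log(B[t, k])
        }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    for (t in (n - 1):1) {
        path[t] <- psi[t + 1, path[t + 1]]
    }
    path
}

#' Call TAD boundaries from a decoded HMM state path
#'
#' A boundary is placed wherever the state path switches from upstream
#' bias (end of one domain) to downstream bias (start of the next), with
#' any no-bias bins in between. The boundary interval covers the bins
#' after the last upstream-biased bin up to and including the first
#' downstream-biased bin, stored half-open in bin units and exported in
#' bp. Domains shorter than `minDomainBins` are merged into the preceding
#' domain (their leading boundary is dropped).
#'
#' @param states an `HMMStates` from [fitDIHMM()].
#' @param minDomainBins minimum domain width in bins (default 3).
#' @param binsize bin width in bp.
#' @param chrom chromosome name.
#' @return a `TADBoundarySet` list: `boundaries` and `domains` (both
#'   [GenomicRanges::GRanges], 1-based inclusive as usual), plus
#'   `boundaryBins`, a two-column matrix of half-open 0-based bin
#'   intervals.
#' @export
callBoundaries <- function(states, minDomainBins = 3L, binsize = 40000L,
                           chrom = "chr1") {
    path <- states$states
    n <- length(path)
    biased <- which(path != "no_bias")
    bstart <- integer(0)
    bend <- integer(0)  # half-open 0-based bin intervals
    if (length(biased) >= 2) {
        st <- path[biased]
        for (k in seq_len(length(biased) - 1)) {
            if (st[k] == "upstream_bias" && st[k + 1] == "downstream_bias") {
                lastU <- biased[k]       # 1-based
                firstD <- biased[k + 1]
                bstart <- c(bstart, lastU)        # = (lastU-1)+1 0-based
                bend <- c(bend, firstD)           # half-open end
            }
        }
    }
    if (length(bstart) && minDomainBins > 1) {
        repeat {
            domStart <- c(0L, bend)
            domEnd <- c(bstart, n)
            len <- domEnd - domStart
            short <- which(len < minDomainBins)
            # a short domain merges into the preceding one: drop the
            # boundary that opens it
            drop <- short[short > 1] - 1L
            drop <- drop[drop <= length(bstart)]
            if (!length(drop)) break
            bstart <- bstart[-drop[1]]
            bend <- bend[-drop[1]]
            if (!length(bstart)) break
        }
    }
    boundaryBins <- cbind(start = bstart, end = bend)
    mk <- function(s0, e0) {  # half-open 0-based bins -> 1-based bp GRanges
        if (!length(s0)) {
            return(GenomicRanges::GRanges())
        }
        GenomicRanges::GRanges(chrom, IRanges::IRanges(
            start = s0 * binsize + 1, end = e0 * binsize))
    }
    domStart <- c(0L, bend)
    domEnd <- c(bstart, n)
    structure(list(
        boundaries = mk(bstart, bend),
        domains = mk(domStart, domEnd),
        boundaryBins = boundaryBins,
        binsize = as.integer(binsize), chrom = chrom),
        class = "TADBoundarySet")
}

#' @export
print.TADBoundarySet <- function(x, ...) {
    cat("TADBoundarySet:", nrow(x$boundaryBins), "boundaries,",
        length(x$domains), "domains on", x$chrom, "\n")
    invisible(x)
}
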