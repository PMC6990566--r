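test_that("bias removal is a no-op when covariates are identical across bins", {
    m <- randomContactMatrix(6, seed = 2)
    cov <- binCovariates(rep(500, 6), rep(0.5, 6), rep(1, 6))
    out <- hicnormNormalize(m, cov)
    expect_equal(contactValues(out), contactValues(m), tolerance = 1e-10)
})

test_that("bins with non-positive covariates become missing with a warning", {
    m <- randomContactMatrix(5, seed = 3)
    cov <- binCovariates(rep(500, 5), rep(0.5, 5), c(1, 1, 0, 1, 1))
    expect_warning(out <- hicnormNormalize(m, cov), "flagged missing")
    expect_true(missingBins(out)[3])
    expect_equal(contactValues(out, na = TRUE)[3, 1], NA_real_)
})

test_that("bias removal matches a hand-written IRLS Poisson oracle", {
    set.seed(7)
    nb <- 6
    eff <- c(rep(400, 3), rep(800, 3))
    gc <- c(rep(0.4, 3), rep(0.8, 3))
    mp <- c(rep(0.5, 3), rep(1, 3))
    m <- randomContactMatrix(nb, seed = 8)
    out <- hicnormNormalize(m, binCovariates(eff, gc, mp))

    # independent IRLS fit of the same Poisson GLM
    v <- contactValues(m)
    ut <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
    y <- v[ut]
    X <- cbind(1,
               log(eff[ut[, 1]] * eff[ut[, 2]]),
               log(gc[ut[, 1]] * gc[ut[, 2]]),
               log(mp[ut[, 1]] * mp[ut[, 2]]))
    # the three covariates are perfectly collinear here (two bin groups):
    # keep intercept + one column, as the model matrix reduces to rank 2
    X <- X[, 1:2]
    b <- rep(0, ncol(X))
    b[1] <- log(mean(y))
    for (it in 1:100) {
        eta <- drop(X %*% b)
        mu <- exp(eta)
        W <- mu
        z <- eta + (y - mu) / mu
        bNew <- solve(crossprod(X, W * X), crossprod(X, W * z))
        if (max(abs(bNew - b)) < 1e-12) {
            b <- bNew
            break
        }
        b <- bNew
    }
    fitted <- exp(drop(X %*% b))
    expected <- y * mean(fitted) / fitted
    got <- contactValues(out)[ut]
    expect_equal(got, expected, tolerance = 1e-6)
})

test_that("band quantile normalization reproduces the hand-computed example", {
    # band |i-j| = 1 of a 4-bin matrix holds three entries per sample
    p1 <- rbind(c(0, 1), c(1, 2), c(2, 3))
    base <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3), c(0, 2), c(1, 3),
                  c(0, 3))
    m1 <- cmFromPairs(4, rbind(p1, base), c(1, 2, 3, rep(9, 7)),
                      sampleId = "a")
    m2 <- cmFromPairs(4, rbind(p1, base), c(4, 5, 6, rep(9, 7)),
                      sampleId = "b")
    out <- bandQuantileNormalize(HiCCohort(list(m1, m2)),
                                 minBandEntries = 3L)
    b1 <- vapply(1:3, function(k) {
        contactValues(out[["a"]])[p1[k, 1] + 1, p1[k, 2] + 1]
    }, numeric(1))
    b2 <- vapply(1:3, function(k) {
        contactValues(out[["b"]])[p1[k, 1] + 1, p1[k, 2] + 1]
    }, numeric(1))
    expect_equal(b1, c(2.5, 3.5, 4.5))
    expect_equal(b2, c(2.5, 3.5, 4.5))
})

test_that("band quantile normalization is idempotent on identical samples", {
    m <- randomContactMatrix(10, seed = 5, sampleId = "a")
    m2 <- ContactMatrix(contactValues(m), sampleId = "b")
    out <- bandQuantileNormalize(HiCCohort(list(m, m2)),
                                 minBandEntries = 2L)
    expect_equal(contactValues(out[["a"]]), contactValues(m))
    expect_equal(contactValues(out[["b"]]), contactValues(m))
})

test_that("processed bands have identical sorted entries across samples", {
    mats <- lapply(1:4, function(s) {
        randomContactMatrix(15, seed = 10 + s, sampleId = paste0("s", s))
    })
    out <- bandQuantileNormalize(HiCCohort(mats), minBandEntries = 5L)
    for (d in c(0, 1, 5, 9)) {
        i <- seq_len(15 - d)
        ent <- vapply(sampleIds(out), function(s) {
            sort(contactValues(out[[s]])[cbind(i, i + d)])
        }, numeric(15 - d))
        expect_equal(ent[, 1], ent[, 2])
        expect_equal(ent[, 1], ent[, 4])
    }
    # symmetry and non-negativity preserved
    v <- contactValues(out[["s1"]])
    expect_equal(v, t(v))
    expect_true(all(v >= 0))
})

test_that("band quantile normalization agrees with limma on complete bands", {
    skip_if_not_installed("limma")
    set.seed(31)
    mats <- lapply(1:3, function(s) {
        v <- matrix(runif(12 * 12, 1, 50), 12, 12)
        v <- (v + t(v)) / 2
        ContactMatrix(v, sampleId = paste0("s", s))
    })
    out <- bandQuantileNormalize(HiCCohort(mats), minBandEntries = 4L)
    for (d in c(1, 4)) {
        i <- seq_len(12 - d)
        x <- vapply(mats, function(m) {
            contactValues(m)[cbind(i, i + d)]
        }, numeric(12 - d))
        ref <- limma::normalizeQuantiles(x)
        got <- vapply(seq_len(3), function(s) {
            contactValues(out[[paste0("s", s)]])[cbind(i, i + d)]
        }, numeric(12 - d))
        expect_equal(got, ref, tolerance = 1e-10,
                     ignore_attr = TRUE)
    }
})

test_that("single-sample cohorts cannot be band-normalized", {
    m <- randomContactMatrix(5, seed = 1)
    expect_error(bandQuantileNormalize(HiCCohort(list(m))), ">= 2 samples")
})

test_that("batch correction removes an additive band shift exactly", {
    set.seed(17)
    mk <- function(shift, id) {
        v <- matrix(runif(100, 10, 20), 10, 10) + shift
        v <- (v + t(v)) / 2
        ContactMatrix(v, sampleId = id)
    }
    ch <- HiCCohort(list(mk(0, "a1"), mk(0, "a2"), mk(10, "b1"),
                         mk(10, "b2")),
                    batch = c("A", "A", "B", "B"))
    out <- batchCorrectBands(ch)
    for (d in c(0, 3, 7)) {
        i <- seq_len(10 - d)
        bandMean <- vapply(sampleIds(out), function(s) {
            mean(contactValues(out[[s]])[cbind(i, i + d)])
        }, numeric(1))
        expect_equal(mean(bandMean[1:2]), mean(bandMean[3:4]),
                     tolerance = 1e-8)
    }
})

test_that("batch correction requires two batches and shrinks injected effects", {
    m <- randomContactMatrix(6, seed = 1)
    expect_error(
        batchCorrectBands(HiCCohort(list(m, m), sampleIds = c("a", "b"))),
        ">= 2 batches")
    # multiplicative factor 1.5 on batch B: between-batch variance of
    # band means must shrink at least 10-fold
    set.seed(23)
    mk <- function(fac, id) {
        v <- matrix(rpois(400, 30), 20, 20) * fac
        v <- (v + t(v)) / 2
        ContactMatrix(v, sampleId = id)
    }
    ch <- HiCCohort(list(mk(1, "a1"), mk(1, "a2"), mk(1.5, "b1"),
                         mk(1.5, "b2")),
                    batch = c("A", "A", "B", "B"))
    out <- batchCorrectBands(ch)
    bv <- function(cohort) {
        vv <- vapply(c(1, 5, 10), function(d) {
            i <- seq_len(20 - d)
            means <- vapply(sampleIds(cohort), function(s) {
                mean(contactValues(cohort[[s]])[cbind(i, i + d)])
            }, numeric(1))
            var(c(mean(means[1:2]), mean(means[3:4])))
        }, numeric(1))
        mean(vv)
    }
    expect_lt(bv(out), bv(ch) / 10)
})
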