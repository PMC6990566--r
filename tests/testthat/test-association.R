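test_that("OLS association matches the normal-equations oracle", {
    set.seed(3)
    for (rep in 1:8) {
        n <- 19
        dos <- rbinom(n, 2, 0.4)
        if (length(unique(dos)) < 2) next
        vals <- rnorm(n, 10, 2)
        pcs <- matrix(rnorm(2 * n), n, 2)
        sex <- rbinom(n, 1, 0.5)
        cov <- covariateSet(pcs = pcs, sex = sex)
        fit <- regressRegion(vals, dos, cov, orientation = "dosageOnStat")
        or <- olsOracle(dos, cbind(`(Intercept)` = 1, stat = vals, cov),
                        "stat")
        expect_equal(fit$beta, or$beta, tolerance = 1e-8)
        expect_equal(fit$se, or$se, tolerance = 1e-8)
        expect_equal(fit$p, or$p, tolerance = 1e-8)
        fit2 <- regressRegion(vals, dos, cov, orientation = "standard")
        or2 <- olsOracle(vals, cbind(`(Intercept)` = 1, dosage = dos, cov),
                         "dosage")
        expect_equal(fit2$beta, or2$beta, tolerance = 1e-8)
        expect_equal(fit2$p, or2$p, tolerance = 1e-8)
    }
})

test_that("a perfect dosage-linear signal is detected with the right sign", {
    dos <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 0, 1, 2)
    vals <- 5 + 2 * dos + c(1:12) * 1e-9
    fit <- regressRegion(vals, dos, orientation = "standard")
    expect_lt(fit$p, 1e-10)
    expect_gt(fit$beta, 0)
    expect_error(regressRegion(vals, rep(1, 12)), "monomorphic")
    cov <- covariateSet(pcs = cbind(dos))  # collinear with dosage
    expect_error(regressRegion(vals, dos, cov, orientation = "standard"),
                 "collinear")
})

test_that("the association test is calibrated at the nominal level", {
    set.seed(5)
    n <- 19
    vals <- rnorm(n, 10, 2)
    cov <- covariateSet(pcs = matrix(rnorm(2 * n), n, 2),
                        sex = rbinom(n, 1, 0.5))
    rej <- vapply(seq_len(1000), function(r) {
        dos <- sample(rbinom(n, 2, 0.4))
        if (length(unique(dos)) < 2) {
            return(NA)
        }
        regressRegion(vals, dos, cov)$p < 0.05
    }, logical(1))
    rate <- mean(rej, na.rm = TRUE)
    expect_gt(rate, 0.03)
    expect_lt(rate, 0.07)
})

test_that("permutation nulls are seeded, reproducible, and uniform", {
    set.seed(7)
    nsv <- 40
    n <- 19
    valuesMat <- matrix(rnorm(nsv * n, 10), nsv, n)
    dosageMat <- matrix(rbinom(nsv * n, 2, 0.4), nsv, n)
    n1 <- permutationNull(valuesMat, dosageMat, nPerm = 50, seed = 11)
    n2 <- permutationNull(valuesMat, dosageMat, nPerm = 50, seed = 11)
    expect_identical(n1, n2)
    n3 <- permutationNull(valuesMat, dosageMat, nPerm = 2, seed = 12)
    expect_false(identical(n1$p[1], n3$p[1]))
    expect_equal(nrow(n1), nsv * 50)
    ks <- suppressWarnings(ks.test(n1$p, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("genomic inflation follows its median-chi-square definition", {
    expect_equal(genomicInflation(rep(0.5, 11))$lambda, 1.0)
    set.seed(9)
    p <- runif(10000)
    expect_equal(genomicInflation(p)$lambda, 1.0, tolerance = 0.03)
    # halving uniform p-values inflates lambda above 1
    expect_gt(genomicInflation(p / 2)$lambda, 1)
    expect_error(genomicInflation(numeric(0)), "no p-values")
    expect_error(genomicInflation(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("QQ coordinates pair sorted observed with null quantiles", {
    set.seed(15)
    p <- runif(50)
    qq <- qqPoints(p, p)
    expect_equal(qq$observed, qq$expected)
    # uniformly smaller observed p-values lie above the identity
    qq2 <- qqPoints(p / 10, p)
    expect_true(all(qq2$observed > qq2$expected))
    # interpolated null quantiles match the type-7 definition
    nullP <- runif(80)
    qq3 <- qqPoints(p, nullP)
    expect_equal(10^(-qq3$expected),
                 unname(quantile(nullP, ppoints(50), type = 7)))
})

test_that("KS stratum comparison matches a brute-force ECDF-gap oracle", {
    expect_equal(compareSizeStrata(c(0.1, 0.5, 0.9),
                                   c(0.1, 0.5, 0.9))$statistic, 0)
    expect_equal(compareSizeStrata(c(0.1, 0.2), c(0.8, 0.9))$statistic, 1)
    set.seed(21)
    for (rep in 1:5) {
        a <- runif(sample(5:20, 1))
        b <- runif(sample(5:20, 1))
        got <- compareSizeStrata(a, b)$statistic
        grid <- sort(unique(c(a, b)))
        oracle <- max(vapply(grid, function(t) {
            abs(mean(a <= t) - mean(b <= t))
        }, numeric(1)))
        expect_equal(got, oracle, tolerance = 1e-12)
    }
})

test_that("group rank-sum test enumerates exactly for small groups", {
    # identical group and null: every permutation ties, p = 1
    x <- c(1, 2, 3, 4)
    expect_equal(groupVsNullWilcoxon(x, x)$p, 1)
    # exact branch equals the classical exact distribution (tie-free)
    set.seed(25)
    for (rep in 1:5) {
        a <- rnorm(4)
        b <- rnorm(4)
        got <- groupVsNullWilcoxon(a, b)
        expect_equal(got$method, "exact enumeration")
        ref <- wilcox.test(a, b, exact = TRUE)$p.value
        expect_equal(got$p, ref, tolerance = 1e-12)
    }
    # a clear +10 shift is detected with the normal approximation
    set.seed(27)
    shifted <- groupVsNullWilcoxon(rnorm(20) + 10, rnorm(20))
    expect_lt(shifted$p, 0.01)
    expect_equal(shifted$method, "normal approximation")
})

test_that("ancestry PCs separate simulated populations deterministically", {
    set.seed(33)
    n <- 40
    pop <- rep(c(0, 1), each = n / 2)
    f <- runif(300, 0.1, 0.9)
    shift <- 0.35 * ifelse(runif(300) < 0.5, 1, -1)
    G <- t(vapply(pop, function(g) {
        rbinom(300, 2, pmin(0.95, pmax(0.05, f + g * shift)))
    }, numeric(300)))
    pcs <- ancestryPCs(G, k = 2)
    s1 <- pcs$scores[pop == 0, 1]
    s2 <- pcs$scores[pop == 1, 1]
    withinSd <- sqrt((var(s1) + var(s2)) / 2)
    expect_gte(abs(mean(s1) - mean(s2)), 5 * withinSd)
    # k = 0 gives an empty covariate block
    expect_equal(ncol(ancestryPCs(G, k = 0)$scores), 0L)
    # duplicated samples receive identical scores
    G2 <- rbind(G, G[1, ])
    p2 <- ancestryPCs(G2, k = 2)
    expect_equal(p2$scores[1, ], p2$scores[n + 1, ])
    expect_error(ancestryPCs(matrix(1, 5, 4)), "no variable columns")
})

test_that("covariate selection prefers a planted confounder and reports lambdas", {
    set.seed(37)
    n <- 19
    nsv <- 120
    conf <- rnorm(n)
    dosageMat <- t(vapply(seq_len(nsv), function(s) {
        rbinom(n, 2, plogis(conf))
    }, numeric(n)))
    spanValues <- t(vapply(seq_len(nsv), function(s) {
        2 * conf + rnorm(n)
    }, numeric(n)))
    flankValues <- t(vapply(seq_len(nsv), function(s) {
        2 * conf + rnorm(n)
    }, numeric(n)))
    sel <- selectCovariates(list(conf = cbind(conf = conf)),
                            spanValues, flankValues, dosageMat)
    expect_equal(sel$chosen, "conf")
    noneRow <- sel$table[sel$table$model == "none", ]
    confRow <- sel$table[sel$table$model == "conf", ]
    expect_gt(noneRow$lambdaMean, confRow$lambdaMean)
    # the lambda table is consistent with direct inflation calls
    ps <- vapply(seq_len(nsv), function(s) {
        regressRegion(spanValues[s, ], dosageMat[s, ],
                      cbind(conf = conf))$p
    }, numeric(1))
    expect_equal(confRow$lambdaSpan, genomicInflation(ps)$lambda)
    # saturated models are excluded with a warning
    big <- matrix(rnorm(n * 17), n, 17)
    expect_warning(
        selectCovariates(list(big = big), spanValues, flankValues,
                         dosageMat),
        "saturates")
})

test_that("flank sweep summarizes widths and flags the strongest flank width", {
    set.seed(39)
    n <- 10
    nb <- 40
    dos <- c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2)
    # dosage-proportional gain confined to pairs within 2 bins of the
    # deletion at bin 20
    mats <- lapply(seq_len(n), function(s) {
        v <- matrix(rnorm(nb * nb, 20, 1), nb, nb)
        near <- 19:23
        v[near, near] <- v[near, near] + 3 * dos[s]
        v <- (v + t(v)) / 2
        ContactMatrix(pmax(v, 0), sampleId = sprintf("S%02d", s))
    })
    ch <- HiCCohort(mats)
    sv <- delGRanges(20 * 40000 + 1, 21 * 40000,
                     setNames(dos, sampleIds(ch)))
    sw <- flankSweep(c(2, 6), ch, sv, orientation = "standard")
    expect_equal(nrow(sw), 2L)
    expect_gt(sw$medianAbsBetaSpan[sw$width == 2],
              sw$medianAbsBetaSpan[sw$width == 6])
    sw1 <- flankSweep(6, ch, sv)
    expect_equal(nrow(sw1), 1L)
    expect_equal(attr(sw1, "bestWidth"), 6)
    # default flank width of the association entry point is 6 bins
    expect_equal(eval(formals(associateDeletions)$nFlank), 6L)
})

test_that("per-bin coefficient maps localize a span-confined effect", {
    set.seed(45)
    n <- 12
    nb <- 30
    dos <- rep(c(0, 1, 2), each = 4)
    delBins <- 14:15  # 0-based
    mats <- lapply(seq_len(n), function(s) {
        v <- matrix(rnorm(nb * nb, 50, 1), nb, nb)
        left <- 12:14
        right <- 17:19
        v[left, right] <- v[left, right] + 5 * dos[s]
        v[right, left] <- t(v[left, right])
        v <- (v + t(v)) / 2
        ContactMatrix(pmax(v, 0), sampleId = sprintf("S%02d", s))
    })
    ch <- HiCCohort(mats)
    sv <- delGRanges(14 * 40000 + 1, 16 * 40000,
                     setNames(dos, sampleIds(ch)))
    cm <- perBinCoefficients(ch, sv, windowBins = 4L,
                             orientation = "standard")
    # deletion cells are masked
    inDel <- cm@bins %in% delBins
    expect_false(any(cm@valid[inDel, ]))
    b <- coefficientGrid(cm)
    spanCells <- outer(cm@offsets < 0, cm@offsets > 0)
    gain <- b[spanCells & cm@valid]
    elsewhere <- b[!spanCells & cm@valid]
    expect_gt(median(gain, na.rm = TRUE), 2)
    expect_lt(median(abs(elsewhere), na.rm = TRUE), 1)
})

test_that("orientation flip preserves per-cell p-values without covariates", {
    set.seed(47)
    n <- 10
    nb <- 12
    dos <- rbinom(n, 2, 0.5)
    dos[1:2] <- c(0, 2)
    mats <- lapply(seq_len(n), function(s) {
        v <- matrix(rnorm(nb * nb, 30, 2), nb, nb)
        v <- (v + t(v)) / 2
        ContactMatrix(pmax(v, 0), sampleId = sprintf("S%02d", s))
    })
    ch <- HiCCohort(mats)
    sv <- delGRanges(5 * 40000 + 1, 6 * 40000,
                     setNames(dos, sampleIds(ch)))
    cmP <- perBinCoefficients(ch, sv, windowBins = 3L,
                              orientation = "dosageOnStat")
    cmS <- perBinCoefficients(ch, sv, windowBins = 3L,
                              orientation = "standard")
    expect_equal(cmP@pval[cmP@valid], cmS@pval[cmS@valid],
                 tolerance = 1e-6)
    # all-equal matrices across samples flag every cell
    same <- HiCCohort(lapply(seq_len(n), function(s) {
        ContactMatrix(contactValues(mats[[1]]),
                      sampleId = sprintf("S%02d", s))
    }))
    cmC <- perBinCoefficients(same, sv, windowBins = 3L,
                              orientation = "standard")
    expect_false(any(cmC@valid))
})

test_that("coefficient-map aggregation is a cellwise robust median", {
    mk <- function(values) {
        W <- 5L
        beta <- matrix(values, W, W)
        new("CoefficientMap", beta = beta,
            pval = matrix(NA_real_, W, W),
            valid = matrix(TRUE, W, W), bins = 0:4,
            offsets = c(-2L, -1L, 0L, 1L, 2L), svId = "x")
    }
    one <- aggregateCoefficientMaps(list(mk(1)))
    # single map: values carried through on the offset grid
    expect_true(all(coefficientGrid(one)[one@valid] == 1))
    agg <- aggregateCoefficientMaps(list(mk(1), mk(3)))
    expect_true(all(coefficientGrid(agg)[agg@valid] == 2))
    # medians resist an outlier map better than means do
    med <- aggregateCoefficientMaps(list(mk(1), mk(2), mk(100)),
                                    "median")
    avg <- aggregateCoefficientMaps(list(mk(1), mk(2), mk(100)), "mean")
    expect_lt(abs(coefficientGrid(med)[1, 2] - 2),
              abs(coefficientGrid(avg)[1, 2] - 2))
})
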