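test_that("hat-matrix LOO equals the naive refits", {
    for (seed in c(71, 72)) {
        gen <- plantedFixture(40, 10, 3, noise = 0.5, seed = seed)
        nms <- gen$truth$signalNames
        hat <- looCV(gen$descriptors, gen$activities, nms, method = "hat")
        ref <- looCV(gen$descriptors, gen$activities, nms, method = "refit")
        expect_equal(hat$predictions, ref$predictions, tolerance = 1e-8)
        expect_equal(hat$r2, ref$r2, tolerance = 1e-10)
        expect_equal(hat$s, ref$s, tolerance = 1e-10)
    }
})

test_that("LOO is exact on noiseless data and correct for intercept-only", {
    gen <- plantedFixture(50, 8, 2, noise = 0, seed = 73)
    res <- looCV(gen$descriptors, gen$activities, gen$truth$signalNames)
    expect_equal(res$r2, 1, tolerance = 1e-10)
    expect_equal(res$s, 0, tolerance = 1e-8)
    # intercept-only: each LOO prediction is the mean of the others
    y <- rnorm(12)
    X <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "x"))
    res0 <- looCV(X, y, character(0))
    manual <- vapply(seq_along(y), function(i) mean(y[-i]), numeric(1))
    expect_equal(unname(res0$predictions), manual, tolerance = 1e-10)
})

test_that("LOO r2 never exceeds the training R2", {
    # shrinkage property over random fixtures
    set.seed(74)
    for (i in 1:25) {
        n <- sample(30:60, 1)
        X <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("x", 1:4)))
        y <- X %*% rnorm(4) + rnorm(n, 0, runif(1, 0.3, 2))
        fit <- fitOLS(X, drop(y))
        loo <- looCV(X, drop(y))
        expect_lte(loo$r2, fitStats(fit)$r2 + 1e-10)
    }
})

test_that("leave-n%-out pools cases and approaches LOO as pct -> 1/n", {
    gen <- plantedFixture(30, 8, 2, noise = 0.6, seed = 75)
    nms <- gen$truth$signalNames
    # noiseless: perfect external prediction for any pct
    clean <- plantedFixture(30, 8, 2, noise = 0, seed = 75)
    r <- leaveNPctOut(clean$descriptors, clean$activities,
                      clean$truth$signalNames, pct = 0.3, nCases = 100,
                      seed = 1)
    expect_equal(r$r2, 1, tolerance = 1e-9)
    # the left-out block size follows round(pct * n)
    r2 <- leaveNPctOut(gen$descriptors, gen$activities, nms, pct = 0.3,
                       nCases = 100, seed = 1)
    expect_identical(r2$nLeftOut, 9)   # round(0.3 * 30)
    expect_identical(round(0.30 * 265), 80)  # paper-scale block size
    # pct = 1/n reproduces LOO within Monte-Carlo error
    loo <- looCV(gen$descriptors, gen$activities, nms)
    lim <- leaveNPctOut(gen$descriptors, gen$activities, nms,
                        pct = 1 / 30 + 1e-9, nCases = 4000, seed = 2)
    expect_identical(lim$nLeftOut, 1)
    expect_lt(abs(lim$r2 - loo$r2), 0.02)
    expect_error(leaveNPctOut(gen$descriptors, gen$activities, nms,
                              pct = 0.6, nCases = 100), "pct")
})

test_that("Y-randomization separates signal from chance correlation", {
    gen <- plantedFixture(120, 15, 4, noise = 0.4, seed = 76)
    nms <- gen$truth$signalNames
    yr <- yRandomization(gen$descriptors, gen$activities, nms,
                         nPermutations = 500, seed = 3)
    expect_gt(yr$sRand / yr$sTrain, 1.5)
    expect_true(yr$pass)
    # scrambled-refit means match a naive per-permutation loop
    X <- descriptorValues(gen$descriptors)[, nms]
    y <- unname(logIC50(gen$activities))
    set.seed(99)
    naive <- replicate(200, {
        yp <- sample(y)
        f <- stats::.lm.fit(cbind(1, X), yp)
        sqrt(sum(f$residuals^2) / (length(y) - length(nms) - 1))
    })
    expect_lt(abs(mean(naive) - yr$sRand), 0.05)
})

test_that("pure-noise responses give sRand close to sTrain", {
    set.seed(77)
    X <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- rnorm(200)
    yr <- yRandomization(X, y, nPermutations = 1000, seed = 5)
    expect_gt(yr$sRand / yr$sTrain, 0.95)
    expect_lt(yr$sRand / yr$sTrain, 1.05)
})

test_that("Golbraikh-Tropsha block behaves at its fixed points", {
    set.seed(78)
    y <- rnorm(50, 3, 1)
    gt <- golbraikhTropsha(y, y)
    expect_equal(gt$k, 1); expect_equal(gt$kPrime, 1)
    expect_equal(gt$r02, 1); expect_equal(gt$rm2, 1)
    expect_true(gt$passAll)
    # doubling the predictions breaks the slope window
    gt2 <- golbraikhTropsha(y, 2 * y)
    expect_equal(gt2$k, 2 * sum(y * y) / sum(y^2))
    expect_false((gt2$k >= 0.85 && gt2$k <= 1.15))
    # swap symmetry: (k, r02) of (obs, pred) are (k', r02') of (pred, obs)
    p <- y + rnorm(50, 0, 0.4)
    a <- golbraikhTropsha(y, p)
    b <- golbraikhTropsha(p, y)
    expect_equal(a$k, b$kPrime, tolerance = 1e-12)
    expect_equal(a$r02, b$r02prime, tolerance = 1e-12)
    expect_equal(a$rm2 >= 0, TRUE)
    # degenerate variance flagged undefined
    expect_false(golbraikhTropsha(rep(1, 5), rnorm(5))$defined)
})

test_that("outlier counting applies the 3*Strain rule", {
    res <- c(a = 0, b = 0, c = 0)
    expect_identical(countOutliers(res, 1)$count, 0L)
    res2 <- c(a = 0.1, b = 3.01, c = -0.2)
    out <- countOutliers(res2, 1)
    expect_identical(out$count, 1L)
    expect_identical(out$ids, "b")
    expect_error(countOutliers(res2, 0), "positive")
    # Gaussian residuals at n = 265: expected count ~ 265 * 0.0027
    counts <- vapply(1:50, function(seed) {
        set.seed(seed)
        e <- rnorm(265)
        countOutliers(e, 1)$count
    }, integer(1))
    expect_gt(mean(counts), 0.3)
    expect_lt(mean(counts), 1.3)
})
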