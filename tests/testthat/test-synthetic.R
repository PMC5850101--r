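test_that("identical seeds give bit-identical datasets", {
    spec <- syntheticSpec(nCompounds = 60, nDescriptors = 80, nSignal = 3,
                          noiseSd = 0.4, seed = 99)
    a <- generateSynthetic(spec)
    b <- generateSynthetic(spec)
    expect_identical(descriptorValues(a$descriptors),
                     descriptorValues(b$descriptors))
    expect_identical(logIC50(a$activities), logIC50(b$activities))
    expect_identical(a$truth, b$truth)
    c <- generateSynthetic(syntheticSpec(nCompounds = 60, nDescriptors = 80,
                                         nSignal = 3, noiseSd = 0.4,
                                         seed = 100))
    expect_false(identical(logIC50(a$activities), logIC50(c$activities)))
})

test_that("noiseless planted model fits exactly (R2 = 1, S = 0)", {
    gen <- plantedFixture(100, 50, 3, noise = 0, seed = 5)
    fit <- fitOLS(gen$descriptors, gen$activities, gen$truth$signalNames)
    st <- fitStats(fit)
    expect_equal(st$r2, 1, tolerance = 1e-12)
    expect_equal(st$s, 0, tolerance = 1e-9)
    expect_equal(max(abs(st$residuals)), 0, tolerance = 1e-9)
    # the fitted coefficients equal the recorded effective truth
    expect_equal(modelCoefficients(fit)[gen$truth$signalNames],
                 gen$truth$beta, tolerance = 1e-8)
    expect_equal(modelIntercept(fit), gen$truth$beta0, tolerance = 1e-8)
})

test_that("nuisance columns have their declared structure", {
    spec <- syntheticSpec(nCompounds = 200, nDescriptors = 100, nSignal = 2,
                          noiseSd = 0.3, collinearBlockCount = 1,
                          collinearBlockSize = 2, fracConstant = 0.05,
                          fracNearConstant = 0.05, fracMissingCols = 0.03,
                          seed = 12)
    gen <- generateSynthetic(spec)
    v <- descriptorValues(gen$descriptors)
    tr <- gen$truth
    # duplicated pair: exact |r| = 1
    blk <- tr$collinearBlocks[[1]]
    expect_equal(abs(cor(v[, blk[1]], v[, blk[2]])), 1, tolerance = 1e-12)
    # constant columns carry a single value
    for (nm in tr$constantNames)
        expect_identical(length(unique(v[, nm])), 1L)
    # near-constant: modal frequency > 95%, but not constant
    for (nm in tr$nearConstantNames) {
        freq <- max(table(v[, nm])) / nrow(v)
        expect_gt(freq, 0.95)
        expect_lt(freq, 1)
    }
    # missing columns contain at least one NA
    for (nm in tr$missingNames)
        expect_gt(sum(is.na(v[, nm])), 0)
    expect_identical(length(tr$constantNames), 5L)
    expect_identical(length(tr$missingNames), 3L)
})

test_that("clean activities lie inside the requested range", {
    rng <- c(log10(0.8), log10(145000))
    for (seed in 1:5) {
        gen <- generateSynthetic(syntheticSpec(
            nCompounds = 150, nDescriptors = 60, nSignal = 8, noiseSd = 0.8,
            activityRange = rng, seed = seed))
        expect_true(all(gen$truth$yClean >= rng[1] - 1e-9))
        expect_true(all(gen$truth$yClean <= rng[2] + 1e-9))
    }
})

test_that("refit on the truth columns recovers the noise level", {
    # oracle: the generating equation; residual SD must estimate noiseSd
    s <- vapply(1:50, function(seed) {
        gen <- plantedFixture(265, 10, 8, noise = 0.8, seed = seed)
        fitStats(fitOLS(gen$descriptors, gen$activities,
                        gen$truth$signalNames))$s
    }, numeric(1))
    expect_lt(abs(mean(s) - 0.8), 0.05)
})

test_that("noiseless signal is the unique exhaustive-search optimum", {
    gen <- plantedFixture(80, 20, 3, noise = 0, seed = 31)
    v <- descriptorValues(gen$descriptors)
    y <- unname(logIC50(gen$activities))
    best <- exhaustiveBestSubset(v, y, 3)
    expect_setequal(colnames(v)[best$subset], gen$truth$signalNames)
    expect_equal(best$s, 0, tolerance = 1e-8)
})

test_that("infeasible specs are rejected with a message", {
    expect_error(syntheticSpec(nDescriptors = 5, nSignal = 8), "nSignal")
    expect_error(syntheticSpec(nCompounds = 50, nDescriptors = 20,
                               nSignal = 5, collinearBlockCount = 10,
                               collinearBlockSize = 3), "infeasible")
    expect_error(syntheticSpec(fracConstant = 0.6, fracNearConstant = 0.6),
                 "jointly")
    expect_error(syntheticSpec(noiseSd = -1), "noiseSd")
})

test_that("truth files serialize as key-value text", {
    gen <- plantedFixture(30, 8, 2, seed = 3)
    f <- tempfile(fileext = ".txt")
    writeTruth(gen$truth, f)
    lines <- readLines(f)
    expect_true(any(grepl("^signal_names = ", lines)))
    expect_true(any(grepl("^noise_sd = ", lines)))
})
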