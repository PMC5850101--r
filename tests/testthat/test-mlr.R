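test_that("exact linear data gives a perfect fit", {
    set.seed(51)
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    y <- 1.5 - 2 * X[, "a"] + 0.7 * X[, "b"]
    fit <- fitOLS(X, y)
    st <- fitStats(fit)
    expect_equal(st$r2, 1, tolerance = 1e-12)
    expect_equal(st$s, 0, tolerance = 1e-10)
    expect_equal(unname(modelCoefficients(fit)), c(-2, 0.7),
                 tolerance = 1e-10)
    expect_equal(modelIntercept(fit), 1.5, tolerance = 1e-10)
})

test_that("the intercept-only model predicts the mean with R2 = 0", {
    set.seed(52)
    X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "z"))
    y <- rnorm(30)
    fit <- fitOLS(X, y, descriptors = character(0))
    expect_equal(fitStats(fit)$r2, 0)
    expect_equal(modelIntercept(fit), mean(y))
    expect_equal(unname(predict(fit, X)), rep(mean(y), 30))
})

test_that("hat-matrix identities hold and stats match lm", {
    gen <- plantedFixture(60, 12, 4, noise = 0.5, seed = 6)
    nms <- gen$truth$signalNames
    fit <- fitOLS(gen$descriptors, gen$activities, nms)
    st <- fitStats(fit)
    expect_equal(sum(st$leverages), length(nms) + 1, tolerance = 1e-8)
    expect_true(all(st$leverages >= 1 / st$n - 1e-12))
    expect_true(all(st$leverages <= 1 + 1e-12))
    # residuals orthogonal to every design column
    X <- descriptorValues(gen$descriptors)[, nms]
    expect_lt(max(abs(crossprod(scale(X), st$residuals))), 1e-6)
    # independent oracle: lm() on the same data
    df <- data.frame(y = unname(logIC50(gen$activities)), X)
    ref <- lm(y ~ ., data = df)
    expect_equal(unname(modelCoefficients(fit)), unname(coef(ref)[-1]),
                 tolerance = 1e-9)
    expect_equal(st$s, summary(ref)$sigma, tolerance = 1e-9)
    expect_equal(st$r2, summary(ref)$r.squared, tolerance = 1e-9)
    expect_equal(unname(st$seCoefficients),
                 unname(summary(ref)$coefficients[-1, 2]), tolerance = 1e-9)
})

test_that("rank deficiency is rejected naming the offending column", {
    set.seed(53)
    x <- rnorm(20)
    X <- cbind(a = x, b = 2 * x, c = rnorm(20))
    expect_error(fitOLS(X, rnorm(20)), "rank-deficient.*b")
})

test_that("prediction matches fitted values and is name-based", {
    gen <- plantedFixture(40, 8, 2, noise = 0.3, seed = 14)
    nms <- gen$truth$signalNames
    fit <- fitOLS(gen$descriptors, gen$activities, nms)
    y <- unname(logIC50(gen$activities))
    pred <- predict(fit, gen$descriptors)
    expect_equal(unname(pred), y - unname(fitStats(fit)$residuals),
                 tolerance = 1e-10)
    # column order must not matter
    v <- descriptorValues(gen$descriptors)
    shuffled <- v[, rev(colnames(v))]
    expect_equal(predict(fit, shuffled), pred)
    expect_error(predict(fit, v[, setdiff(colnames(v), nms[1])]),
                 "missing from newdata")
    # an all-zero descriptor row predicts the intercept
    zero <- matrix(0, 1, length(nms), dimnames = list("z", nms))
    expect_equal(unname(predict(fit, zero)), modelIntercept(fit))
})

test_that("a published-style equation predicts its intercept at zero", {
    # eight fingerprint/E-state terms all zero -> prediction is the
    # intercept of the equation (4.37 log10 nM)
    eq <- new("QSARLinearModel",
              descriptorNames = c("mindssC", "maxHCsats", "M66", "PC494",
                                  "PC534", "PC686", "KR3577", "KR4268"),
              coefficients = c(mindssC = 0.46, maxHCsats = -0.85,
                               M66 = 0.88, PC494 = -0.54, PC534 = -2.76,
                               PC686 = -1.12, KR3577 = 2.68,
                               KR4268 = -1.44),
              intercept = 4.37, r2Train = 0.69, sTrain = 0.80,
              nTrain = 265L, residuals = numeric(0), leverages = numeric(0),
              seCoefficients = numeric(8), seIntercept = 0)
    zeros <- matrix(0, 1, 8, dimnames = list("q", descriptorNames(eq)))
    expect_equal(unname(predict(eq, zeros)), 4.37)
})

test_that("subset statistics follow the stated conventions", {
    set.seed(54)
    y <- rnorm(25); d <- 3
    expect_equal(subsetStats(y, y, d)$r2, 1)
    expect_equal(subsetStats(y, y, d)$s, 0)
    # constant shift: r2 stays 1, s has the closed form sqrt(n/(n-d-1))
    sh <- subsetStats(y, y + 1, d)
    expect_equal(sh$r2, 1, tolerance = 1e-12)
    expect_equal(sh$s, sqrt(25 / (25 - d - 1)), tolerance = 1e-12)
    # training-set consistency: subsetStats reproduces the fit's R2 and S
    gen <- plantedFixture(50, 10, 3, noise = 0.4, seed = 55)
    fit <- fitOLS(gen$descriptors, gen$activities, gen$truth$signalNames)
    pred <- predict(fit, gen$descriptors)
    st <- subsetStats(unname(logIC50(gen$activities)), unname(pred), 3)
    expect_equal(st$r2, fitStats(fit)$r2, tolerance = 1e-10)
    expect_equal(st$s, fitStats(fit)$s, tolerance = 1e-10)
    # degenerate variance flagged
    expect_warning(res <- subsetStats(rep(1, 5), rnorm(5), 1), "zero variance")
    expect_true(res$degenerate)
})

test_that("random predictions have near-zero r2", {
    set.seed(56)
    st <- subsetStats(rnorm(1000), rnorm(1000), 3)
    expect_lt(st$r2, 0.02)
})

test_that("VIF follows the partial-R2 closed forms", {
    set.seed(57)
    n <- 200
    # two exactly orthogonal, mean-zero columns (orthogonal to the intercept)
    q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
    colnames(q) <- c("u", "v")
    res <- vifAndCorr(q)
    expect_equal(unname(res$vif), c(1, 1), tolerance = 1e-10)
    # exact pairwise correlation 0.5 among three columns -> VIF = 1.5 each
    R <- matrix(0.5, 3, 3); diag(R) <- 1
    q3 <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
    X <- q3 %*% chol(R)
    colnames(X) <- c("a", "b", "c")
    res3 <- vifAndCorr(X)
    expect_equal(unname(res3$vif), rep(1.5, 3), tolerance = 1e-8)
    expect_equal(res3$r2Max, 0.25, tolerance = 1e-8)
    # brute-force oracle for one column
    r2a <- summary(lm(X[, "a"] ~ X[, "b"] + X[, "c"]))$r.squared
    expect_equal(res3$vif[["a"]], 1 / (1 - r2a), tolerance = 1e-8)
    # duplicated column -> infinite VIF, flagged
    dup <- cbind(X, d = X[, "a"])
    resd <- vifAndCorr(dup)
    expect_true(resd$collinear)
    expect_true(is.infinite(resd$vifMax))
})

test_that("model serialization writes equation and table", {
    gen <- plantedFixture(40, 6, 2, noise = 0.2, seed = 58)
    fit <- fitOLS(gen$descriptors, gen$activities, gen$truth$signalNames)
    f1 <- tempfile(); f2 <- tempfile(fileext = ".csv")
    writeModelEquation(fit, f1)
    expect_true(any(grepl("^log10IC50 = ", readLines(f1))))
    writeModelTable(fit, f2)
    tab <- read.csv(f2)
    expect_identical(nrow(tab), 3L)
    expect_equal(tab$coefficient[1], modelIntercept(fit))
})
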