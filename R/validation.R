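## Internal and external validation battery for a fixed descriptor subset:
## leave-one-out and leave-n%-out cross-validation, Y-randomization,
## Golbraikh-Tropsha external criteria, and the o3 outlier count. The
## descriptor selection is NOT repeated inside the folds: the battery
## validates the final subset, as is conventional for this workflow.

#' Leave-one-out cross-validation
#'
#' Each training compound is predicted by the model refit on the remaining
#' n - 1. The default computes the LOO predictions through the hat-matrix
#' identity \code{e_i/(1 - h_i)}; \code{method = "refit"} performs the n
#' explicit refits (identical within numerical precision; kept as the
#' oracle).
#'
#' @param x descriptor source (matrix or \linkS4class{DescriptorMatrix}).
#' @param y response (\linkS4class{ActivitySet} or numeric).
#' @param descriptors model columns.
#' @param method \code{"hat"} (default) or \code{"refit"}.
#' @return List with \code{r2} (squared Pearson correlation of observed
#'   and LOO-predicted), \code{s} (\code{sqrt(PRESS/(n - d - 1))}),
#'   \code{predictions}.
#' @export
looCV <- function(x, y, descriptors = NULL, method = c("hat", "refit")) {
    method <- match.arg(method)
    xy <- .xyMatrix(x, y, descriptors)
    X <- xy$X; yv <- xy$y
    n <- nrow(X); d <- ncol(X)
    if (n <= d + 2L) stop("need n > d + 2 for leave-one-out")
    if (method == "hat") {
        fit <- fitOLS(X, yv)
        st <- fitStats(fit)
        h <- st$leverages
        if (any(1 - h < 1e-10)) stop("leverage ~ 1: LOO undefined")
        pred <- yv - st$residuals / (1 - h)
    } else {
        pred <- vapply(seq_len(n), function(i) {
            fit <- fitOLS(X[-i, , drop = FALSE], yv[-i])
            unname(predict(fit, X[i, , drop = FALSE]))
        }, numeric(1))
        names(pred) <- names(yv)
    }
    press <- sum((yv - pred)^2)
    list(r2 = stats::cor(yv, pred)^2,
         s = sqrt(press / (n - d - 1L)),
         predictions = pred)
}

#' Leave-n%-out cross-validation
#'
#' \code{nCases} random draws each leave out \code{round(pct * n)}
#' compounds; the model is refit on the remainder and the left-out block is
#' predicted. All (observed, predicted) pairs are pooled across cases, then
#' r-squared (squared Pearson) and S (denominator: pooled count minus
#' d + 1) are computed as in leave-one-out.
#'
#' @inheritParams looCV
#' @param pct fraction left out per case, in (0, 0.5).
#' @param nCases number of random cases (>= 100).
#' @param seed integer seed.
#' @return List with \code{r2}, \code{s}, \code{nLeftOut}, \code{nCases},
#'   \code{pct}.
#' @export
leaveNPctOut <- function(x, y, descriptors = NULL, pct = 0.30,
                         nCases = 5000L, seed = 1L) {
    xy <- .xyMatrix(x, y, descriptors)
    X <- xy$X; yv <- xy$y
    n <- nrow(X); d <- ncol(X)
    if (pct <= 0 || pct >= 0.5) stop("'pct' must lie in (0, 0.5)")
    nCases <- .checkScalarCount(nCases, "nCases", 100L)
    m <- max(1L, round(pct * n))
    if (n - m <= d + 1L) stop("remainder smaller than d + 2; reduce pct")
    oldSeed <- .Random.seed_save()
    on.exit(.Random.seed_restore(oldSeed), add = TRUE)
    set.seed(seed)
    Xaug <- cbind(1, X)
    obs <- numeric(nCases * m); prd <- numeric(nCases * m)
    for (case in seq_len(nCases)) {
        out <- sample.int(n, m)
        cf <- stats::.lm.fit(Xaug[-out, , drop = FALSE], yv[-out])$coefficients
        at <- (case - 1L) * m + seq_len(m)
        obs[at] <- yv[out]
        prd[at] <- drop(Xaug[out, , drop = FALSE] %*% cf)
    }
    list(r2 = stats::cor(obs, prd)^2,
         s = sqrt(sum((obs - prd)^2) / (length(obs) - d - 1L)),
         nLeftOut = m, nCases = nCases, pct = pct)
}

#' Y-randomization
#'
#' Scrambles the response, refits the same descriptor subset, and records
#' R2 and S per permutation; reports the means. A valid structure-activity
#' relationship shows \code{sRand} clearly above the unscrambled Strain
#' (pass flag).
#'
#' @inheritParams looCV
#' @param nPermutations number of scrambles (>= 100).
#' @param seed integer seed.
#' @return List with \code{r2Rand}, \code{sRand} (means over
#'   permutations), \code{sTrain}, \code{nPermutations}, \code{pass}
#'   (\code{sRand > sTrain}).
#' @export
yRandomization <- function(x, y, descriptors = NULL, nPermutations = 2000L,
                           seed = 1L) {
    xy <- .xyMatrix(x, y, descriptors)
    X <- xy$X; yv <- xy$y
    n <- nrow(X); d <- ncol(X)
    nPermutations <- .checkScalarCount(nPermutations, "nPermutations", 1L)
    qrX <- .qrDesign(X)
    Q <- qr.Q(qrX)
    tss <- sum((yv - mean(yv))^2)
    rssTrain <- sum(qr.resid(qrX, yv)^2)
    sTrain <- sqrt(rssTrain / (n - d - 1L))
    oldSeed <- .Random.seed_save()
    on.exit(.Random.seed_restore(oldSeed), add = TRUE)
    set.seed(seed)
    perms <- matrix(0, n, nPermutations)
    for (p in seq_len(nPermutations)) {
        repeat {
            pr <- sample.int(n)
            if (n == 1L || !identical(pr, seq_len(n))) break
        }
        perms[, p] <- yv[pr]
    }
    rss <- colSums(perms^2) - colSums(crossprod(Q, perms)^2)
    rss[rss < 0] <- 0
    r2 <- 1 - rss / tss
    s <- sqrt(rss / (n - d - 1L))
    list(r2Rand = mean(r2), sRand = mean(s), sTrain = sTrain,
         nPermutations = nPermutations, pass = mean(s) > sTrain)
}

#' Golbraikh-Tropsha external validation block
#'
#' Through-origin regression slopes and determination coefficients on the
#' external (observed, predicted) pairs: k is the slope of predicted on
#' observed through the origin, k' the converse; R0^2 (resp. R0'^2) is the
#' coefficient of determination of the corresponding through-origin line on
#' its own axes; \code{rm2 = r2 * (1 - sqrt(r2 - r02))}. Pass thresholds:
#' \code{1 - r02/r2 < 0.1} (or the primed variant), slope within
#' [0.85, 1.15] (either k or k'), and \code{rm2 > 0.5}.
#'
#' @param yObs,yPred numeric vectors (n >= 3, nonzero variances).
#' @return List with \code{r2, r02, r02prime, k, kPrime, rm2} and pass
#'   flags \code{passR0, passSlope, passRm2, passAll}; \code{defined} is
#'   \code{FALSE} (all statistics \code{NA}) on degenerate variance.
#' @export
golbraikhTropsha <- function(yObs, yPred) {
    yObs <- as.numeric(yObs); yPred <- as.numeric(yPred)
    n <- length(yObs)
    if (length(yPred) != n || n < 3L) stop("need matched vectors, n >= 3")
    if (stats::var(yObs) == 0 || stats::var(yPred) == 0)
        return(list(r2 = NA_real_, r02 = NA_real_, r02prime = NA_real_,
                    k = NA_real_, kPrime = NA_real_, rm2 = NA_real_,
                    passR0 = NA, passSlope = NA, passRm2 = NA,
                    passAll = NA, defined = FALSE))
    r2 <- stats::cor(yObs, yPred)^2
    k <- sum(yObs * yPred) / sum(yObs^2)
    kPrime <- sum(yObs * yPred) / sum(yPred^2)
    r02 <- 1 - sum((yPred - k * yObs)^2) / sum((yPred - mean(yPred))^2)
    r02prime <- 1 - sum((yObs - kPrime * yPred)^2) /
        sum((yObs - mean(yObs))^2)
    rm2 <- r2 * (1 - sqrt(max(r2 - r02, 0)))
    passR0 <- (1 - r02 / r2 < 0.1) || (1 - r02prime / r2 < 0.1)
    passSlope <- (k >= 0.85 && k <= 1.15) || (kPrime >= 0.85 && kPrime <= 1.15)
    passRm2 <- rm2 > 0.5
    list(r2 = r2, r02 = r02, r02prime = r02prime, k = k, kPrime = kPrime,
         rm2 = rm2, passR0 = passR0, passSlope = passSlope,
         passRm2 = passRm2, passAll = passR0 && passSlope && passRm2,
         defined = TRUE)
}

#' Count training-set outliers (o3)
#'
#' Compounds whose absolute training residual exceeds 3 times Strain.
#'
#' @param residuals named numeric vector of training residuals.
#' @param sTrain training standard deviation (> 0).
#' @return List with \code{count} and \code{ids}.
#' @export
countOutliers <- function(residuals, sTrain) {
    if (!is.numeric(sTrain) || length(sTrain) != 1L || sTrain <= 0)
        stop("'sTrain' must be a positive scalar")
    out <- which(abs(residuals) > 3 * sTrain)
    list(count = length(out),
         ids = names(residuals)[out] %||% as.character(out))
}
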