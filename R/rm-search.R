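## Replacement-method (RM) descriptor subset search. From a random
## d-subset, repeatedly replace the descriptor whose coefficient has the
## largest relative error |SE/beta| by the pool candidate minimising the
## training standard deviation Strain, until a full sweep over all d
## positions accepts no replacement. Multiple random starts; the best model
## over all starts is returned. The search approaches the quality of the
## exact combinatorial full search at a fraction of its cost.

# Candidate RSS for replacing one column: given the QR of the fixed design
# (intercept + the other d-1 columns) and the candidate block Z, the RSS of
# each augmented fit follows from one projection:
#   RSS(z) = RSS_fixed - (w'e)^2 / (w'w),  w = z - QQ'z,  e = y - QQ'y.
# Candidates that would make the design numerically rank-deficient get +Inf
# (skipped silently). Correctness is pinned to the naive per-candidate
# refit by a regression test.
.candidateRSS <- function(qrFixed, y, Z) {
    Q <- qr.Q(qrFixed)
    e <- y - drop(Q %*% crossprod(Q, y))
    rssFixed <- sum(e^2)
    W <- Z - Q %*% crossprod(Q, Z)
    den <- colSums(W^2)
    num <- drop(crossprod(W, e))^2
    rss <- rssFixed - num / den
    degen <- den <= pmax(colSums(Z^2), 1) * 1e-10
    rss[degen] <- Inf
    rss[rss < 0] <- 0
    list(rss = rss, rssFixed = rssFixed)
}

# One fit of a subset: coefficients, SEs and RSS, cheap path used inside
# the sweeps.
.subsetFit <- function(X, y, subset) {
    Xs <- X[, subset, drop = FALSE]
    qrX <- qr(cbind(1, Xs))
    if (qrX$rank < length(subset) + 1L) return(NULL)
    cf <- qr.coef(qrX, y)
    res <- qr.resid(qrX, y)
    rss <- sum(res^2)
    n <- length(y); d <- length(subset)
    s2 <- rss / (n - d - 1L)
    R <- qr.R(qrX)
    diagv <- numeric(length(qrX$pivot))
    diagv[qrX$pivot] <- diag(chol2inv(R))
    se <- sqrt(s2 * diagv)
    list(coef = cf[-1L], se = se[-1L], rss = rss, s = sqrt(s2))
}

#' Replacement-method descriptor selection
#'
#' Searches a prefiltered descriptor pool for the d-subset minimising the
#' training standard deviation Strain of the multivariable linear
#' regression. Each random start is refined by sweeps: positions are ranked
#' by decreasing relative coefficient error |SE(b_k)/b_k|; the worst-ranked
#' position not yet visited this sweep is offered every out-of-subset pool
#' descriptor as a replacement, and the candidate giving the smallest
#' Strain is accepted if it strictly improves on the incumbent (ties broken
#' by lower pool index). Convergence: a full sweep over all d positions
#' with no accepted replacement. Deterministic given \code{seed}.
#'
#' @param x prefiltered \linkS4class{DescriptorMatrix} or numeric matrix
#'   (no missing values, no exact collinearity).
#' @param y \linkS4class{ActivitySet} or numeric response.
#' @param d subset size (1 <= d <= pool size; d = pool size returns the
#'   full-pool model).
#' @param nStarts number of random starts (default 30).
#' @param maxSweeps sweep cap per start (default 25).
#' @param seed integer seed.
#' @param initialSubsets optional list of character/integer subsets used as
#'   additional (warm) starts before the random ones.
#' @return List with \code{model} (\linkS4class{QSARLinearModel} refit on
#'   the best subset) and \code{trace}, a list with one entry per start
#'   (\code{startIndex}, per-sweep best \code{strain}, \code{replacements},
#'   \code{converged}) plus \code{bestStart}.
#' @seealso [modelLadder()]
#' @export
rmSelect <- function(x, y, d, nStarts = 30L, maxSweeps = 25L, seed = 1L,
                     initialSubsets = NULL) {
    xy <- .xyMatrix(x, y)
    X <- xy$X; yv <- xy$y
    if (anyNA(X)) stop("missing values in pool; prefilter first")
    n <- nrow(X); D <- ncol(X)
    d <- .checkScalarCount(d, "d", 1L)
    if (d > D) stop("pool smaller than d (D = ", D, ", d = ", d, ")")
    if (n <= d + 1L) stop("need n > d + 1")
    nStarts <- .checkScalarCount(nStarts, "nStarts", if (d == D) 0L else 1L)
    maxSweeps <- .checkScalarCount(maxSweeps, "maxSweeps", 1L)

    oldSeed <- .Random.seed_save()
    on.exit(.Random.seed_restore(oldSeed), add = TRUE)
    set.seed(seed)

    starts <- list()
    for (ini in initialSubsets) {
        sub <- if (is.character(ini)) match(ini, colnames(X)) else as.integer(ini)
        if (anyNA(sub) || length(sub) != d)
            stop("each initial subset must name d pool columns")
        starts[[length(starts) + 1L]] <- sort(sub)
    }
    if (d == D) {
        starts <- list(seq_len(D))
    } else {
        for (s in seq_len(nStarts)) {
            for (try in 1:100) {
                sub <- sort(sample.int(D, d))
                if (!is.null(.subsetFit(X, yv, sub))) break
                if (try == 100)
                    stop("could not draw a full-rank random start")
            }
            starts[[length(starts) + 1L]] <- sub
        }
    }

    denom <- n - d - 1L
    bestRSS <- Inf; bestSubset <- NULL; bestStart <- NA_integer_
    traces <- vector("list", length(starts))

    for (si in seq_along(starts)) {
        subset <- starts[[si]]
        fit <- .subsetFit(X, yv, subset)
        if (is.null(fit)) { # rank-deficient warm start: skip
            traces[[si]] <- list(startIndex = si, strain = numeric(0),
                                 replacements = 0L, converged = FALSE)
            next
        }
        sweepStrain <- numeric(0)
        nRepl <- 0L
        converged <- FALSE
        for (sw in seq_len(maxSweeps)) {
            frozen <- rep(FALSE, d)
            changed <- FALSE
            while (any(!frozen)) {
                relErr <- abs(fit$se / fit$coef)
                relErr[!is.finite(relErr)] <- Inf
                open <- which(!frozen)
                j <- open[which.max(relErr[open])]
                outside <- setdiff(seq_len(D), subset)
                fixed <- cbind(1, X[, subset[-j], drop = FALSE])
                qrFixed <- qr(fixed)
                cand <- .candidateRSS(qrFixed, yv,
                                      X[, outside, drop = FALSE])
                # incumbent evaluated through the same projection for a
                # like-for-like comparison
                incRSS <- .candidateRSS(qrFixed, yv,
                                        X[, subset[j], drop = FALSE])$rss
                bi <- which.min(cand$rss)      # first min = lowest pool index
                if (length(bi) && is.finite(cand$rss[bi]) &&
                    cand$rss[bi] < incRSS * (1 - 1e-12)) {
                    subset[j] <- outside[bi]
                    nRepl <- nRepl + 1L
                    changed <- TRUE
                    fit <- .subsetFit(X, yv, subset)
                }
                frozen[j] <- TRUE
            }
            sweepStrain <- c(sweepStrain, sqrt(fit$rss / denom))
            if (!changed) { converged <- TRUE; break }
        }
        traces[[si]] <- list(startIndex = si, strain = sweepStrain,
                             replacements = nRepl, converged = converged)
        if (fit$rss < bestRSS) {
            bestRSS <- fit$rss; bestSubset <- subset; bestStart <- si
        }
    }
    if (is.null(bestSubset)) stop("no usable start found")
    model <- fitOLS(X, yv, colnames(X)[sort(bestSubset)])
    list(model = model,
         trace = list(starts = traces, bestStart = bestStart))
}

# Greedy forward extension of a subset by the best single additions; used
# to warm-start the next ladder size from the previous optimum.
.extendSubset <- function(X, y, subset, by) {
    for (i in seq_len(by)) {
        outside <- setdiff(seq_len(ncol(X)), subset)
        qrFixed <- qr(cbind(1, X[, subset, drop = FALSE]))
        cand <- .candidateRSS(qrFixed, y, X[, outside, drop = FALSE])
        subset <- c(subset, outside[which.min(cand$rss)])
    }
    sort(subset)
}

#' Model ladder: best RM model per subset size
#'
#' Runs \code{\link{rmSelect}} on the training subset for every size in
#' \code{dRange} and tabulates, per size, the selected descriptors and
#' R2/S on train, validation and (when present) test subsets. The selected
#' model is the smallest d whose validation S is within \code{selectTol} of
#' the ladder's minimum — keeping the model dimension as small as possible.
#'
#' @param x prefiltered \linkS4class{DescriptorMatrix} covering all
#'   compounds of the partition.
#' @param act \linkS4class{ActivitySet}.
#' @param partition \linkS4class{SubsetPartition} defining train/val/test.
#' @param dRange integer vector of subset sizes (default 1:9).
#' @param nStarts,maxSweeps,seed passed to \code{\link{rmSelect}}.
#' @param warmStart also start each size from the previous size's optimum
#'   extended by the best single addition (default TRUE); this enforces a
#'   monotone non-increasing Strain ladder.
#' @param selectTol tolerance on validation S for the size selection
#'   (default 0.01).
#' @return List with \code{table} (one row per d), \code{models} (by d),
#'   \code{selectedD} and \code{selectedModel}.
#' @export
modelLadder <- function(x, act, partition, dRange = 1:9, nStarts = 10L,
                        maxSweeps = 25L, seed = 1L, warmStart = TRUE,
                        selectTol = 0.01) {
    dRange <- sort(unique(as.integer(dRange)))
    if (any(dRange < 1L)) stop("dRange must be >= 1")
    m <- descriptorValues(x)
    yAll <- logIC50(act)
    lab <- partitionLabels(partition)
    idx <- function(s) names(lab)[lab == s]
    trainIds <- idx("train"); valIds <- idx("val"); testIds <- idx("test")
    if (!all(c(trainIds, valIds, testIds) %in% rownames(m)))
        stop("partition ids missing from the descriptor matrix")
    Xtr <- m[trainIds, , drop = FALSE]; ytr <- as.numeric(yAll[trainIds])

    models <- list(); rows <- list()
    prevSubset <- NULL
    for (d in dRange) {
        init <- NULL
        if (warmStart && !is.null(prevSubset) && d > length(prevSubset))
            init <- list(.extendSubset(Xtr, ytr, prevSubset,
                                       d - length(prevSubset)))
        sel <- rmSelect(Xtr, ytr, d, nStarts = nStarts,
                        maxSweeps = maxSweeps,
                        seed = .stageSeed(seed, "search") + d,
                        initialSubsets = init)
        mod <- sel$model
        prevSubset <- match(descriptorNames(mod), colnames(Xtr))
        val <- subsetStats(yAll[valIds],
                           predict(mod, m[valIds, , drop = FALSE]), d)
        tst <- if (length(testIds) >= 3L)
            subsetStats(yAll[testIds],
                        predict(mod, m[testIds, , drop = FALSE]), d)
        else list(r2 = NA_real_, s = NA_real_)
        models[[as.character(d)]] <- mod
        rows[[as.character(d)]] <- data.frame(
            d = d, descriptors = paste(descriptorNames(mod), collapse = ";"),
            r2Train = mod@r2Train, sTrain = mod@sTrain,
            r2Val = val$r2, sVal = val$s, r2Test = tst$r2, sTest = tst$s)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    selD <- tab$d[which(tab$sVal <= min(tab$sVal) + selectTol)[1L]]
    tab$selected <- tab$d == selD
    list(table = tab, models = models, selectedD = selD,
         selectedModel = models[[as.character(selD)]])
}
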