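## Synthetic descriptor-pool generator. Emulates the statistical structure of
## a kinase-inhibitor QSAR table: a large pool of mostly irrelevant
## descriptors (continuous E-state-like columns and binary fingerprint-like
## columns), nuisance columns (constant, near-constant, containing missing
## values, collinear blocks), and a planted linear signal on a few columns
## driving log10 IC50 with Gaussian noise.

#' Specification of a synthetic QSAR dataset
#'
#' Collects and validates the parameters of the generator. Defaults emulate
#' a curated kinase-inhibitor dataset: 530 compounds, activities spanning
#' log10 IC50 of 0.8 to 145,000 nM, an 8-descriptor linear signal with
#' residual noise of 0.8 log units, about 60\% binary (fingerprint-like)
#' columns, and small fractions of constant, near-constant and
#' missing-value columns plus a few exactly collinear blocks.
#'
#' @param nCompounds number of compounds N.
#' @param nDescriptors pool size D.
#' @param nSignal number of signal descriptors d carrying the planted model.
#' @param noiseSd Gaussian noise SD added to the clean activity (log10 units).
#' @param collinearBlockCount,collinearBlockSize number and size (parent
#'   plus affine copies) of exactly collinear column blocks.
#' @param fracBinary fraction of plain decoy columns that are binary.
#' @param fracConstant,fracNearConstant,fracMissingCols fractions of the pool
#'   made constant, near-constant (modal value in more than 95\% of rows),
#'   or containing at least one missing entry.
#' @param activityRange (min, max) of the clean log10 IC50 in log10 nM.
#' @param seed integer; identical seeds give bit-identical output.
#' @return A validated list of class \code{SyntheticSpec}.
#' @seealso [generateSynthetic()]
#' @export
syntheticSpec <- function(nCompounds = 530, nDescriptors = 2000, nSignal = 8,
                          noiseSd = 0.8, collinearBlockCount = 10,
                          collinearBlockSize = 3, fracBinary = 0.6,
                          fracConstant = 0.02, fracNearConstant = 0.02,
                          fracMissingCols = 0.01,
                          activityRange = c(log10(0.8), log10(145000)),
                          seed = 1L) {
    spec <- list(
        nCompounds = .checkScalarCount(nCompounds, "nCompounds", 2L),
        nDescriptors = .checkScalarCount(nDescriptors, "nDescriptors", 1L),
        nSignal = .checkScalarCount(nSignal, "nSignal", 0L),
        noiseSd = as.numeric(noiseSd),
        collinearBlockCount = .checkScalarCount(collinearBlockCount,
                                                "collinearBlockCount", 0L),
        collinearBlockSize = .checkScalarCount(collinearBlockSize,
                                               "collinearBlockSize", 0L),
        fracBinary = .checkFraction(fracBinary, "fracBinary"),
        fracConstant = .checkFraction(fracConstant, "fracConstant"),
        fracNearConstant = .checkFraction(fracNearConstant, "fracNearConstant"),
        fracMissingCols = .checkFraction(fracMissingCols, "fracMissingCols"),
        activityRange = as.numeric(activityRange),
        seed = .checkScalarCount(seed, "seed", 0L))
    if (spec$noiseSd < 0) stop("'noiseSd' must be >= 0")
    if (length(spec$activityRange) != 2L ||
        spec$activityRange[1] >= spec$activityRange[2])
        stop("'activityRange' must be (min, max) with min < max")
    if (spec$nSignal > spec$nDescriptors)
        stop("infeasible spec: nSignal exceeds nDescriptors")
    if (spec$fracConstant + spec$fracNearConstant + spec$fracMissingCols > 1)
        stop("infeasible spec: column-type fractions jointly exceed 1")
    if (spec$collinearBlockCount > 0 && spec$collinearBlockSize < 2)
        stop("'collinearBlockSize' must be >= 2 when blocks are requested")
    counts <- .syntheticCounts(spec)
    if (counts$nDecoy < 0)
        stop("infeasible spec: signal, collinear, constant, near-constant ",
             "and missing columns together exceed the pool size")
    spec$counts <- counts
    class(spec) <- "SyntheticSpec"
    spec
}

.syntheticCounts <- function(spec) {
    D <- spec$nDescriptors
    nConst <- round(spec$fracConstant * D)
    nNearConst <- round(spec$fracNearConstant * D)
    nMissing <- round(spec$fracMissingCols * D)
    nBlockCols <- spec$collinearBlockCount * spec$collinearBlockSize
    nDecoy <- D - spec$nSignal - nBlockCols - nConst - nNearConst - nMissing
    list(nConst = nConst, nNearConst = nNearConst, nMissing = nMissing,
         nBlockCols = nBlockCols, nDecoy = nDecoy)
}

#' Generate a synthetic descriptor matrix and activity set
#'
#' Draws a compound-by-descriptor pool in which exactly \code{nSignal}
#' columns carry the true linear model \eqn{y = \beta_0 + \sum_k \beta_k x_k
#' + \epsilon}, \eqn{\epsilon \sim N(0, noiseSd)}; all other columns are
#' independent of the response. Signal columns are standard-normal; raw
#' coefficients are drawn uniformly in \eqn{\pm[0.3, 3]}. When the clean
#' activity would overflow \code{activityRange} it is affinely mapped into
#' the range, and the recorded truth carries the effective (post-map)
#' coefficients, so the planted model stays exactly linear. Decoys are
#' i.i.d. standard normal or Bernoulli (per-column prevalence uniform in
#' [0.1, 0.5]); collinear blocks are exact affine copies of a fresh parent
#' column; near-constant columns have their modal value in more than 95\%
#' of rows; missing-value columns contain at least one \code{NA}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return List with \code{descriptors} (\linkS4class{DescriptorMatrix}),
#'   \code{activities} (\linkS4class{ActivitySet}) and \code{truth}, a list
#'   recording \code{beta0}, effective \code{beta} (named), the signal
#'   column names, the nuisance column names
#'   (\code{constantNames}, \code{nearConstantNames}, \code{missingNames},
#'   \code{collinearBlocks}), \code{noiseSd}, the range-map scale
#'   \code{activityScale}, and the clean (pre-noise) activity.
#' @examples
#' gen <- generateSynthetic(syntheticSpec(nCompounds = 50, nDescriptors = 20,
#'                                        nSignal = 2, noiseSd = 0,
#'                                        collinearBlockCount = 0,
#'                                        fracConstant = 0, fracNearConstant = 0,
#'                                        fracMissingCols = 0, seed = 7))
#' gen$truth$signalNames
#' @export
generateSynthetic <- function(spec) {
    if (!inherits(spec, "SyntheticSpec"))
        stop("'spec' must come from syntheticSpec()")
    oldSeed <- .Random.seed_save()
    on.exit(.Random.seed_restore(oldSeed), add = TRUE)
    set.seed(spec$seed)

    N <- spec$nCompounds; D <- spec$nDescriptors; d <- spec$nSignal
    cn <- spec$counts
    cols <- vector("list", D)
    type <- character(D)
    ptr <- 0L

    # signal block
    Xs <- matrix(stats::rnorm(N * d), N, d)
    for (k in seq_len(d)) { ptr <- ptr + 1L; cols[[ptr]] <- Xs[, k]
                            type[ptr] <- "signal" }
    signalIdx <- seq_len(d)

    # collinear blocks: parent + exact affine copies
    blockIdx <- vector("list", spec$collinearBlockCount)
    for (b in seq_len(spec$collinearBlockCount)) {
        parent <- stats::rnorm(N)
        idx <- integer(spec$collinearBlockSize)
        ptr <- ptr + 1L; cols[[ptr]] <- parent; type[ptr] <- "collinear"
        idx[1L] <- ptr
        for (m in seq_len(spec$collinearBlockSize - 1L)) {
            a <- sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 2)
            cshift <- stats::rnorm(1)
            ptr <- ptr + 1L; cols[[ptr]] <- a * parent + cshift
            type[ptr] <- "collinear"; idx[m + 1L] <- ptr
        }
        blockIdx[[b]] <- idx
    }

    # constant columns
    for (k in seq_len(cn$nConst)) {
        ptr <- ptr + 1L; cols[[ptr]] <- rep(stats::rnorm(1), N)
        type[ptr] <- "constant"
    }

    # near-constant: modal value in > 95% of rows, at least one other value
    for (k in seq_len(cn$nNearConst)) {
        nMinor <- max(1L, min(N - 1L, floor(N * stats::runif(1, 0.005, 0.045))))
        v <- rep(0, N)
        v[sample.int(N, nMinor)] <- stats::rnorm(nMinor)
        ptr <- ptr + 1L; cols[[ptr]] <- v; type[ptr] <- "nearconstant"
    }

    # columns with missing entries (at least one NA each)
    for (k in seq_len(cn$nMissing)) {
        v <- stats::rnorm(N)
        nNA <- max(1L, stats::rbinom(1L, N, 0.05))
        v[sample.int(N, nNA)] <- NA_real_
        ptr <- ptr + 1L; cols[[ptr]] <- v; type[ptr] <- "missing"
    }

    # plain decoys: continuous N(0,1) or Bernoulli fingerprints
    nBin <- round(spec$fracBinary * cn$nDecoy)
    isBin <- sample(rep(c(TRUE, FALSE), c(nBin, cn$nDecoy - nBin)))
    for (k in seq_len(cn$nDecoy)) {
        v <- if (isBin[k]) as.numeric(stats::rbinom(N, 1L,
                                                    stats::runif(1, 0.1, 0.5)))
             else stats::rnorm(N)
        ptr <- ptr + 1L; cols[[ptr]] <- v; type[ptr] <- "decoy"
    }

    X <- do.call(cbind, cols)

    # planted model: raw coefficients in +-[0.3, 3]; clean activity affinely
    # mapped into activityRange when it would overflow
    betaRaw <- sample(c(-1, 1), d, replace = TRUE) * stats::runif(d, 0.3, 3)
    yRaw <- if (d > 0) drop(Xs %*% betaRaw) else rep(0, N)
    lo <- spec$activityRange[1]; hi <- spec$activityRange[2]
    mid <- (lo + hi) / 2
    spread <- max(yRaw) - min(yRaw)
    scale <- if (spread > (hi - lo)) (hi - lo) / spread else 1
    rawMid <- (max(yRaw) + min(yRaw)) / 2
    yClean <- mid + scale * (yRaw - rawMid)
    beta <- betaRaw * scale
    beta0 <- mid - scale * rawMid
    y <- yClean + stats::rnorm(N, 0, spec$noiseSd)

    # shuffle columns so structure is not positional, then name
    perm <- sample.int(D)
    X <- X[, perm, drop = FALSE]
    type <- type[perm]
    nameOf <- sprintf("D%05d", seq_len(D))
    pos <- match(seq_len(D), perm)       # original index -> final position
    colnames(X) <- nameOf
    ids <- sprintf("CPD%04d", seq_len(N))
    rownames(X) <- ids

    signalNames <- nameOf[pos[signalIdx]]
    names(beta) <- signalNames
    truth <- list(
        beta0 = beta0, beta = beta, signalNames = signalNames,
        constantNames = nameOf[type == "constant"],
        nearConstantNames = nameOf[type == "nearconstant"],
        missingNames = nameOf[type == "missing"],
        collinearBlocks = lapply(blockIdx, function(ix) nameOf[pos[ix]]),
        noiseSd = spec$noiseSd, activityScale = scale,
        yClean = stats::setNames(yClean, ids))

    list(descriptors = DescriptorMatrix(X),
         activities = ActivitySet(ids, logIC50 = y),
         truth = truth)
}

# save/restore the caller's RNG state so seeded generators are side-effect
# free with respect to the global stream
.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed_restore <- function(saved) {
    if (is.null(saved)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", saved, envir = globalenv())
    invisible(NULL)
}
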