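## Ordinary least-squares core. Every statistic downstream (replacement
## search, validation battery, applicability domain) is defined in terms of
## these fits. Conventions fixed package-wide: the model always carries an
## intercept; the regression standard deviation is
## S = sqrt(RSS / (n - d - 1)) for a d-descriptor model; leverages are the
## hat-matrix diagonal of the intercept-augmented design.

# QR of the intercept-augmented design; errors name the offending columns
# on rank deficiency.
.qrDesign <- function(X, reject = TRUE) {
    Xaug <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(Xaug)
    if (reject && qrX$rank < ncol(Xaug)) {
        bad <- colnames(Xaug)[qrX$pivot[(qrX$rank + 1L):ncol(Xaug)]]
        stop("rank-deficient design; offending column(s): ",
             paste(bad, collapse = ", "))
    }
    qrX
}

#' Fit an ordinary least-squares QSAR model
#'
#' Fits \code{log10IC50 = b0 + sum(b_k x_k)} by QR-based least squares on
#' the selected descriptor columns, and computes the training statistics
#' used throughout the package: R2train, Strain = sqrt(RSS/(n - d - 1)),
#' residuals, hat-matrix leverages, and coefficient standard errors.
#'
#' @param x a \linkS4class{DescriptorMatrix} or numeric matrix (compounds as
#'   rows).
#' @param y an \linkS4class{ActivitySet} (matched to \code{x} by compound
#'   id) or a numeric response vector in row order.
#' @param descriptors character vector naming the model columns; default all
#'   columns of \code{x}. \code{character(0)} fits the intercept-only model.
#' @return A \linkS4class{QSARLinearModel}.
#' @examples
#' gen <- generateSynthetic(syntheticSpec(nCompounds = 60, nDescriptors = 10,
#'                                        nSignal = 2, noiseSd = 0,
#'                                        collinearBlockCount = 0,
#'                                        fracConstant = 0, fracNearConstant = 0,
#'                                        fracMissingCols = 0, seed = 3))
#' fit <- fitOLS(gen$descriptors, gen$activities, gen$truth$signalNames)
#' fitStats(fit)$r2   # 1: noiseless planted model
#' @export
fitOLS <- function(x, y, descriptors = NULL) {
    xy <- .xyMatrix(x, y, descriptors)
    X <- xy$X; yv <- xy$y
    if (anyNA(X))
        stop("missing descriptor values in the fitted columns")
    n <- nrow(X); d <- ncol(X)
    if (n <= d + 1L)
        stop("need n > d + 1 (n = ", n, ", d = ", d, ")")
    qrX <- .qrDesign(X)
    coefAll <- qr.coef(qrX, yv)
    fitted <- drop(qr.fitted(qrX, yv))
    res <- yv - fitted
    rss <- sum(res^2)
    tss <- sum((yv - mean(yv))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    if (d == 0L && tss > 0) r2 <- 0
    s <- sqrt(rss / (n - d - 1L))
    Q <- qr.Q(qrX)
    h <- rowSums(Q^2)
    # (X'X)^-1 diagonal, honouring any pivoting
    R <- qr.R(qrX)
    xtxinv <- chol2inv(R)
    piv <- qrX$pivot
    diagv <- numeric(length(piv)); diagv[piv] <- diag(xtxinv)
    se <- s * sqrt(diagv)
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    new("QSARLinearModel",
        descriptorNames = colnames(X) %||% character(0),
        coefficients = stats::setNames(as.numeric(coefAll[-1L]),
                                       colnames(X)),
        intercept = as.numeric(coefAll[1L]),
        r2Train = r2, sTrain = s, nTrain = as.integer(n),
        residuals = stats::setNames(as.numeric(res), ids),
        leverages = stats::setNames(as.numeric(h), ids),
        seCoefficients = stats::setNames(as.numeric(se[-1L]), colnames(X)),
        seIntercept = as.numeric(se[1L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict activities from a fitted model
#'
#' Applies \code{intercept + sum(coefficient * value)} per compound.
#' Descriptor columns are matched by name, never by position.
#'
#' @param object a \linkS4class{QSARLinearModel}.
#' @param newdata a \linkS4class{DescriptorMatrix}, matrix or data frame
#'   containing (at least) the model's named columns.
#' @param ... ignored.
#' @return Numeric vector of predicted log10 IC50, named by compound id
#'   when available.
#' @export
setMethod("predict", "QSARLinearModel", function(object, newdata, ...) {
    m <- if (is(newdata, "DescriptorMatrix")) descriptorValues(newdata)
         else as.matrix(newdata)
    nms <- object@descriptorNames
    miss <- setdiff(nms, colnames(m))
    if (length(miss))
        stop("descriptor column(s) missing from newdata: ",
             paste(miss, collapse = ", "))
    pred <- rep(object@intercept, nrow(m))
    if (length(nms))
        pred <- pred + drop(m[, nms, drop = FALSE] %*% object@coefficients)
    stats::setNames(as.numeric(pred), rownames(m))
})

#' Prediction statistics for a compound subset
#'
#' R-squared is the squared Pearson correlation between observed and
#' predicted activities (the convention of the external-validation
#' framework used here); S is \code{sqrt(sum((obs - pred)^2)/(n - d - 1))},
#' with d the number of model descriptors.
#'
#' @param yObs,yPred numeric vectors of equal length (n >= 3).
#' @param d model size used in the S denominator.
#' @return List with \code{r2}, \code{s}, \code{n}, and \code{degenerate}
#'   (\code{TRUE} when either vector has zero variance, in which case
#'   \code{r2} is \code{NA}).
#' @export
subsetStats <- function(yObs, yPred, d) {
    yObs <- as.numeric(yObs); yPred <- as.numeric(yPred)
    n <- length(yObs)
    if (length(yPred) != n) stop("observed and predicted lengths differ")
    if (n < 3L) stop("need n >= 3")
    degenerate <- stats::var(yObs) == 0 || stats::var(yPred) == 0
    r2 <- if (degenerate) NA_real_ else stats::cor(yObs, yPred)^2
    if (degenerate) warning("zero variance: r2 undefined")
    s <- sqrt(sum((yObs - yPred)^2) / (n - d - 1))
    list(r2 = r2, s = s, n = n, degenerate = degenerate)
}

#' Variance inflation factors and descriptor correlation matrix
#'
#' \code{VIF_k = 1/(1 - R2_k)} where \code{R2_k} comes from regressing
#' column k on the remaining model columns (with intercept); also the
#' pairwise squared Pearson correlation matrix and its maximum off-diagonal
#' entry. Perfect multicollinearity yields an infinite VIF and a flag.
#'
#' @param x matrix or \linkS4class{DescriptorMatrix} (d >= 2 columns).
#' @param descriptors optional column selection.
#' @return List with \code{vif} (named), \code{pairR2} (matrix),
#'   \code{vifMax}, \code{r2Max}, \code{collinear} flag.
#' @export
vifAndCorr <- function(x, descriptors = NULL) {
    m <- if (is(x, "DescriptorMatrix")) descriptorValues(x) else as.matrix(x)
    if (!is.null(descriptors)) m <- m[, descriptors, drop = FALSE]
    d <- ncol(m)
    if (d < 2L) stop("need at least 2 descriptor columns")
    pairR2 <- stats::cor(m)^2
    vif <- vapply(seq_len(d), function(k) {
        others <- m[, -k, drop = FALSE]
        qrX <- .qrDesign(others, reject = FALSE)
        res <- qr.resid(qrX, m[, k])
        tss <- sum((m[, k] - mean(m[, k]))^2)
        r2k <- if (tss > 0) 1 - sum(res^2) / tss else 1
        if (r2k >= 1 - 1e-10) Inf else 1 / (1 - r2k)
    }, numeric(1))
    names(vif) <- colnames(m)
    off <- pairR2; diag(off) <- NA
    list(vif = vif, pairR2 = pairR2, vifMax = max(vif),
         r2Max = max(off, na.rm = TRUE), collinear = any(is.infinite(vif)))
}

#' Serialize a fitted model
#'
#' \code{writeModelEquation} writes a human-readable equation file;
#' \code{writeModelTable} a machine-readable CSV of terms and coefficients.
#'
#' @param model a \linkS4class{QSARLinearModel}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeModelEquation <- function(model, path) {
    d <- length(model@descriptorNames)
    terms <- if (d) paste(sprintf("%+.6g*%s", model@coefficients,
                                  model@descriptorNames), collapse = " ")
             else ""
    writeLines(c(
        paste0("log10IC50 = ", trimws(paste(terms,
               sprintf("%+.6g", model@intercept)))),
        sprintf("n_train = %d", model@nTrain),
        sprintf("d = %d", d),
        sprintf("R2_train = %.6g", model@r2Train),
        sprintf("S_train = %.6g", model@sTrain)), path)
    invisible(path)
}

#' @rdname writeModelEquation
#' @export
writeModelTable <- function(model, path) {
    tab <- data.frame(
        term = c("(Intercept)", model@descriptorNames),
        coefficient = c(model@intercept, unname(model@coefficients)),
        se = c(model@seIntercept, unname(model@seCoefficients)))
    utils::write.csv(tab, path, row.names = FALSE)
    invisible(path)
}
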