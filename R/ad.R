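## Applicability domain (AD): decides for which query compounds a model's
## prediction is an interpolation rather than an extrapolation. Two
## alternative criteria are implemented: the leverage approach (hat value
## against the warning leverage h* = 3(d+1)/n) and the standardization
## approach (per-descriptor absolute standardized deviations from the
## training distribution).

#' Warning leverage h*
#'
#' \code{h* = 3 (d + 1) / nTrain}, the conventional threshold separating
#' interpolation from extrapolation on the hat-matrix diagonal of a
#' d-descriptor model with intercept.
#'
#' @param d number of model descriptors.
#' @param nTrain training-set size (> d + 1).
#' @return Numeric scalar.
#' @examples
#' warningLeverage(8, 265)   # 0.1019 to 4 decimals
#' @export
warningLeverage <- function(d, nTrain) {
    d <- .checkScalarCount(d, "d", 0L)
    nTrain <- .checkScalarCount(nTrain, "nTrain", 2L)
    if (nTrain <= d + 1L) stop("need nTrain > d + 1")
    3 * (d + 1) / nTrain
}

# Leverages of query rows against a training design (intercept-augmented):
# h_i = x_i' (X'X)^-1 x_i.
.queryLeverage <- function(Xtrain, Xquery) {
    qrX <- qr(cbind(1, Xtrain))
    if (qrX$rank < ncol(Xtrain) + 1L)
        stop("singular training design; cannot compute leverages")
    R <- qr.R(qrX)
    xtxinv <- chol2inv(R)
    piv <- qrX$pivot
    A <- matrix(0, length(piv), length(piv))
    A[piv, piv] <- xtxinv
    Q <- cbind(1, Xquery)
    rowSums((Q %*% A) * Q)
}

#' Leverage applicability domain
#'
#' A query compound is inside the domain iff its leverage on the training
#' design of the model's descriptors is below the warning leverage
#' \code{\link{warningLeverage}(d, nTrain)}.
#'
#' @param model a \linkS4class{QSARLinearModel}.
#' @param xTrain training descriptors (matrix or
#'   \linkS4class{DescriptorMatrix}) containing the model columns.
#' @param xQuery query descriptors, same requirement.
#' @param hStar optional threshold override.
#' @return List with \code{hStar} and \code{table}, a data frame of
#'   (id, leverage, inside).
#' @export
leverageAD <- function(model, xTrain, xQuery, hStar = NULL) {
    nms <- descriptorNames(model)
    tr <- .xyMatrix(xTrain, rep(0, nrow(if (is(xTrain, "DescriptorMatrix"))
        descriptorValues(xTrain) else xTrain)), nms)$X
    qu <- if (is(xQuery, "DescriptorMatrix")) descriptorValues(xQuery)
          else as.matrix(xQuery)
    miss <- setdiff(nms, colnames(qu))
    if (length(miss))
        stop("model column(s) missing from query: ",
             paste(miss, collapse = ", "))
    qu <- qu[, nms, drop = FALSE]
    if (is.null(hStar)) hStar <- warningLeverage(length(nms), nrow(tr))
    h <- .queryLeverage(tr, qu)
    ids <- rownames(qu) %||% as.character(seq_len(nrow(qu)))
    list(hStar = hStar,
         table = data.frame(id = ids, leverage = h, inside = h < hStar))
}

#' Standardization applicability domain
#'
#' For each query compound the d absolute standardized deviations
#' \code{s_ik = |x_ik - mean_k(train)| / sd_k(train)} are computed. The
#' compound is inside if \code{max(s_ik) <= 3}; otherwise, if
#' \code{min(s_ik) < 3}, the fallback statistic
#' \code{sNew = mean(s_ik) + 1.28 * sd(s_ik)} (sample SD) decides:
#' inside iff \code{sNew <= 3}. If even the minimum reaches 3 the compound
#' is outside and \code{sNew} is not computed.
#'
#' @param xTrain,xQuery descriptor sources containing \code{descriptors}.
#' @param descriptors model columns (default: all columns of
#'   \code{xTrain}).
#' @return Data frame of (id, sMax, sMin, sNew, inside); \code{sNew} is
#'   \code{NA} where the fallback does not apply. Training columns with
#'   zero SD are excluded with a warning.
#' @export
standardizationAD <- function(xTrain, xQuery, descriptors = NULL) {
    tr <- if (is(xTrain, "DescriptorMatrix")) descriptorValues(xTrain)
          else as.matrix(xTrain)
    qu <- if (is(xQuery, "DescriptorMatrix")) descriptorValues(xQuery)
          else as.matrix(xQuery)
    if (is.null(descriptors)) descriptors <- colnames(tr)
    miss <- setdiff(descriptors, colnames(qu))
    if (length(miss))
        stop("descriptor column(s) missing from query: ",
             paste(miss, collapse = ", "))
    tr <- tr[, descriptors, drop = FALSE]
    qu <- qu[, descriptors, drop = FALSE]
    mu <- colMeans(tr)
    sds <- apply(tr, 2L, stats::sd)
    bad <- sds == 0
    if (any(bad)) {
        warning("training column(s) with zero SD excluded: ",
                paste(descriptors[bad], collapse = ", "))
        mu <- mu[!bad]; sds <- sds[!bad]
        qu <- qu[, !bad, drop = FALSE]
    }
    if (!ncol(qu)) stop("no usable descriptor columns")
    S <- abs(sweep(sweep(qu, 2L, mu), 2L, sds, "/"))
    sMax <- apply(S, 1L, max)
    sMin <- apply(S, 1L, min)
    sNew <- rep(NA_real_, nrow(S))
    inside <- sMax <= 3
    fb <- !inside & sMin < 3
    if (any(fb)) {
        sNew[fb] <- rowMeans(S[fb, , drop = FALSE]) +
            1.28 * apply(S[fb, , drop = FALSE], 1L, stats::sd)
        inside[fb] <- sNew[fb] <= 3
    }
    ids <- rownames(qu) %||% as.character(seq_len(nrow(qu)))
    data.frame(id = ids, sMax = sMax, sMin = sMin, sNew = sNew,
               inside = inside, row.names = NULL)
}

#' Williams plot table
#'
#' The underlying data of a Williams plot: per compound, the subset label,
#' the leverage against the training design, and the standardized residual
#' (residual / Strain). Compounds breaching \code{hStar} or
#' |standardized residual| > 3 are flagged.
#'
#' @param model a \linkS4class{QSARLinearModel}.
#' @param x descriptors for all partitioned compounds.
#' @param act \linkS4class{ActivitySet}.
#' @param partition \linkS4class{SubsetPartition}.
#' @param hStar optional threshold override.
#' @return List with \code{hStar} and \code{table}: data frame of
#'   (id, subset, leverage, stdResidual, leverageExceeded,
#'   residualOutlier).
#' @export
williamsTable <- function(model, x, act, partition, hStar = NULL) {
    m <- if (is(x, "DescriptorMatrix")) descriptorValues(x) else as.matrix(x)
    nms <- descriptorNames(model)
    lab <- partitionLabels(partition)
    ids <- names(lab)
    if (!all(ids %in% rownames(m)))
        stop("partition ids missing from the descriptor matrix")
    trainIds <- ids[lab == "train"]
    tr <- m[trainIds, nms, drop = FALSE]
    if (is.null(hStar)) hStar <- warningLeverage(length(nms), length(trainIds))
    h <- .queryLeverage(tr, m[ids, nms, drop = FALSE])
    y <- logIC50(act)[ids]
    pred <- predict(model, m[ids, , drop = FALSE])
    res <- as.numeric(y) - pred
    # a perfect fit (Strain = 0) leaves zero residuals standardized to zero
    stdres <- if (model@sTrain > 0) res / model@sTrain
              else ifelse(res == 0, 0, sign(res) * Inf)
    list(hStar = hStar,
         table = data.frame(id = ids, subset = as.character(lab),
                            leverage = h, stdResidual = as.numeric(stdres),
                            leverageExceeded = h > hStar,
                            residualOutlier = abs(stdres) > 3,
                            row.names = NULL))
}
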