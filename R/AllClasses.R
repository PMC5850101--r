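#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- classes --

#' DescriptorMatrix: compounds-by-descriptors numeric grid
#'
#' Container for a molecular descriptor table: N compounds (rows) by D
#' descriptors (columns), numeric, with missing cells stored as \code{NA}.
#' Both the raw descriptor pool and a fitted model's few selected columns
#' live in this class. Row names are compound identifiers, column names are
#' descriptor names; both must be unique and non-empty.
#'
#' @slot values numeric matrix with complete, unique dimnames.
#'
#' @seealso [DescriptorMatrix()] (constructor), [readDescriptorTable()]
#' @export
setClass("DescriptorMatrix", representation(values = "matrix"))

setValidity("DescriptorMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    ids <- rownames(v); nms <- colnames(v)
    if (is.null(ids) || is.null(nms))
        return("'values' must carry compound ids as rownames and descriptor names as colnames")
    if (anyDuplicated(ids)) return("duplicated compound ids")
    if (anyDuplicated(nms)) return("duplicated descriptor names")
    if (any(!nzchar(ids)) || any(!nzchar(nms)))
        return("empty compound id or descriptor name")
    TRUE
})

#' ActivitySet: per-compound inhibitory activity
#'
#' Stores the half-maximal inhibitory concentration IC50 (nM, strictly
#' positive) together with its base-10 logarithm, the response variable of
#' every regression in the package. The two representations are kept
#' consistent to within 1e-12.
#'
#' @slot compoundIds character vector of unique ids.
#' @slot ic50 numeric, nM, > 0.
#' @slot logIC50 numeric, \code{log10(ic50)}.
#'
#' @seealso [ActivitySet()] (constructor), [readActivityTable()]
#' @export
setClass("ActivitySet", representation(
    compoundIds = "character", ic50 = "numeric", logIC50 = "numeric"))

setValidity("ActivitySet", function(object) {
    n <- length(object@compoundIds)
    if (length(object@ic50) != n || length(object@logIC50) != n)
        return("compoundIds, ic50 and logIC50 must have equal length")
    if (anyDuplicated(object@compoundIds)) return("duplicated compound ids")
    if (any(!is.finite(object@ic50)) || any(object@ic50 <= 0))
        return("ic50 must be finite and strictly positive (nM)")
    if (any(abs(object@logIC50 - log10(object@ic50)) > 1e-12))
        return("logIC50 inconsistent with log10(ic50)")
    TRUE
})

#' SubsetPartition: train/validation/test labels
#'
#' Assigns every compound to exactly one of the three modelling subsets.
#' All three subsets must be non-empty.
#'
#' @slot compoundIds character vector of unique ids.
#' @slot labels factor with levels \code{train}, \code{val}, \code{test}.
#'
#' @seealso [SubsetPartition()] (constructor), [bsmSplit()]
#' @export
setClass("SubsetPartition", representation(
    compoundIds = "character", labels = "factor"))

setValidity("SubsetPartition", function(object) {
    if (length(object@labels) != length(object@compoundIds))
        return("labels and compoundIds must have equal length")
    if (anyDuplicated(object@compoundIds)) return("duplicated compound ids")
    if (!identical(levels(object@labels), c("train", "val", "test")))
        return("labels must be a factor with levels train, val, test")
    if (anyNA(object@labels)) return("every compound must be labeled")
    if (any(table(object@labels) == 0L))
        return("all three subsets must be non-empty")
    TRUE
})

#' QSARLinearModel: a fitted multivariable linear regression model
#'
#' A d-descriptor ordinary least-squares model of log10 IC50 with intercept,
#' together with its training statistics: R2train, Strain
#' (\code{sqrt(RSS/(n - d - 1))}), per-compound residuals and hat-matrix
#' leverages, and coefficient standard errors (used by the replacement-method
#' search to rank positions by relative error |SE/beta|).
#'
#' @slot descriptorNames character, the d selected descriptor names.
#' @slot coefficients numeric, named by descriptor.
#' @slot intercept numeric scalar.
#' @slot r2Train,sTrain numeric scalars.
#' @slot nTrain integer, training-set size.
#' @slot residuals,leverages numeric, named by compound id.
#' @slot seCoefficients numeric, named; \code{seIntercept} numeric scalar.
#'
#' @seealso [fitOLS()], [rmSelect()]
#' @export
setClass("QSARLinearModel", representation(
    descriptorNames = "character",
    coefficients    = "numeric",
    intercept       = "numeric",
    r2Train         = "numeric",
    sTrain          = "numeric",
    nTrain          = "integer",
    residuals       = "numeric",
    leverages       = "numeric",
    seCoefficients  = "numeric",
    seIntercept     = "numeric"))

setValidity("QSARLinearModel", function(object) {
    d <- length(object@descriptorNames)
    if (length(object@coefficients) != d)
        return("one coefficient per descriptor required")
    if (d > 0 && !identical(names(object@coefficients), object@descriptorNames))
        return("coefficients must be named by descriptorNames")
    if (length(object@intercept) != 1L) return("intercept must be a scalar")
    if (length(object@residuals) != length(object@leverages))
        return("residuals and leverages must have equal length")
    TRUE
})

## ----------------------------------------------------------- constructors --

#' Construct a DescriptorMatrix
#'
#' @param values numeric matrix, or object coercible to one.
#' @param compoundIds,descriptorNames optional dimnames; taken from
#'   \code{values} when absent.
#' @return A \linkS4class{DescriptorMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("d1", "d2")))
#' DescriptorMatrix(m)
#' @export
DescriptorMatrix <- function(values, compoundIds = NULL, descriptorNames = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(compoundIds)) rownames(values) <- as.character(compoundIds)
    if (!is.null(descriptorNames)) colnames(values) <- as.character(descriptorNames)
    new("DescriptorMatrix", values = values)
}

#' Construct an ActivitySet
#'
#' Exactly one of \code{ic50} (nM) or \code{logIC50} must be supplied; the
#' other representation is derived.
#'
#' @param compoundIds character ids.
#' @param ic50 numeric IC50 in nM (> 0), or \code{NULL}.
#' @param logIC50 numeric log10 IC50, or \code{NULL}.
#' @return An \linkS4class{ActivitySet}.
#' @examples
#' ActivitySet(c("a", "b"), ic50 = c(1000, 0.8))
#' @export
ActivitySet <- function(compoundIds, ic50 = NULL, logIC50 = NULL) {
    compoundIds <- as.character(compoundIds)
    if (is.null(ic50) == is.null(logIC50))
        stop("supply exactly one of 'ic50' or 'logIC50'")
    if (is.null(logIC50)) {
        if (any(!is.finite(ic50)) || any(ic50 <= 0))
            stop("IC50 values must be finite and strictly positive (nM)")
        logIC50 <- log10(ic50)
    } else {
        ic50 <- 10^logIC50
    }
    new("ActivitySet", compoundIds = compoundIds,
        ic50 = unname(ic50), logIC50 = unname(logIC50))
}

#' Construct a SubsetPartition
#'
#' @param compoundIds character ids.
#' @param labels character or factor with values among train/val/test.
#' @return A \linkS4class{SubsetPartition}.
#' @export
SubsetPartition <- function(compoundIds, labels) {
    labels <- factor(as.character(labels), levels = c("train", "val", "test"))
    new("SubsetPartition", compoundIds = as.character(compoundIds),
        labels = labels)
}

## -------------------------------------------------------------- accessors --

#' @rdname compoundIds
#' @aliases compoundIds,DescriptorMatrix-method
setMethod("compoundIds", "DescriptorMatrix", function(x) rownames(x@values))

#' @rdname compoundIds
setMethod("compoundIds", "ActivitySet", function(x) x@compoundIds)

#' @rdname compoundIds
setMethod("compoundIds", "SubsetPartition", function(x) x@compoundIds)

#' @rdname descriptorNames
setMethod("descriptorNames", "DescriptorMatrix", function(x) colnames(x@values))

#' @rdname descriptorNames
setMethod("descriptorNames", "QSARLinearModel", function(x) x@descriptorNames)

#' @rdname descriptorValues
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)

#' @rdname missingMask
setMethod("missingMask", "DescriptorMatrix", function(x) is.na(x@values))

#' @rdname nCompounds
setMethod("nCompounds", "DescriptorMatrix", function(x) nrow(x@values))

#' @rdname nCompounds
setMethod("nDescriptors", "DescriptorMatrix", function(x) ncol(x@values))

#' @rdname ic50
setMethod("ic50", "ActivitySet",
          function(x) stats::setNames(x@ic50, x@compoundIds))

#' @rdname logIC50
setMethod("logIC50", "ActivitySet",
          function(x) stats::setNames(x@logIC50, x@compoundIds))

#' @rdname partitionLabels
setMethod("partitionLabels", "SubsetPartition",
          function(x) stats::setNames(x@labels, x@compoundIds))

#' @rdname subsetIds
setMethod("subsetIds", "SubsetPartition", function(x, subset) {
    subset <- match.arg(subset, c("train", "val", "test"))
    x@compoundIds[x@labels == subset]
})

#' @rdname subsetSizes
setMethod("subsetSizes", "SubsetPartition", function(x) {
    tab <- table(x@labels)
    stats::setNames(as.integer(tab), names(tab))
})

#' @rdname modelCoefficients
setMethod("modelCoefficients", "QSARLinearModel", function(x) x@coefficients)

#' @rdname modelIntercept
setMethod("modelIntercept", "QSARLinearModel", function(x) x@intercept)

#' @rdname fitStats
setMethod("fitStats", "QSARLinearModel", function(x) {
    list(r2 = x@r2Train, s = x@sTrain, n = x@nTrain,
         d = length(x@descriptorNames),
         residuals = x@residuals, leverages = x@leverages,
         seCoefficients = x@seCoefficients, seIntercept = x@seIntercept)
})

## ------------------------------------------------------------- subsetting --

#' Subset a DescriptorMatrix
#'
#' Rows select compounds, columns select descriptors; character indices match
#' ids/names. Always returns a \linkS4class{DescriptorMatrix} (drop is
#' ignored).
#'
#' @param x a \linkS4class{DescriptorMatrix}.
#' @param i,j row/column indices.
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "DescriptorMatrix", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    new("DescriptorMatrix", values = v)
})

#' @describeIn DescriptorMatrix-class dimensions (compounds, descriptors)
#' @param x a \linkS4class{DescriptorMatrix}.
#' @export
setMethod("dim", "DescriptorMatrix", function(x) dim(x@values))

## ------------------------------------------------------------------- show --

setMethod("show", "DescriptorMatrix", function(object) {
    v <- object@values
    cat(sprintf("DescriptorMatrix: %d compounds x %d descriptors\n",
                nrow(v), ncol(v)))
    nmiss <- sum(is.na(v))
    cat(sprintf("  missing cells: %d (%.2f%%)\n", nmiss,
                if (length(v)) 100 * nmiss / length(v) else 0))
    if (ncol(v)) cat("  descriptors: ",
        paste(utils::head(colnames(v), 5), collapse = ", "),
        if (ncol(v) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "ActivitySet", function(object) {
    cat(sprintf("ActivitySet: %d compounds\n", length(object@compoundIds)))
    if (length(object@ic50))
        cat(sprintf("  IC50 range: %.3g - %.3g nM (log10: %.3f - %.3f)\n",
                    min(object@ic50), max(object@ic50),
                    min(object@logIC50), max(object@logIC50)))
})

setMethod("show", "SubsetPartition", function(object) {
    sz <- table(object@labels)
    cat(sprintf("SubsetPartition: %d compounds (train %d / val %d / test %d)\n",
                length(object@compoundIds), sz[["train"]], sz[["val"]],
                sz[["test"]]))
})

setMethod("show", "QSARLinearModel", function(object) {
    d <- length(object@descriptorNames)
    cat(sprintf("QSARLinearModel: d = %d descriptors, n = %d\n",
                d, object@nTrain))
    terms <- if (d) paste(sprintf("%+.3g %s", object@coefficients,
                                  object@descriptorNames), collapse = " ")
             else ""
    cat("  log10IC50 =", terms, sprintf("%+.3g\n", object@intercept))
    cat(sprintf("  R2train = %.3f, Strain = %.3f\n",
                object@r2Train, object@sTrain))
})
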