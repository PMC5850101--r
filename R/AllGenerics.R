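#' Compound identifiers of an object
#'
#' @param x a \linkS4class{DescriptorMatrix}, \linkS4class{ActivitySet} or
#'   \linkS4class{SubsetPartition}.
#' @return Character vector of compound identifiers.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Descriptor names
#'
#' @param x a \linkS4class{DescriptorMatrix} or \linkS4class{QSARLinearModel}.
#' @return Character vector of descriptor (column) names.
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' Numeric descriptor grid
#'
#' @param x a \linkS4class{DescriptorMatrix}.
#' @return Numeric matrix (compounds as rows, descriptors as columns);
#'   missing cells are \code{NA}.
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' Missing-value mask
#'
#' @param x a \linkS4class{DescriptorMatrix}.
#' @return Logical matrix, \code{TRUE} where the descriptor value is absent.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Number of compounds / descriptors
#'
#' @param x a \linkS4class{DescriptorMatrix}.
#' @return Integer count.
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' @rdname nCompounds
#' @export
setGeneric("nDescriptors", function(x) standardGeneric("nDescriptors"))

#' IC50 values in nM
#'
#' @param x an \linkS4class{ActivitySet}.
#' @return Numeric vector of IC50 (nM), named by compound id.
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' log10 IC50 values
#'
#' @param x an \linkS4class{ActivitySet}.
#' @return Numeric vector of log10 IC50 (IC50 in nM), named by compound id.
#' @export
setGeneric("logIC50", function(x) standardGeneric("logIC50"))

#' Subset labels of a partition
#'
#' @param x a \linkS4class{SubsetPartition}.
#' @return Factor with levels \code{train}, \code{val}, \code{test}, named by
#'   compound id.
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' Ids belonging to one subset
#'
#' @param x a \linkS4class{SubsetPartition}.
#' @param subset one of \code{"train"}, \code{"val"}, \code{"test"}.
#' @return Character vector of compound ids.
#' @export
setGeneric("subsetIds", function(x, subset) standardGeneric("subsetIds"))

#' Subset sizes
#'
#' @param x a \linkS4class{SubsetPartition}.
#' @return Named integer vector (train, val, test).
#' @export
setGeneric("subsetSizes", function(x) standardGeneric("subsetSizes"))

#' Model coefficients (without intercept)
#'
#' @param x a \linkS4class{QSARLinearModel}.
#' @return Named numeric vector of regression coefficients.
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' Model intercept
#'
#' @param x a \linkS4class{QSARLinearModel}.
#' @return Numeric scalar.
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))

#' Training-fit statistics
#'
#' Statistics of the least-squares training fit: \code{r2} (coefficient of
#' determination), \code{s} (regression standard deviation,
#' \code{sqrt(RSS/(n - d - 1))}), \code{n}, \code{d}, per-compound
#' \code{residuals} and hat-matrix \code{leverages}, and coefficient
#' standard errors.
#'
#' @param x a \linkS4class{QSARLinearModel}.
#' @return Named list.
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))
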