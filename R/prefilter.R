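## Descriptor-pool prefiltering: remove uninformative columns (missing
## values, constant, near-constant) and collinear duplicates, so the
## replacement-method search operates on a linearly independent, informative
## pool.

#' Drop uninformative descriptor columns
#'
#' Removes, in this order of precedence, every column with at least one
#' missing entry, every constant column, and every column whose modal value
#' frequency is at least \code{nearConstFrac}.
#'
#' @param dm a \linkS4class{DescriptorMatrix} with at least 2 compounds.
#' @param nearConstFrac modal-frequency threshold (default 0.95).
#' @return List with the filtered \code{descriptors} and a \code{report}
#'   (removed column names by category, pool sizes before/after).
#' @seealso [dropCollinear()], [prefilterPool()]
#' @export
dropUninformative <- function(dm, nearConstFrac = 0.95) {
    v <- descriptorValues(dm)
    if (nrow(v) < 2L) stop("need at least 2 compounds")
    nearConstFrac <- .checkFraction(nearConstFrac, "nearConstFrac")
    nms <- colnames(v)
    hasMissing <- colSums(is.na(v)) > 0L
    modalFreq <- apply(v, 2L, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(1)
        max(tabulate(match(col, unique(col)))) / length(col)
    })
    isConstant <- !hasMissing & modalFreq == 1
    isNearConst <- !hasMissing & !isConstant & modalFreq >= nearConstFrac
    keep <- !hasMissing & !isConstant & !isNearConst
    if (!any(keep)) stop("all descriptor columns removed as uninformative")
    report <- list(removedMissing = nms[hasMissing],
                   removedConstant = nms[isConstant],
                   removedNearConstant = nms[isNearConst],
                   removedCollinear = data.frame(kept = character(),
                                                 dropped = character()),
                   poolSizeBefore = ncol(v), poolSizeAfter = sum(keep))
    list(descriptors = dm[, keep], report = report)
}

#' Drop collinear descriptor columns
#'
#' Greedy scan in column order: a column whose squared Pearson correlation
#' with any already-kept column reaches \code{r2Threshold} is dropped (the
#' earlier column wins). The kept pool therefore has all pairwise r-squared
#' below the threshold. Run after \code{\link{dropUninformative}}: missing
#' values are not allowed here.
#'
#' @param dm a \linkS4class{DescriptorMatrix}, complete (no \code{NA}).
#' @param r2Threshold squared-correlation cutoff (default 0.998, i.e. only
#'   effectively linearly dependent pairs are pruned).
#' @return List with \code{descriptors} and \code{report}; the report's
#'   \code{removedCollinear} is a data frame of (kept, dropped) name pairs,
#'   the kept name being the first retained column that triggered the drop.
#' @export
dropCollinear <- function(dm, r2Threshold = 0.998) {
    v <- descriptorValues(dm)
    if (anyNA(v)) stop("missing values present; run dropUninformative first")
    r2Threshold <- .checkFraction(r2Threshold, "r2Threshold")
    n <- nrow(v); nms <- colnames(v)
    mu <- colMeans(v)
    vc <- sweep(v, 2L, mu)
    ss <- sqrt(colSums(vc^2))
    zeroSd <- ss == 0
    vs <- sweep(vc, 2L, pmax(ss, .Machine$double.eps), "/")
    keptIdx <- integer(0)
    pairs <- list()
    for (j in seq_len(ncol(v))) {
        if (zeroSd[j]) { keptIdx <- c(keptIdx, j); next }  # constant: no r defined
        if (length(keptIdx)) {
            cand <- keptIdx[!zeroSd[keptIdx]]
            if (length(cand)) {
                r <- drop(crossprod(vs[, cand, drop = FALSE], vs[, j]))
                hit <- which(r^2 >= r2Threshold - 1e-12)
                if (length(hit)) {
                    pairs[[length(pairs) + 1L]] <-
                        c(kept = nms[cand[hit[1L]]], dropped = nms[j])
                    next
                }
            }
        }
        keptIdx <- c(keptIdx, j)
    }
    removed <- if (length(pairs))
        as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
    else data.frame(kept = character(), dropped = character())
    report <- list(removedMissing = character(),
                   removedConstant = character(),
                   removedNearConstant = character(),
                   removedCollinear = removed,
                   poolSizeBefore = ncol(v), poolSizeAfter = length(keptIdx))
    list(descriptors = dm[, keptIdx], report = report)
}

#' Prefilter a descriptor pool
#'
#' \code{\link{dropUninformative}} followed by \code{\link{dropCollinear}},
#' with a merged report.
#'
#' @inheritParams dropUninformative
#' @inheritParams dropCollinear
#' @return List with \code{descriptors} and merged \code{report}.
#' @export
prefilterPool <- function(dm, nearConstFrac = 0.95, r2Threshold = 0.998) {
    step1 <- dropUninformative(dm, nearConstFrac)
    step2 <- dropCollinear(step1$descriptors, r2Threshold)
    report <- list(removedMissing = step1$report$removedMissing,
                   removedConstant = step1$report$removedConstant,
                   removedNearConstant = step1$report$removedNearConstant,
                   removedCollinear = step2$report$removedCollinear,
                   poolSizeBefore = step1$report$poolSizeBefore,
                   poolSizeAfter = step2$report$poolSizeAfter)
    list(descriptors = step2$descriptors, report = report)
}

#' Write a prefilter report
#'
#' One row per removed column: name, removal reason, and for collinear
#' removals the retained partner.
#'
#' @param report a prefilter report.
#' @param path file path (CSV).
#' @return \code{path}, invisibly.
#' @export
writePrefilterReport <- function(report, path) {
    rows <- rbind(
        data.frame(descriptor = report$removedMissing, reason = "missing",
                   keptPartner = NA_character_),
        data.frame(descriptor = report$removedConstant, reason = "constant",
                   keptPartner = NA_character_),
        data.frame(descriptor = report$removedNearConstant,
                   reason = "near_constant", keptPartner = NA_character_),
        if (nrow(report$removedCollinear))
            data.frame(descriptor = report$removedCollinear$dropped,
                       reason = "collinear",
                       keptPartner = report$removedCollinear$kept)
    )
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}
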