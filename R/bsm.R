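## Balanced subsets splitting: k-means clustering in (autoscaled) descriptor
## space, then within-cluster allocation to train/val/test so every cluster
## is represented in each subset it can populate, with global sizes fixed by
## largest-remainder apportionment.

# Largest-remainder apportionment of n into parts proportional to
# fractions; ties in the fractional remainder favour earlier subsets
# (train, then val, then test).
.apportion <- function(n, fractions) {
    raw <- n * fractions
    sizes <- floor(raw)
    left <- n - sum(sizes)
    if (left > 0) {
        ord <- order(-(raw - sizes), seq_along(fractions))
        take <- ord[seq_len(left)]
        sizes[take] <- sizes[take] + 1L
    }
    as.integer(sizes)
}

#' Target subset sizes for a split
#'
#' Apportions n compounds among train/val/test proportionally to
#' \code{fractions} by the largest-remainder rule (remainder seats go to
#' the subsets with the largest fractional parts; ties favour train, then
#' val). For n = 530 and fractions (0.5, 0.25, 0.25) this gives
#' 265/133/132.
#'
#' @param n number of compounds.
#' @param fractions length-3 positive fractions summing to 1.
#' @return Named integer vector (train, val, test).
#' @export
subsetTargetSizes <- function(n, fractions = c(0.5, 0.25, 0.25)) {
    fractions <- .checkFractions3(fractions)
    stats::setNames(.apportion(.checkScalarCount(n, "n", 3L), fractions),
                    c("train", "val", "test"))
}

.checkFractions3 <- function(fractions) {
    fractions <- as.numeric(fractions)
    if (length(fractions) != 3L || any(fractions <= 0))
        stop("'fractions' must be 3 positive values (train, val, test)")
    if (abs(sum(fractions) - 1) > 1e-9)
        stop("'fractions' must sum to 1")
    fractions
}

#' Balanced subsets split via k-means clustering
#'
#' Clusters the compounds by k-means (Euclidean distance) on the optionally
#' autoscaled descriptor space, then allocates each cluster's members to
#' train/val/test: members are ordered by distance from their cluster
#' centroid (closest first) and apportioned within the cluster by the same
#' largest-remainder rule as the global sizes, so clusters of size >= 3
#' contribute to every subset. A final deterministic adjustment pass moves
#' boundary members between subsets until the global sizes of
#' \code{\link{subsetTargetSizes}} are met exactly.
#'
#' @param x a \linkS4class{DescriptorMatrix} (no missing values, N >= 10)
#'   or numeric matrix.
#' @param fractions train/val/test fractions (default 0.5/0.25/0.25).
#' @param kClusters number of clusters; default \code{ceiling(N/20)},
#'   at least 2. Must not exceed N.
#' @param standardize autoscale columns (zero mean, unit SD) before
#'   clustering; default \code{TRUE} since Euclidean k-means is
#'   scale-sensitive and descriptor pools mix binary and continuous columns.
#' @param seed integer seed (k-means restarts and any ties).
#' @param nInit k-means restarts; best within-cluster sum of squares kept.
#' @return List with \code{partition} (\linkS4class{SubsetPartition}),
#'   \code{clusters} (named integer vector), \code{kClusters}, and
#'   \code{sizes}.
#' @export
bsmSplit <- function(x, fractions = c(0.5, 0.25, 0.25), kClusters = NULL,
                     standardize = TRUE, seed = 1L, nInit = 10L) {
    m <- if (is(x, "DescriptorMatrix")) descriptorValues(x) else as.matrix(x)
    n <- nrow(m)
    if (n < 10L) stop("need at least 10 compounds to split")
    if (anyNA(m)) stop("missing descriptor values; prefilter first")
    fractions <- .checkFractions3(fractions)
    if (is.null(kClusters)) kClusters <- max(2L, ceiling(n / 20))
    kClusters <- .checkScalarCount(kClusters, "kClusters", 2L)
    if (kClusters > n) stop("kClusters exceeds the number of compounds")
    ids <- rownames(m) %||% as.character(seq_len(n))

    ms <- m
    if (standardize) {
        sds <- apply(ms, 2L, stats::sd)
        ok <- sds > 0
        ms <- scale(ms[, ok, drop = FALSE])
    }
    k <- min(kClusters, nrow(unique(ms)))

    oldSeed <- .Random.seed_save()
    on.exit(.Random.seed_restore(oldSeed), add = TRUE)
    set.seed(seed)
    km <- suppressWarnings(stats::kmeans(ms, centers = k, nstart = nInit,
                                         iter.max = 100L))
    cluster <- km$cluster
    centd <- sqrt(rowSums((ms - km$centers[cluster, , drop = FALSE])^2))

    target <- .apportion(n, fractions)
    labels <- integer(n)            # 1 train, 2 val, 3 test
    for (cl in seq_len(k)) {
        members <- which(cluster == cl)
        members <- members[order(centd[members], members)]
        cnt <- .apportion(length(members), fractions)
        labels[members] <- rep.int(1:3, cnt)
    }

    # adjustment pass to hit the global targets exactly
    repeat {
        assigned <- tabulate(labels, 3L)
        excess <- assigned - target
        if (all(excess == 0L)) break
        over <- which.max(excess)
        under <- which.max(-excess)
        candIdx <- which(labels == over)
        # prefer moving from the cluster holding most members of the
        # over-full subset; within it, the member farthest from its centroid
        tab <- table(cluster[candIdx])
        cl <- as.integer(names(tab)[which.max(tab)])
        inCl <- candIdx[cluster[candIdx] == cl]
        move <- inCl[order(-centd[inCl], inCl)][1L]
        labels[move] <- under
    }

    part <- SubsetPartition(ids, c("train", "val", "test")[labels])
    list(partition = part,
         clusters = stats::setNames(cluster, ids),
         kClusters = k,
         sizes = subsetSizes(part))
}

#' Activity-balance diagnostics for a partition
#'
#' Per-subset summary of log10 IC50 (n, mean, SD, min, max) plus the
#' two-sample Kolmogorov-Smirnov distance between the training subset and
#' each other subset. Diagnostic only; no decision is taken.
#'
#' @param part a \linkS4class{SubsetPartition}.
#' @param act an \linkS4class{ActivitySet} covering the partitioned ids.
#' @return Data frame with one row per subset.
#' @export
balanceDiagnostics <- function(part, act) {
    y <- logIC50(act)
    lab <- partitionLabels(part)
    miss <- setdiff(names(lab), names(y))
    if (length(miss)) stop("activities missing for partitioned compound(s)")
    groups <- split(as.numeric(y[names(lab)]), lab)
    ksd <- function(a, b) {
        if (stats::sd(c(a, b)) == 0) return(0)
        unname(suppressWarnings(stats::ks.test(a, b)$statistic))
    }
    out <- do.call(rbind, lapply(names(groups), function(g) {
        v <- groups[[g]]
        data.frame(subset = g, n = length(v), mean = mean(v),
                   sd = stats::sd(v), min = min(v), max = max(v),
                   ksFromTrain = if (g == "train") 0
                                 else ksd(groups$train, v))
    }))
    rownames(out) <- NULL
    out
}
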