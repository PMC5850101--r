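# Fixture builders shared across the suite. All fixtures are generated in
# code; no data files.

# tiny named matrix -> DescriptorMatrix
dmFixture <- function(values, ids = NULL, nms = NULL) {
    values <- as.matrix(values)
    if (is.null(ids)) ids <- sprintf("c%02d", seq_len(nrow(values)))
    if (is.null(nms)) nms <- sprintf("d%02d", seq_len(ncol(values)))
    DescriptorMatrix(values, ids, nms)
}

# a clean planted dataset: continuous pool, no nuisance columns
plantedFixture <- function(n = 100, D = 20, d = 3, noise = 0, seed = 1,
                           fracBinary = 0) {
    generateSynthetic(syntheticSpec(
        nCompounds = n, nDescriptors = D, nSignal = d, noiseSd = noise,
        collinearBlockCount = 0, fracBinary = fracBinary,
        fracConstant = 0, fracNearConstant = 0, fracMissingCols = 0,
        seed = seed))
}

# exhaustive best-subset oracle: minimum RSS over all size-d subsets by
# naive per-subset refits (the brute-force reference for the RM search)
exhaustiveBestSubset <- function(X, y, d) {
    combos <- utils::combn(ncol(X), d)
    rss <- apply(combos, 2L, function(ix)
        sum(stats::.lm.fit(cbind(1, X[, ix, drop = FALSE]), y)$residuals^2))
    best <- which.min(rss)
    list(subset = combos[, best], rss = rss[best],
         s = sqrt(rss[best] / (nrow(X) - d - 1)))
}

# write a small delimited file
writeLinesTmp <- function(lines) {
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    f
}
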