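## Internal helpers shared across modules.

# Delimiter auto-detection among comma / tab / semicolon: the candidate that
# splits the header into the most fields wins; ties favour the comma.
.detectDelim <- function(path) {
    header <- readLines(path, n = 1L, warn = FALSE)
    if (!length(header)) stop("empty file: ", path)
    cands <- c("," = ",", "\t" = "\t", ";" = ";")
    counts <- vapply(cands, function(d)
        length(strsplit(header, d, fixed = TRUE)[[1]]), integer(1))
    cands[[which.max(counts)]]
}

.checkScalarCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
        stop("'", name, "' must be a single integer >= ", min)
    as.integer(x)
}

.checkFraction <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
        stop("'", name, "' must be a single value in [0, 1]")
    as.numeric(x)
}

# Resolve (x, y) inputs used throughout the regression modules: x may be a
# DescriptorMatrix or plain matrix, y an ActivitySet (matched by id) or a
# numeric vector in row order.
.xyMatrix <- function(x, y, descriptors = NULL) {
    m <- if (is(x, "DescriptorMatrix")) descriptorValues(x) else as.matrix(x)
    if (!is.null(descriptors)) {
        descriptors <- as.character(descriptors)
        miss <- setdiff(descriptors, colnames(m))
        if (length(miss))
            stop("descriptor column(s) not found: ",
                 paste(miss, collapse = ", "))
        m <- m[, descriptors, drop = FALSE]
    }
    if (is(y, "ActivitySet")) {
        if (is.null(rownames(m)))
            stop("descriptor rows carry no compound ids to match activities")
        idx <- match(rownames(m), compoundIds(y))
        if (anyNA(idx))
            stop("activities missing for ",
                 sum(is.na(idx)), " compound(s); align first")
        yv <- logIC50(y)[idx]
    } else {
        yv <- as.numeric(y)
        if (length(yv) != nrow(m))
            stop("length of response does not match number of compounds")
        names(yv) <- rownames(m)
    }
    list(X = m, y = yv)
}

# Derive a reproducible sub-seed for a named pipeline stage from the master
# seed; kept below 2^31.
.stageSeed <- function(seed, stage) {
    offs <- c(generate = 11L, prefilter = 23L, split = 37L, search = 53L,
              loo = 67L, lno = 71L, yrand = 83L, ad = 97L)
    off <- if (stage %in% names(offs)) offs[[stage]] else 101L
    (as.integer(seed) * 1000L + off) %% .Machine$integer.max
}
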