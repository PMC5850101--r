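## Reading and writing the delimited-text formats: descriptor tables,
## activity tables, partitions, and plain key-value summaries.

#' Read a descriptor table
#'
#' Reads a delimited text file (comma, tab or semicolon; auto-detected from
#' the header unless \code{delim} is given) with a header row of descriptor
#' names and the compound identifier in the first column. Non-numeric or
#' empty cells become missing values (\code{NA}) and are flagged in
#' \code{\link{missingMask}}.
#'
#' @param path file path.
#' @param delim optional single-character delimiter overriding detection.
#' @return A \linkS4class{DescriptorMatrix}; row and column order preserved.
#' @seealso [writeDescriptorTable()]
#' @export
readDescriptorTable <- function(path, delim = NULL) {
    if (is.null(delim)) delim <- .detectDelim(path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L) stop("descriptor table needs a header and data rows")
    fields <- strsplit(lines, delim, fixed = TRUE)
    header <- fields[[1L]]
    ncolumns <- length(header)
    nms <- trimws(header[-1L])
    if (anyDuplicated(nms))
        stop("duplicated descriptor column name(s): ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    body <- fields[-1L]
    # strsplit drops trailing empty fields; pad, but reject genuinely ragged rows
    lens <- lengths(body)
    bad <- which(lens > ncolumns | lens < 2L)
    if (length(bad))
        stop("ragged row at line ", bad[1L] + 1L, ": expected ",
             ncolumns, " fields, found ", lens[bad[1L]])
    body <- lapply(body, function(f) c(f, rep("", ncolumns - length(f))))
    ids <- trimws(vapply(body, `[[`, character(1), 1L))
    if (anyDuplicated(ids))
        stop("duplicated compound id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    cells <- trimws(t(vapply(body, function(f) f[-1L], character(ncolumns - 1L))))
    if (ncolumns == 2L) cells <- matrix(cells, ncol = 1L)
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    vals[cells == ""] <- NA_real_
    dimnames(vals) <- list(ids, nms)
    DescriptorMatrix(vals)
}

#' Write a descriptor table
#'
#' Inverse of \code{\link{readDescriptorTable}}; missing cells are written
#' as empty fields. Values are written with full precision so that a
#' write/read round trip is exact for finite entries.
#'
#' @param dm a \linkS4class{DescriptorMatrix}.
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param idColumn name of the identifier column in the header.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(dm, path, delim = ",", idColumn = "compound") {
    v <- descriptorValues(dm)
    chr <- array(vapply(v, function(x)
        if (is.na(x)) "" else format(x, digits = 17), character(1)), dim(v))
    lines <- c(paste(c(idColumn, colnames(v)), collapse = delim),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i], chr[i, ]), collapse = delim),
                   character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Read an activity table
#'
#' Two delimited columns: compound id and activity. With
#' \code{ic50Given = TRUE} (default) the value is IC50 in nM and is
#' log10-transformed internally; otherwise it is already log10 IC50.
#'
#' @param path file path.
#' @param ic50Given flag; see Details.
#' @param delim optional delimiter override.
#' @param header whether the file carries a header row (default TRUE).
#' @return An \linkS4class{ActivitySet}.
#' @export
readActivityTable <- function(path, ic50Given = TRUE, delim = NULL,
                              header = TRUE) {
    if (is.null(delim)) delim <- .detectDelim(path)
    tab <- utils::read.table(path, sep = delim, header = header,
                             colClasses = c("character", "numeric"),
                             strip.white = TRUE)
    if (ncol(tab) < 2L) stop("activity table needs two columns (id, value)")
    ids <- tab[[1L]]; val <- tab[[2L]]
    if (anyNA(val)) stop("non-numeric activity value(s) in ", path)
    if (ic50Given) {
        if (any(val <= 0))
            stop("nonpositive IC50 value(s); IC50 must be > 0 nM")
        ActivitySet(ids, ic50 = val)
    } else {
        ActivitySet(ids, logIC50 = val)
    }
}

#' Write an activity table
#'
#' @param act an \linkS4class{ActivitySet}.
#' @param path file path.
#' @param ic50 write IC50 in nM (default) or log10 IC50.
#' @param delim field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeActivityTable <- function(act, path, ic50 = TRUE, delim = ",") {
    val <- if (ic50) act@ic50 else act@logIC50
    lines <- c(paste(c("compound", if (ic50) "ic50_nM" else "log10_ic50"),
                     collapse = delim),
               paste(act@compoundIds, format(val, digits = 17), sep = delim))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a subset partition
#'
#' Two-column delimited text: compound id and subset label
#' (train/val/test).
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return \code{readPartition}: a \linkS4class{SubsetPartition}.
#' @export
readPartition <- function(path, delim = NULL) {
    if (is.null(delim)) delim <- .detectDelim(path)
    tab <- utils::read.table(path, sep = delim, header = TRUE,
                             colClasses = "character", strip.white = TRUE)
    SubsetPartition(tab[[1L]], tab[[2L]])
}

#' @rdname readPartition
#' @param part a \linkS4class{SubsetPartition}.
#' @export
writePartition <- function(part, path, delim = ",") {
    lines <- c(paste(c("compound", "subset"), collapse = delim),
               paste(part@compoundIds, as.character(part@labels), sep = delim))
    writeLines(lines, path)
    invisible(path)
}

#' Align a descriptor matrix with an activity set
#'
#' Restricts both objects to the intersection of their compound ids, in the
#' descriptor matrix's order, and reports how many ids were dropped from
#' each side.
#'
#' @param dm a \linkS4class{DescriptorMatrix}.
#' @param act an \linkS4class{ActivitySet}.
#' @return List with elements \code{descriptors}, \code{activities},
#'   \code{droppedDescriptors}, \code{droppedActivities}.
#' @export
alignCompounds <- function(dm, act) {
    idsD <- compoundIds(dm); idsA <- compoundIds(act)
    common <- idsD[idsD %in% idsA]
    if (!length(common))
        stop("no compound ids shared between descriptors and activities")
    dropD <- length(idsD) - length(common)
    dropA <- length(idsA) - length(common)
    if (dropD + dropA > 0)
        message("alignCompounds: dropped ", dropD, " descriptor row(s) and ",
                dropA, " activity entry(ies) outside the id intersection")
    idx <- match(common, idsA)
    list(descriptors = dm[common, ],
         activities = new("ActivitySet", compoundIds = common,
                          ic50 = act@ic50[idx], logIC50 = act@logIC50[idx]),
         droppedDescriptors = dropD, droppedActivities = dropA)
}

# key = value summary files (reports, planted truth)
.writeKeyValue <- function(x, path) {
    vals <- vapply(x, function(v)
        paste(format(v, digits = 15), collapse = " "), character(1))
    writeLines(paste(names(x), vals, sep = " = "), path)
    invisible(path)
}

#' Write a planted-truth record
#'
#' Serializes the generating model of a synthetic dataset (intercept,
#' coefficients, signal descriptor names, noise SD) as a key-value text
#' file.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generateSynthetic}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
    .writeKeyValue(list(
        signal_names = paste(truth$signalNames, collapse = " "),
        beta0 = truth$beta0,
        beta = paste(format(truth$beta, digits = 15), collapse = " "),
        noise_sd = truth$noiseSd,
        activity_scale = truth$activityScale), path)
}
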