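## Regression-to-classification scoring: compounds at or below an IC50
## threshold (default 1000 nM) are the highly active class; observed and
## predicted activities are classified with the same rule and scored with
## the Cooper statistics (accuracy, sensitivity, specificity) and the
## Matthews correlation coefficient.

#' Classify predictions and score against observations
#'
#' Applies the activity threshold in log space (\code{log10 IC50 <=
#' log10(thresholdNM)}; a compound at exactly the threshold is active) to
#' both observed and predicted activities, builds the confusion matrix with
#' active as the positive class, and computes accuracy (percent),
#' sensitivity, specificity and MCC. Any zero factor in the MCC
#' denominator yields MCC = 0 by convention.
#'
#' @param yObsLog,yPredLog observed and predicted log10 IC50 (equal
#'   length).
#' @param thresholdNM activity threshold in nM (> 0, default 1000).
#' @return List with \code{thresholdNM}, counts \code{tp, fp, tn, fn},
#'   \code{accuracyPct}, \code{sensitivity}, \code{specificity},
#'   \code{mcc}.
#' @examples
#' classifyAndScore(c(2, 3, 4), c(2.5, 2.9, 4.2))
#' @export
classifyAndScore <- function(yObsLog, yPredLog, thresholdNM = 1000) {
    yObsLog <- as.numeric(yObsLog); yPredLog <- as.numeric(yPredLog)
    if (length(yObsLog) != length(yPredLog))
        stop("observed and predicted lengths differ")
    if (!is.numeric(thresholdNM) || length(thresholdNM) != 1L ||
        thresholdNM <= 0)
        stop("'thresholdNM' must be a positive scalar")
    thr <- log10(thresholdNM)
    obsAct <- yObsLog <= thr
    prdAct <- yPredLog <= thr
    tp <- sum(obsAct & prdAct); fn <- sum(obsAct & !prdAct)
    fp <- sum(!obsAct & prdAct); tn <- sum(!obsAct & !prdAct)
    n <- tp + fp + tn + fn
    se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    denomFactors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    mcc <- if (any(denomFactors == 0)) 0
           else (tp * tn - fp * fn) / sqrt(prod(denomFactors))
    list(thresholdNM = thresholdNM, tp = tp, fp = fp, tn = tn, fn = fn,
         accuracyPct = if (n > 0) 100 * (tp + tn) / n else NA_real_,
         sensitivity = se, specificity = sp, mcc = mcc)
}

#' Write a classification report
#'
#' Confusion matrix plus Cooper statistics and MCC as CSV.
#'
#' @param report result of \code{\link{classifyAndScore}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeClassificationReport <- function(report, path) {
    tab <- data.frame(
        statistic = c("threshold_nM", "tp", "fp", "tn", "fn",
                      "accuracy_pct", "sensitivity", "specificity", "mcc"),
        value = c(report$thresholdNM, report$tp, report$fp, report$tn,
                  report$fn, report$accuracyPct, report$sensitivity,
                  report$specificity, report$mcc))
    utils::write.csv(tab, path, row.names = FALSE)
    invisible(path)
}
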