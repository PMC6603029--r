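#' Threshold classification of likelihood scores
#'
#' A nodule is called malignant (1) iff y >= threshold, benign (0)
#' otherwise; the boundary is inclusive and the published operating point
#' is 0.51.
#'
#' @param y numeric vector of likelihood scores (must be finite).
#' @param threshold decision threshold (default 0.51).
#' @return integer vector of 0/1 predicted labels.
#' @examples
#' classifyMalignant(c(0.51, 0.509))  # 1 0
#' @export
classifyMalignant <- function(y, threshold = 0.51) {
    if (any(!is.finite(y))) stop("scores must be finite")
    as.integer(y >= threshold)
}

#' Confusion matrix from true and predicted labels
#'
#' Positive = malignant = 1. TP/FN/FP/TN follow the usual conventions:
#' TP = correctly called malignant, FN = malignant called benign,
#' FP = benign called malignant, TN = correctly called benign.
#'
#' @param truth,predicted binary 0/1 vectors of equal length.
#' @return an [EvalReport-class] carrying the counts and the derived
#'   metrics (no ROC; combine with [rocAuc()] or use [evaluateScores()]).
#' @export
confusionMatrix <- function(truth, predicted) {
    if (length(truth) != length(predicted))
        stop("truth and predicted must have equal length")
    if (!length(truth)) stop("empty input")
    if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
        stop("labels must be binary 0/1")
    evalReport(tp = sum(truth == 1 & predicted == 1),
               fn = sum(truth == 1 & predicted == 0),
               fp = sum(truth == 0 & predicted == 1),
               tn = sum(truth == 0 & predicted == 0))
}

.safe_ratio <- function(num, den, what) {
    if (den == 0) {
        warning(what, " undefined (zero denominator); reported as NA")
        return(NA_real_)
    }
    num / den
}

#' Diagnostic metrics from confusion counts
#'
#' Computes accuracy = (TP+TN)/(TP+FN+FP+TN) together with both metric
#' conventions: the aliases that reproduce the source models' reported
#' numbers, `paperSensitivity` = TP/(TP+FP) and `paperSpecificity` =
#' TN/(TN+FN), and the standard epidemiological `stdSensitivity` =
#' TP/(TP+FN) and `stdSpecificity` = TN/(TN+FP). Ratios with a zero
#' denominator are NA with a warning.
#'
#' @param tp,fn,fp,tn non-negative integer counts (total >= 1).
#' @param roc optional data.frame of (fpr, tpr) points.
#' @param auc optional area under the ROC.
#' @return an [EvalReport-class].
#' @examples
#' evalReport(tp = 155, fn = 10, fp = 7, tn = 28)
#' @export
evalReport <- function(tp, fn, fp, tn,
                       roc = data.frame(fpr = numeric(0),
                                        tpr = numeric(0)),
                       auc = NA_real_) {
    counts <- c(tp, fn, fp, tn)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    total <- sum(counts)
    if (total == 0) stop("all-zero confusion matrix")
    new("EvalReport",
        tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
        tn = as.integer(tn),
        accuracy = (tp + tn) / total,
        paperSensitivity = .safe_ratio(tp, tp + fp, "paperSensitivity"),
        paperSpecificity = .safe_ratio(tn, tn + fn, "paperSpecificity"),
        stdSensitivity = .safe_ratio(tp, tp + fn, "stdSensitivity"),
        stdSpecificity = .safe_ratio(tn, tn + fp, "stdSpecificity"),
        roc = roc, auc = auc)
}

#' @rdname radiolik-generics
#' @export
setMethod("confusionCounts", "EvalReport", function(x)
    c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn))

#' Coerce an EvalReport's metrics to a named list
#'
#' @param x an [EvalReport-class].
#' @return named list of counts and metrics (proportions in [0, 1]).
#' @export
metricsList <- function(x) {
    stopifnot(is(x, "EvalReport"))
    list(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn,
         accuracy = x@accuracy,
         paper_sensitivity = x@paperSensitivity,
         paper_specificity = x@paperSpecificity,
         std_sensitivity = x@stdSensitivity,
         std_specificity = x@stdSpecificity,
         auc = x@auc)
}

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport: TP %d  FN %d  FP %d  TN %d\n",
                object@tp, object@fn, object@fp, object@tn))
    cat(sprintf("  accuracy %.4f | sensitivity TP/(TP+FP) %.4f | specificity TN/(TN+FN) %.4f\n",
                object@accuracy, object@paperSensitivity,
                object@paperSpecificity))
    cat(sprintf("  std sensitivity %.4f | std specificity %.4f | AUC %s\n",
                object@stdSensitivity, object@stdSpecificity,
                ifelse(is.na(object@auc), "-",
                       sprintf("%.4f", object@auc))))
})

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision rule y >= t over all distinct observed scores
#' (plus the +/- infinity endpoints), grouping tied scores into a single
#' threshold step; TPR = TP/(TP+FN), FPR = FP/(FP+TN). The AUC is the
#' trapezoidal integral, which equals the Mann-Whitney pair-counting
#' statistic with ties counted 1/2.
#'
#' @param scores numeric vector of likelihood scores.
#' @param truth binary 0/1 labels (both classes must be present).
#' @return list with `roc` (data.frame of fpr, tpr, sorted from (0,0) to
#'   (1,1)) and `auc`.
#' @export
rocAuc <- function(scores, truth) {
    if (length(scores) != length(truth))
        stop("scores and truth must have equal length")
    if (!all(truth %in% c(0, 1))) stop("labels must be binary 0/1")
    npos <- sum(truth == 1); nneg <- sum(truth == 0)
    if (npos == 0 || nneg == 0)
        stop("both classes must be present for a ROC curve")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- truth[ord]
    # group tied scores into single steps
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(y == 1); fp <- cumsum(y == 0)
    last <- !duplicated(grp, fromLast = TRUE)
    tpr <- c(0, tp[last] / npos)
    fpr <- c(0, fp[last] / nneg)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Full evaluation of likelihood scores against true labels
#'
#' Thresholds the scores with [classifyMalignant()], tallies the confusion
#' matrix, computes all metrics and the ROC/AUC.
#'
#' @param scores numeric vector of likelihood scores.
#' @param truth binary 0/1 true labels.
#' @param threshold decision threshold (default 0.51).
#' @return an [EvalReport-class].
#' @export
evaluateScores <- function(scores, truth, threshold = 0.51) {
    pred <- classifyMalignant(scores, threshold)
    cm <- confusionMatrix(truth, pred)
    ra <- if (length(unique(truth)) == 2) rocAuc(scores, truth)
          else list(roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
                    auc = NA_real_)
    evalReport(cm@tp, cm@fn, cm@fp, cm@tn, roc = ra$roc, auc = ra$auc)
}

#' Write an evaluation report to JSON
#'
#' Counts, all metrics and the ROC points.
#'
#' @param report an [EvalReport-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEvalReport <- function(report, path) {
    out <- metricsList(report)
    out$roc <- report@roc
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "columns")
    invisible(path)
}
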