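#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom stats cor dist kruskal.test pchisq rnorm runif sd var
#'   setNames predict coef
#' @importFrom utils read.csv write.csv
NULL

.FEATURE_CLASSES <- c("shape", "firstorder", "glcm", "gldm", "glszm",
                      "glrlm", "ngtdm")

#' RadiomicsExperiment: a radiomic feature table
#'
#' Container for a cohort of tumors/nodules with named radiomic features,
#' built on \link[SummarizedExperiment]{SummarizedExperiment}: features are
#' rows, samples are columns. `rowData()` carries the feature-class
#' annotation (`featureClass`, one of shape / firstorder / glcm / gldm /
#' glszm / glrlm / ngtdm) and the derived `kind` (shape vs texture);
#' `colData()` carries the optional binary malignancy label (`label`,
#' 0 = benign, 1 = malignant).
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("RadiomicsExperiment", contains = "SummarizedExperiment")

setValidity("RadiomicsExperiment", function(object) {
    msg <- NULL
    v <- assay(object)
    if (!is.numeric(v))
        msg <- c(msg, "feature values must be numeric")
    else if (length(v) && any(!is.finite(v)))
        msg <- c(msg, "feature values must all be finite")
    rn <- rownames(object)
    if (nrow(object) > 0 && (is.null(rn) || anyDuplicated(rn)))
        msg <- c(msg, "feature names must be present and unique")
    cn <- colnames(object)
    if (ncol(object) > 0 && (is.null(cn) || anyDuplicated(cn)))
        msg <- c(msg, "sample ids must be present and unique")
    rd <- rowData(object)
    if (!all(c("featureClass", "kind") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'featureClass' and 'kind'")
    else {
        fc <- as.character(rd$featureClass)
        if (!all(fc %in% .FEATURE_CLASSES))
            msg <- c(msg, "featureClass entries must be one of the seven radiomic classes")
        kd <- as.character(rd$kind)
        if (!identical(kd, as.character(ifelse(fc == "shape",
                                               "shape", "texture"))))
            msg <- c(msg, "kind must be 'shape' iff featureClass is 'shape', else 'texture'")
    }
    if ("label" %in% colnames(colData(object))) {
        lab <- colData(object)$label
        if (!all(lab %in% c(0L, 1L)))
            msg <- c(msg, "labels must be 0 (benign) or 1 (malignant)")
    }
    if (is.null(msg)) TRUE else msg
})

#' LikelihoodModel: a two-feature nonlinear likelihood function
#'
#' Holds one of the two published functional forms. `MLF1` is
#' y = a + b ln(x1) + c ln(x1^2) + d/x2 + e/x2^2 + f/x2^3 + g/x2^4 with
#' x1 = tumor volume and x2 = large-area low-gray-level emphasis (LALGLE);
#' `MLF2` is y = a + b x1 + c x1^2 + d x1^3 + e x1^4 + f ln(x2) with
#' x1 = surface-to-volume ratio (SVR) and x2 = GLCM sum entropy.
#' y near 1 indicates malignancy, near 0 benignity.
#'
#' @slot formId character, "MLF1" or "MLF2".
#' @slot coefficients named numeric, length 7 (MLF1: a-g) or 6 (MLF2: a-f).
#' @slot residualSE numeric, residual standard error of the y estimates
#'   (NA when unknown).
#' @slot x1Feature,x2Feature character, names of the bound feature columns.
#' @slot squaredLog logical; for MLF1 only, interpret the printed
#'   "ln(x1^2)" term as (ln x1)^2 instead of the literal ln(x1^2) = 2 ln(x1).
#' @export
setClass("LikelihoodModel",
    representation(formId = "character", coefficients = "numeric",
                   residualSE = "numeric", x1Feature = "character",
                   x2Feature = "character", squaredLog = "logical"),
    prototype(residualSE = NA_real_, x1Feature = NA_character_,
              x2Feature = NA_character_, squaredLog = FALSE))

setValidity("LikelihoodModel", function(object) {
    msg <- NULL
    if (!object@formId %in% c("MLF1", "MLF2"))
        msg <- c(msg, "formId must be 'MLF1' or 'MLF2'")
    p <- if (identical(object@formId, "MLF1")) 7L else 6L
    if (length(object@coefficients) != p)
        msg <- c(msg, sprintf("%s requires %d coefficients", object@formId, p))
    if (any(!is.finite(object@coefficients)))
        msg <- c(msg, "coefficients must be finite")
    if (length(object@residualSE) != 1 ||
        (!is.na(object@residualSE) &&
         (!is.finite(object@residualSE) || object@residualSE < 0)))
        msg <- c(msg, "residualSE must be a single non-negative number or NA")
    if (is.null(msg)) TRUE else msg
})

#' RankerOutput: raw scores from one feature-ranking algorithm
#'
#' @slot rankerName character, algorithm identifier.
#' @slot scores named numeric vector, one finite score per feature.
#' @slot orientation character, "higher_better" or "lower_better".
#' @export
setClass("RankerOutput",
    representation(rankerName = "character", scores = "numeric",
                   orientation = "character"))

setValidity("RankerOutput", function(object) {
    msg <- NULL
    if (!object@orientation %in% c("higher_better", "lower_better"))
        msg <- c(msg, "orientation must be higher_better or lower_better")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must all be finite")
    if (is.null(names(object@scores)))
        msg <- c(msg, "scores must be named by feature")
    if (is.null(msg)) TRUE else msg
})

#' ReliabilityReport: per-feature reliability / discriminability screen
#'
#' @slot results data.frame with columns `feature`, `ccc` (Lin's concordance
#'   correlation across test-retest pairs; NA when not computed), `kw_p`
#'   (Kruskal-Wallis p-value against the binary label; NA when not computed)
#'   and `retained` (logical conjunction of the requested gates).
#' @slot cccMin numeric, CCC retention threshold (strict `>`); NA if the CCC
#'   gate was not requested.
#' @slot alpha numeric, Kruskal-Wallis significance level (strict `<`); NA if
#'   the discriminability gate was not requested.
#' @export
setClass("ReliabilityReport",
    representation(results = "data.frame", cccMin = "numeric",
                   alpha = "numeric"))

setValidity("ReliabilityReport", function(object) {
    need <- c("feature", "ccc", "kw_p", "retained")
    if (!all(need %in% colnames(object@results)))
        return("results must have columns feature, ccc, kw_p, retained")
    TRUE
})

#' ConsensusRanking: equal-weight consensus over a bank of rankers
#'
#' @slot group character, "supervised" or "unsupervised".
#' @slot scores data.frame ordered by rank, with columns `feature`, one
#'   normalized-score column per ranker (oriented higher-is-better and
#'   min-max scaled to [0, 1]), `consensus` (their equal-weight mean) and
#'   `rank` (1 = best; ties broken by ascending feature name).
#' @slot rankers character, names of the contributing rankers.
#' @slot method character, "score" (normalized-score averaging) or "rank"
#'   (mean rank position) commensuration.
#' @export
setClass("ConsensusRanking",
    representation(group = "character", scores = "data.frame",
                   rankers = "character", method = "character"))

setValidity("ConsensusRanking", function(object) {
    msg <- NULL
    sc <- object@scores
    if (!all(c("feature", "consensus", "rank") %in% colnames(sc)))
        msg <- c(msg, "scores must have feature, consensus and rank columns")
    else if (nrow(sc) && !setequal(sc$rank, seq_len(nrow(sc))))
        msg <- c(msg, "ranks must be a permutation of 1..n_features")
    if (is.null(msg)) TRUE else msg
})

#' RadiomicSignature: one shape + one texture feature
#'
#' @slot shapeFeature character, name of the shape-class feature.
#' @slot textureFeature character, name of the texture (non-shape) feature.
#' @slot sourceGroup character, ranking group the signature came from.
#' @export
setClass("RadiomicSignature",
    representation(shapeFeature = "character", textureFeature = "character",
                   sourceGroup = "character"))

#' EvalReport: confusion matrix, diagnostic metrics and ROC
#'
#' Metric conventions follow the source models' reporting: alongside the
#' standard epidemiological sensitivity TP/(TP+FN) and specificity
#' TN/(TN+FP), the report exposes `paperSensitivity` = TP/(TP+FP) and
#' `paperSpecificity` = TN/(TN+FN), the ratios reported under the names
#' "sensitivity"/"specificity" in the originating study. Undefined ratios
#' (zero denominator) are NA.
#'
#' @slot tp,fn,fp,tn integer counts (positive = malignant = 1).
#' @slot accuracy,paperSensitivity,paperSpecificity,stdSensitivity,stdSpecificity
#'   numeric metrics in [0, 1] (NA when undefined).
#' @slot roc data.frame of (`fpr`, `tpr`) points from the threshold sweep
#'   (empty when scores were unavailable).
#' @slot auc numeric, trapezoidal area under the ROC (NA when unavailable).
#' @export
setClass("EvalReport",
    representation(tp = "integer", fn = "integer", fp = "integer",
                   tn = "integer", accuracy = "numeric",
                   paperSensitivity = "numeric", paperSpecificity = "numeric",
                   stdSensitivity = "numeric", stdSpecificity = "numeric",
                   roc = "data.frame", auc = "numeric"),
    prototype(roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
              auc = NA_real_))

setValidity("EvalReport", function(object) {
    counts <- c(object@tp, object@fn, object@fp, object@tn)
    if (any(counts < 0)) return("confusion counts must be non-negative")
    TRUE
})
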