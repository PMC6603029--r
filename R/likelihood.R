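## The two published likelihood functional forms, their exact printed
## coefficients, and least-squares fitting of the same forms to new data.

.MLF1_COEF <- c(a = -2.45226185349294,
                b = 0.568013700683048,
                c = -2.32311348575522e-02,
                d = -2.68371595182609e-02,
                e = 3.61336660703077e-03,
                f = -1.08094045817984e-04,
                g = 9.40291849279405e-07)

.MLF2_COEF <- c(a = 0.747801694861307,
                b = 2.22684037581268,
                c = -5.58568390095777,
                d = 3.631765847909,
                e = -0.730551994128231,
                f = 1.28142101694647e-02)

#' Basis expansion for the MLF I functional form
#'
#' y = a + b ln(x1) + c ln(x1^2) + d/x2 + e/x2^2 + f/x2^3 + g/x2^4, where
#' x1 is the tumor volume (mm^3) and x2 the large-area low-gray-level
#' emphasis. The third basis function is the literal ln(x1^2) = 2 ln(x1),
#' exactly as the form is printed, which makes the basis rank-deficient by
#' construction (only b + 2c is identifiable); set `squaredLog = TRUE` for
#' the alternative (ln x1)^2 reading.
#'
#' @param x1,x2 numeric vectors (recycled to a common length); requires
#'   x1 > 0 and x2 != 0.
#' @param squaredLog interpret the third term as (ln x1)^2.
#' @return numeric matrix with columns a..g (n x 7).
#' @export
basisMLF1 <- function(x1, x2, squaredLog = FALSE) {
    n <- max(length(x1), length(x2))
    x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
    if (any(!is.finite(x1)) || any(!is.finite(x2)))
        stop("x1 and x2 must be finite")
    if (any(x1 <= 0)) stop("MLF1 requires x1 > 0 (log domain)")
    if (any(x2 == 0)) stop("MLF1 requires x2 != 0 (reciprocal domain)")
    lx <- log(x1)
    cbind(a = rep(1, n), b = lx,
          c = if (squaredLog) lx^2 else 2 * lx,
          d = 1 / x2, e = 1 / x2^2, f = 1 / x2^3, g = 1 / x2^4)
}

#' Basis expansion for the MLF II functional form
#'
#' y = a + b x1 + c x1^2 + d x1^3 + e x1^4 + f ln(x2), where x1 is the
#' surface-to-volume ratio and x2 the GLCM sum entropy.
#'
#' @param x1,x2 numeric vectors (recycled to a common length); requires
#'   x2 > 0.
#' @return numeric matrix with columns a..f (n x 6).
#' @export
basisMLF2 <- function(x1, x2) {
    n <- max(length(x1), length(x2))
    x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
    if (any(!is.finite(x1)) || any(!is.finite(x2)))
        stop("x1 and x2 must be finite")
    if (any(x2 <= 0)) stop("MLF2 requires x2 > 0 (log domain)")
    cbind(a = rep(1, n), b = x1, c = x1^2, d = x1^3, e = x1^4,
          f = log(x2))
}

.basis <- function(model, x1, x2) {
    if (model@formId == "MLF1") basisMLF1(x1, x2, model@squaredLog)
    else basisMLF2(x1, x2)
}

#' Construct a LikelihoodModel
#'
#' @param formId "MLF1" or "MLF2".
#' @param coefficients numeric vector (length 7 for MLF1, 6 for MLF2);
#'   names a..g are applied.
#' @param residualSE residual standard error of the y estimates (NA when
#'   unknown).
#' @param x1Feature,x2Feature names of the feature columns bound to x1
#'   and x2.
#' @param squaredLog MLF1 only: use the (ln x1)^2 reading of the third
#'   basis term.
#' @return a [LikelihoodModel-class].
#' @export
LikelihoodModel <- function(formId, coefficients, residualSE = NA_real_,
                            x1Feature = NA_character_,
                            x2Feature = NA_character_, squaredLog = FALSE) {
    coefficients <- setNames(as.numeric(coefficients),
                             letters[seq_along(coefficients)])
    new("LikelihoodModel", formId = formId, coefficients = coefficients,
        residualSE = as.numeric(residualSE), x1Feature = x1Feature,
        x2Feature = x2Feature, squaredLog = squaredLog)
}

#' The published likelihood models with their printed coefficients
#'
#' Returns MLF I (x1 = tumor volume, x2 = LALGLE; residual standard error
#' 0.30) or MLF II (x1 = surface-to-volume ratio, x2 = sum entropy;
#' residual standard error 0.20) with every coefficient at full printed
#' precision. The pretrained MLF I always uses the literal ln(x1^2)
#' reading, since the printed coefficients belong to the printed form.
#'
#' @param formId "MLF1" or "MLF2".
#' @return a [LikelihoodModel-class].
#' @examples
#' pretrainedModel("MLF2")
#' @export
pretrainedModel <- function(formId = c("MLF1", "MLF2")) {
    formId <- match.arg(formId)
    if (formId == "MLF1")
        LikelihoodModel("MLF1", .MLF1_COEF, residualSE = 0.30,
                        x1Feature = "shape_Volume",
                        x2Feature = "glszm_LargeAreaLowGrayLevelEmphasis")
    else
        LikelihoodModel("MLF2", .MLF2_COEF, residualSE = 0.20,
                        x1Feature = "shape_SurfaceVolumeRatio",
                        x2Feature = "glcm_SumEntropy")
}

#' Evaluate a likelihood model
#'
#' y = coefficients . basis(x1, x2); the result is an unbounded real (no
#' clamping to [0, 1]) — values near 1 indicate malignancy, near 0
#' benignity. Domain violations (x1 <= 0 for MLF1, x2 <= 0, ...) raise
#' errors; `clipEps`, when given, substitutes that positive floor for
#' out-of-domain values instead, for pipeline robustness.
#'
#' @param object a [LikelihoodModel-class].
#' @param x1,x2 numeric vectors of feature values.
#' @param clipEps optional positive floor applied to x1 and x2 before
#'   evaluation.
#' @return numeric vector of y scores.
#' @export
predictLikelihood <- function(object, x1, x2, clipEps = NULL) {
    stopifnot(is(object, "LikelihoodModel"))
    if (!is.null(clipEps)) {
        stopifnot(clipEps > 0)
        x1 <- pmax(x1, clipEps); x2 <- pmax(x2, clipEps)
    }
    drop(.basis(object, x1, x2) %*% object@coefficients)
}

#' @describeIn predictLikelihood predict method; `newdata` may be a
#'   [RadiomicsExperiment-class] (features taken from the model's bindings)
#'   or a data.frame/list with elements `x1` and `x2`.
#' @param newdata input data for prediction.
#' @param ... passed on to `predictLikelihood` (e.g. `clipEps`).
#' @export
predict.LikelihoodModel <- function(object, newdata, ...) {
    if (is(newdata, "RadiomicsExperiment")) {
        miss <- setdiff(c(object@x1Feature, object@x2Feature),
                        rownames(newdata))
        if (length(miss))
            stop("features not present in table: ",
                 paste(miss, collapse = ", "))
        v <- assay(newdata, "features")
        predictLikelihood(object, v[object@x1Feature, ],
                          v[object@x2Feature, ], ...)
    } else {
        predictLikelihood(object, newdata$x1, newdata$x2, ...)
    }
}

#' Fit a likelihood functional form by least squares
#'
#' Ordinary least squares of y (typically the 0/1 malignancy state) on the
#' basis-expanded design matrix — for these linear-in-coefficients forms
#' this is the minimum-RSS solution. The solution is computed with the SVD
#' pseudoinverse, so a rank-deficient design (MLF1's printed basis is
#' exactly collinear: the ln(x1^2) column equals twice the ln(x1) column)
#' yields the minimum-norm coefficient vector; predictions are invariant
#' to the deficiency and the combination b + 2c is identified. The
#' residual standard error is sqrt(RSS / (n - p_eff)) with p_eff the
#' numerical rank of the design.
#'
#' @param formId "MLF1" or "MLF2".
#' @param x1,x2 numeric feature vectors (within the form's domain).
#' @param y numeric response (0/1 labels or real).
#' @param x1Feature,x2Feature optional feature-name bindings stored on the
#'   model.
#' @param squaredLog MLF1 only: fit the (ln x1)^2 variant of the third
#'   basis term.
#' @return a fitted [LikelihoodModel-class].
#' @export
fitLikelihood <- function(formId = c("MLF1", "MLF2"), x1, x2, y,
                          x1Feature = NA_character_,
                          x2Feature = NA_character_, squaredLog = FALSE) {
    formId <- match.arg(formId)
    n <- length(y)
    if (length(x1) != n || length(x2) != n)
        stop("x1, x2 and y must have equal length")
    if (any(!is.finite(y))) stop("y must be finite")
    X <- if (formId == "MLF1") basisMLF1(x1, x2, squaredLog)
         else basisMLF2(x1, x2)
    p <- ncol(X)
    if (n < p)
        stop("need at least ", p, " observations to fit ", formId)
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    r <- sum(sv$d > tol)
    if (r == 0) stop("degenerate design: all basis columns are zero")
    dinv <- c(1 / sv$d[seq_len(r)], rep(0, p - r))
    coef <- drop(sv$v %*% (dinv * crossprod(sv$u, y)))
    fitted <- drop(X %*% coef)
    rss <- sum((y - fitted)^2)
    dfres <- n - r
    rse <- if (dfres > 0) sqrt(rss / dfres) else 0
    LikelihoodModel(formId, coef, residualSE = rse,
                    x1Feature = x1Feature, x2Feature = x2Feature,
                    squaredLog = squaredLog)
}

#' @rdname radiolik-generics
#' @export
setMethod("formId", "LikelihoodModel", function(x) x@formId)

#' @rdname radiolik-generics
#' @export
setMethod("residualSE", "LikelihoodModel", function(x) x@residualSE)

#' Coefficients of a likelihood model
#'
#' @param object a [LikelihoodModel-class].
#' @param ... ignored.
#' @return named numeric vector (a..g for MLF1, a..f for MLF2).
#' @exportS3Method stats::coef
coef.LikelihoodModel <- function(object, ...) object@coefficients

setMethod("show", "LikelihoodModel", function(object) {
    cat("LikelihoodModel", object@formId,
        if (object@formId == "MLF1" && object@squaredLog)
            "[(ln x1)^2 variant]" else "", "\n")
    cat("  x1 =", object@x1Feature, ", x2 =", object@x2Feature, "\n")
    print(signif(object@coefficients, 6))
    cat("  residual SE:", format(object@residualSE), "\n")
})

#' Read / write a likelihood model as JSON
#'
#' The interchange schema has keys form_id, coefficients, residual_se,
#' x1_feature, x2_feature (and optionally squared_log).
#'
#' @param model a [LikelihoodModel-class].
#' @param path JSON file path.
#' @return `writeLikelihoodModel`: invisibly, `path`;
#'   `readLikelihoodModel`: a [LikelihoodModel-class].
#' @export
writeLikelihoodModel <- function(model, path) {
    jsonlite::write_json(
        list(form_id = model@formId,
             coefficients = as.list(model@coefficients),
             residual_se = model@residualSE,
             x1_feature = model@x1Feature, x2_feature = model@x2Feature,
             squared_log = model@squaredLog),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeLikelihoodModel
#' @export
readLikelihoodModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    LikelihoodModel(j$form_id, unlist(j$coefficients),
                    residualSE = if (is.null(j$residual_se)) NA_real_
                                 else j$residual_se,
                    x1Feature = j$x1_feature, x2Feature = j$x2_feature,
                    squaredLog = isTRUE(j$squared_log))
}
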