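#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements, combining precision (correlation)
#' with accuracy (mean/variance shift):
#' CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2).
#' The default uses population (1/n) moments, the original estimator; set
#' `moments = "sample"` for the 1/(n-1) variant.
#'
#' @param x,y numeric vectors of equal length >= 2 (e.g. a feature measured
#'   on a test and a retest scan of the same subjects).
#' @param moments "population" (default) or "sample".
#' @return a number in [-1, 1].
#' @examples
#' concordanceCorrelation(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
concordanceCorrelation <- function(x, y,
                                   moments = c("population", "sample")) {
    moments <- match.arg(moments)
    if (length(x) != length(y)) stop("x and y must have equal length")
    n <- length(x)
    if (n < 2) stop("need at least 2 paired observations")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("x and y must be finite")
    mx <- mean(x); my <- mean(y)
    denomn <- if (moments == "population") n else n - 1
    vx <- sum((x - mx)^2) / denomn
    vy <- sum((y - my)^2) / denomn
    sxy <- sum((x - mx) * (y - my)) / denomn
    denom <- vx + vy + (mx - my)^2
    if (denom == 0)
        stop("CCC undefined: both vectors constant with equal means")
    2 * sxy / denom
}

#' Kruskal-Wallis p-value for one feature against group labels
#'
#' Rank-based one-way test (H statistic with mid-rank ties and tie
#' correction; p from the chi-square approximation with groups - 1 degrees
#' of freedom), via [stats::kruskal.test()]. An all-tied feature (every
#' value identical) returns p = 1 with a warning rather than erroring, so
#' batch screening never aborts on a constant feature.
#'
#' @param values numeric vector.
#' @param groups vector of group labels (>= 2 distinct groups, total
#'   n >= 3).
#' @return the p-value.
#' @export
kruskalWallisP <- function(values, groups) {
    if (length(values) == 0) stop("empty input")
    if (length(values) != length(groups))
        stop("values and groups must have equal length")
    g <- factor(groups)
    g <- droplevels(g)
    if (nlevels(g) < 2) stop("need at least 2 groups")
    if (length(values) < 3) stop("need total n >= 3")
    if (length(unique(values)) == 1L) {
        warning("all values tied; Kruskal-Wallis degenerate, returning p = 1")
        return(1)
    }
    stats::kruskal.test(values, g)$p.value
}

#' Test-retest reliability and discriminability screen
#'
#' Two conjunctive gates reduce a radiomic feature set: (1) reliability —
#' per-feature Lin's CCC between the cohort's values and a paired retest
#' table must exceed `cccMin` (strict `>`); (2) discriminability — the
#' Kruskal-Wallis p-value of the feature against the binary malignancy
#' label must fall below `alpha` (strict `<`). Either gate can be switched
#' off by passing `retest = NULL` resp. `alpha = NULL`; a feature whose
#' statistic is undefined fails the corresponding gate only if that gate
#' was requested.
#'
#' @param x a labeled [RadiomicsExperiment-class] (labels required when
#'   `alpha` is non-NULL).
#' @param retest a paired [RadiomicsExperiment-class] with the same feature
#'   names, whose sample ids are all present in `x` (the retest cohort may
#'   be a subset of the samples), or NULL to skip the CCC gate.
#' @param cccMin CCC retention threshold (default 0.85).
#' @param alpha Kruskal-Wallis significance level (default 0.05), or NULL
#'   to skip the discriminability gate.
#' @param moments moment convention passed to [concordanceCorrelation()].
#' @return a [ReliabilityReport-class].
#' @export
reliabilityFilter <- function(x, retest = NULL, cccMin = 0.85, alpha = 0.05,
                              moments = c("population", "sample")) {
    stopifnot(is(x, "RadiomicsExperiment"))
    moments <- match.arg(moments)
    feats <- rownames(x)
    ccc <- rep(NA_real_, length(feats))
    kwp <- rep(NA_real_, length(feats))
    names(ccc) <- names(kwp) <- feats

    if (!is.null(retest)) {
        stopifnot(is(retest, "RadiomicsExperiment"))
        if (!setequal(rownames(retest), feats))
            stop("retest table must have the same feature names")
        if (!all(colnames(retest) %in% colnames(x)))
            stop("retest sample ids must all be present in the cohort table")
        a <- assay(x, "features")[feats, colnames(retest), drop = FALSE]
        b <- assay(retest, "features")[feats, colnames(retest), drop = FALSE]
        undef <- character(0)
        for (f in feats) {
            ccc[f] <- tryCatch(
                concordanceCorrelation(a[f, ], b[f, ], moments = moments),
                error = function(e) { NA_real_ })
            if (is.na(ccc[f])) undef <- c(undef, f)
        }
        if (length(undef))
            warning("CCC undefined for: ", paste(undef, collapse = ", "))
    }

    if (!is.null(alpha)) {
        if (!(is.numeric(alpha) && length(alpha) == 1 &&
              alpha > 0 && alpha <= 1))
            stop("alpha must be in (0, 1]")
        lab <- sampleLabels(x)
        if (is.null(lab))
            stop("labels required for the Kruskal-Wallis gate")
        vals <- assay(x, "features")
        kwp[feats] <- suppressWarnings(
            vapply(feats, function(f) kruskalWallisP(vals[f, ], lab),
                   numeric(1)))
    }

    pass_ccc <- if (is.null(retest)) rep(TRUE, length(feats))
                else !is.na(ccc) & ccc > cccMin
    pass_kw <- if (is.null(alpha)) rep(TRUE, length(feats))
               else !is.na(kwp) & kwp < alpha
    new("ReliabilityReport",
        results = data.frame(feature = feats, ccc = unname(ccc),
                             kw_p = unname(kwp),
                             retained = pass_ccc & pass_kw,
                             stringsAsFactors = FALSE, row.names = NULL),
        cccMin = if (is.null(retest)) NA_real_ else cccMin,
        alpha = if (is.null(alpha)) NA_real_ else alpha)
}

#' @rdname radiolik-generics
#' @export
setMethod("retainedFeatures", "ReliabilityReport", function(x)
    x@results$feature[x@results$retained])

#' Coerce a ReliabilityReport to a data.frame
#'
#' @param x a [ReliabilityReport-class].
#' @param row.names,optional ignored (standard coercion signature).
#' @param ... ignored.
#' @return data.frame with columns feature, ccc, kw_p, retained.
#' @export
setMethod("as.data.frame", "ReliabilityReport",
    function(x, row.names = NULL, optional = FALSE, ...) x@results)

setMethod("show", "ReliabilityReport", function(object) {
    r <- object@results
    cat("ReliabilityReport:", nrow(r), "features,",
        sum(r$retained), "retained\n")
    cat(sprintf("  gates: CCC > %s, Kruskal-Wallis p < %s\n",
                format(object@cccMin), format(object@alpha)))
})

#' Write a reliability report to CSV
#'
#' Columns: feature, ccc, kw_p, retained.
#'
#' @param report a [ReliabilityReport-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeReliabilityReport <- function(report, path) {
    write.csv(format(report@results, digits = 15, trim = TRUE,
                     scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
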