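#' Equal-weight consensus over a bank of ranker outputs
#'
#' Each ranker's scores are oriented to higher-is-better (lower_better
#' scores are negated), min-max normalized to [0, 1] per ranker (a
#' constant ranker maps to all 0.5 with a warning), and averaged with
#' equal weights; features are ranked by descending consensus, ties broken
#' by ascending feature name. `method = "rank"` averages rank positions
#' instead of normalized scores (the consensus is then reported as a
#' mean-rank-derived score, still higher-is-better).
#'
#' @param outputs list of [RankerOutput-class] objects covering the same
#'   feature set.
#' @param group label stored on the result ("supervised", "unsupervised",
#'   or any descriptive string).
#' @param method "score" (default, normalized-score averaging) or "rank"
#'   (mean of rank positions).
#' @return a [ConsensusRanking-class].
#' @export
consensusRank <- function(outputs, group = "custom",
                          method = c("score", "rank")) {
    method <- match.arg(method)
    if (!length(outputs)) stop("need at least one ranker output")
    stopifnot(all(vapply(outputs, is, logical(1), "RankerOutput")))
    feats <- names(outputs[[1]]@scores)
    for (o in outputs)
        if (!setequal(names(o@scores), feats))
            stop("feature-set mismatch across rankers (",
                 o@rankerName, ")")
    norm <- lapply(outputs, function(o) {
        s <- o@scores[feats]
        if (o@orientation == "lower_better") s <- -s
        if (method == "rank") {
            # mean rank position, mapped so higher = better
            r <- rank(-s, ties.method = "average")
            return((length(s) - r) / max(1, length(s) - 1))
        }
        rng <- diff(range(s))
        if (rng == 0) {
            warning("ranker '", o@rankerName,
                    "' is constant; normalized scores set to 0.5")
            return(setNames(rep(0.5, length(s)), feats))
        }
        (s - min(s)) / rng
    })
    names(norm) <- vapply(outputs, function(o) o@rankerName, character(1))
    mat <- do.call(cbind, norm)
    consensus <- rowMeans(mat)
    ord <- order(-consensus, feats)
    sc <- data.frame(feature = feats, mat, consensus = consensus,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     row.names = NULL)
    sc <- sc[ord, , drop = FALSE]
    sc$rank <- seq_len(nrow(sc))
    rownames(sc) <- NULL
    new("ConsensusRanking", group = group, scores = sc,
        rankers = names(norm), method = method)
}

#' @rdname radiolik-generics
#' @export
setMethod("consensusScores", "ConsensusRanking", function(x) x@scores)

setMethod("show", "ConsensusRanking", function(object) {
    cat("ConsensusRanking (", object@group, "): ",
        nrow(object@scores), " features, rankers: ",
        paste(object@rankers, collapse = ", "), "\n", sep = "")
    print(utils::head(object@scores[, c("feature", "consensus", "rank")], 5))
})

#' Select a shape + texture diagnostic signature
#'
#' From the top-`topK` entries of a consensus ranking, picks the
#' highest-ranked shape-class feature and the highest-ranked texture
#' (non-shape) feature. Shape and texture carry complementary information
#' about a nodule, so the pair can serve as two quasi-independent
#' covariates of a likelihood model.
#'
#' @param ranking a [ConsensusRanking-class].
#' @param kinds named character vector mapping each feature to
#'   "shape"/"texture", or a [RadiomicsExperiment-class] from which
#'   [featureKinds()] is taken.
#' @param topK size of the head of the ranking searched (default 25).
#' @return a [RadiomicSignature-class].
#' @export
selectSignature <- function(ranking, kinds, topK = 25) {
    stopifnot(is(ranking, "ConsensusRanking"))
    if (is(kinds, "RadiomicsExperiment")) kinds <- featureKinds(kinds)
    sc <- ranking@scores
    top <- utils::head(sc$feature, topK)
    missing_kind <- setdiff(top, names(kinds))
    if (length(missing_kind))
        stop("no kind annotation for: ",
             paste(missing_kind, collapse = ", "))
    shapes <- top[kinds[top] == "shape"]
    textures <- top[kinds[top] == "texture"]
    if (!length(shapes))
        stop("top-", topK, " list contains no shape feature")
    if (!length(textures))
        stop("top-", topK, " list contains no texture feature")
    new("RadiomicSignature", shapeFeature = shapes[1],
        textureFeature = textures[1], sourceGroup = ranking@group)
}

#' @rdname radiolik-generics
#' @export
setMethod("shapeFeature", "RadiomicSignature", function(x) x@shapeFeature)

#' @rdname radiolik-generics
#' @export
setMethod("textureFeature", "RadiomicSignature", function(x) x@textureFeature)

setMethod("show", "RadiomicSignature", function(object) {
    cat("RadiomicSignature [", object@sourceGroup, "]: shape = ",
        object@shapeFeature, ", texture = ", object@textureFeature, "\n",
        sep = "")
})

.RANKER_GROUPS <- list(
    supervised = c("fisher", "relieff", "mutual_info"),
    unsupervised = c("laplacian", "spec", "redundancy", "variance"))

#' Run a group of rankers and form their consensus
#'
#' The supervised (wrapper) group comprises Fisher score, ReliefF and
#' mutual information; the unsupervised (filter) group Laplacian score,
#' SPEC, minimum-redundancy and min-max variance. Additional rankers can
#' be supplied via `extraRankers` (named list of functions taking the
#' value matrix and, for supervised use, a `labels` argument) without
#' changing the consensus logic.
#'
#' @param x a [RadiomicsExperiment-class] (labels required for the
#'   supervised group) or samples-by-features matrix.
#' @param group "supervised" or "unsupervised".
#' @param labels binary labels (taken from `x` when omitted).
#' @param kNeighbors neighborhood size for ReliefF / graph rankers.
#' @param method consensus commensuration, see [consensusRank()].
#' @param extraRankers named list of additional ranker functions returning
#'   [RankerOutput-class] objects.
#' @return a [ConsensusRanking-class].
#' @export
rankFeatures <- function(x, group = c("supervised", "unsupervised"),
                         labels = NULL, kNeighbors = NULL,
                         method = c("score", "rank"),
                         extraRankers = list()) {
    group <- match.arg(group)
    method <- match.arg(method)
    v <- .as_values(x)
    outputs <- if (group == "supervised") {
        y <- .get_labels(x, labels)
        k <- if (is.null(kNeighbors)) 10 else kNeighbors
        list(fisherScore(v, y), relieffScore(v, y, kNeighbors = k),
             mutualInfoScore(v, y))
    } else {
        k <- if (is.null(kNeighbors)) 5 else kNeighbors
        list(laplacianScore(v, kNeighbors = k),
             specScore(v, kNeighbors = k),
             redundancyScore(v), varianceScore(v))
    }
    for (nm in names(extraRankers))
        outputs <- c(outputs, list(extraRankers[[nm]](v)))
    consensusRank(outputs, group = group, method = method)
}

#' Write a consensus ranking to CSV
#'
#' Columns: feature, one normalized-score column per ranker, consensus,
#' rank.
#'
#' @param ranking a [ConsensusRanking-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRanking <- function(ranking, path) {
    sc <- ranking@scores
    num <- vapply(sc, is.numeric, logical(1)) &
        !(colnames(sc) == "rank")
    sc[num] <- lapply(sc[num], function(z)
        trimws(formatC(z, digits = 15, format = "g")))
    write.csv(sc, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
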