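## Feature-ranking algorithm bank. Every ranker takes a samples x features
## value matrix (or a RadiomicsExperiment) and returns a RankerOutput with
## one finite score per feature plus its orientation; consensusRank() makes
## the scores commensurable.

.as_values <- function(x) {
    if (is(x, "RadiomicsExperiment")) featureValues(x) else as.matrix(x)
}

.get_labels <- function(x, labels) {
    if (is.null(labels) && is(x, "RadiomicsExperiment"))
        labels <- sampleLabels(x)
    if (is.null(labels)) stop("labels are required for a supervised ranker")
    if (length(unique(labels)) < 2) stop("both classes must be present")
    as.integer(labels)
}

.ranker_output <- function(name, scores, orientation) {
    new("RankerOutput", rankerName = name, scores = scores,
        orientation = orientation)
}

# replace +Inf sentinels by (max finite) + 1 so downstream normalization
# stays finite
.definite <- function(s, context) {
    inf <- !is.finite(s)
    if (any(inf)) {
        warning(context, ": infinite score for ",
                paste(names(s)[inf], collapse = ", "),
                "; replaced by max finite score + 1")
        s[inf] <- if (all(inf)) 1 else max(s[!inf]) + 1
    }
    s
}

#' Fisher score (supervised)
#'
#' Ratio of between-class separation to within-class variance, per feature:
#' F_j = sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c sigma^2_cj, with population
#' (1/n_c) class variances. Higher is better. A feature with zero pooled
#' within-class variance gets the maximal finite score + 1 with a warning.
#'
#' @param x samples-by-features matrix or [RadiomicsExperiment-class].
#' @param labels binary 0/1 vector (taken from `x` when omitted).
#' @return a [RankerOutput-class], orientation higher_better.
#' @export
fisherScore <- function(x, labels = NULL) {
    v <- .as_values(x)
    y <- .get_labels(x, labels)
    mu <- colMeans(v)
    num <- den <- rep(0, ncol(v))
    for (c in unique(y)) {
        vc <- v[y == c, , drop = FALSE]
        nc <- nrow(vc)
        if (nc < 2) stop("each class needs >= 2 samples")
        muc <- colMeans(vc)
        num <- num + nc * (muc - mu)^2
        den <- den + nc * colMeans(sweep(vc, 2, muc)^2)
    }
    s <- ifelse(den == 0 & num == 0, 0, num / den)
    names(s) <- colnames(v)
    .ranker_output("fisher", .definite(s, "fisherScore"), "higher_better")
}

#' ReliefF weights (supervised)
#'
#' Features are pre-scaled to [0, 1]; neighbors are found by Manhattan
#' distance; every sample serves as an anchor (deterministic). For each
#' anchor, the per-feature mean absolute difference to its k nearest
#' same-class hits is subtracted from that to its k nearest other-class
#' misses; weights are averaged over anchors and lie in [-1, 1]. Higher is
#' better. k is truncated when a class is too small.
#'
#' @param x samples-by-features matrix or [RadiomicsExperiment-class].
#' @param labels binary 0/1 vector (taken from `x` when omitted).
#' @param kNeighbors number of hits/misses per anchor (default 10).
#' @return a [RankerOutput-class], orientation higher_better.
#' @export
relieffScore <- function(x, labels = NULL, kNeighbors = 10) {
    v <- .as_values(x)
    y <- .get_labels(x, labels)
    n <- nrow(v); p <- ncol(v)
    rng <- apply(v, 2, function(col) diff(range(col)))
    sc <- sweep(v, 2, apply(v, 2, min))
    nz <- rng > 0
    sc[, nz] <- sweep(sc[, nz, drop = FALSE], 2, rng[nz], "/")
    sc[, !nz] <- 0
    d <- as.matrix(dist(sc, method = "manhattan"))
    w <- rep(0, p)
    for (i in seq_len(n)) {
        same <- which(y == y[i]); same <- same[same != i]
        other <- which(y != y[i])
        if (!length(same) || !length(other)) next
        kh <- min(kNeighbors, length(same))
        km <- min(kNeighbors, length(other))
        hits <- same[order(d[i, same], same)][seq_len(kh)]
        miss <- other[order(d[i, other], other)][seq_len(km)]
        dh <- abs(sweep(sc[hits, , drop = FALSE], 2, sc[i, ]))
        dm <- abs(sweep(sc[miss, , drop = FALSE], 2, sc[i, ]))
        w <- w + colMeans(dm) - colMeans(dh)
    }
    s <- w / n
    names(s) <- colnames(v)
    .ranker_output("relieff", s, "higher_better")
}

#' Mutual information with the class label (supervised)
#'
#' Each feature is discretized into `nBins` equal-width bins over its range
#' and the mutual information (in nats) between the binned feature and the
#' binary label is computed from the contingency table. Higher is better.
#'
#' @param x samples-by-features matrix or [RadiomicsExperiment-class].
#' @param labels binary 0/1 vector (taken from `x` when omitted).
#' @param nBins number of equal-width bins (default 10).
#' @return a [RankerOutput-class], orientation higher_better.
#' @export
mutualInfoScore <- function(x, labels = NULL, nBins = 10) {
    v <- .as_values(x)
    y <- .get_labels(x, labels)
    n <- nrow(v)
    s <- apply(v, 2, function(col) {
        if (diff(range(col)) == 0) return(0)
        b <- cut(col, breaks = nBins, include.lowest = TRUE)
        tab <- table(b, y) / n
        px <- rowSums(tab); py <- colSums(tab)
        pos <- tab > 0
        sum(tab[pos] * log(tab[pos] / outer(px, py)[pos]))
    })
    names(s) <- colnames(v)
    .ranker_output("mutual_info", s, "higher_better")
}

# shared kNN heat-kernel graph for the two spectral rankers: Euclidean
# distances, union-symmetrized k-nearest-neighbor edges, weights
# exp(-d^2/sigma^2) with sigma = mean kNN distance unless given
.knn_heat_graph <- function(v, kNeighbors, heatSigma = NULL) {
    n <- nrow(v)
    if (n < kNeighbors + 1) stop("need n >= kNeighbors + 1 samples")
    d <- as.matrix(dist(v))
    adj <- matrix(FALSE, n, n)
    knn_d <- numeric(0)
    for (i in seq_len(n)) {
        ord <- order(d[i, -i], (seq_len(n))[-i])
        nb <- ((seq_len(n))[-i])[ord][seq_len(kNeighbors)]
        adj[i, nb] <- TRUE
        knn_d <- c(knn_d, d[i, nb])
    }
    adj <- adj | t(adj)
    sigma <- if (is.null(heatSigma)) mean(knn_d) else heatSigma
    if (sigma <= 0) sigma <- 1      # degenerate all-coincident data
    # floor the exponent so retained edges never underflow to weight 0
    # (raw radiomic scales can make d >> sigma), keeping degrees positive
    W <- exp(pmax(-d^2 / sigma^2, -700)) * adj
    W
}

#' Laplacian score (unsupervised)
#'
#' Locality-preserving power of each feature on a k-nearest-neighbor heat
#' kernel graph: L_j = (f' L f) / (f' D f) with f the D-weighted-mean
#' centered feature, L = D - W the graph Laplacian. Lower is better
#' (smooth-on-the-graph features score low). Constant features have a zero
#' denominator and are assigned the worst score with a warning.
#'
#' @param x samples-by-features matrix or [RadiomicsExperiment-class].
#' @param kNeighbors graph neighborhood size (default 5).
#' @param heatSigma heat-kernel bandwidth; by default the mean kNN
#'   distance.
#' @return a [RankerOutput-class], orientation lower_better.
#' @export
laplacianScore <- function(x, kNeighbors = 5, heatSigma = NULL) {
    v <- .as_values(x)
    W <- .knn_heat_graph(v, kNeighbors, heatSigma)
    dg <- rowSums(W)
    s <- apply(v, 2, function(f) {
        if (diff(range(f)) == 0) return(Inf)   # zero denominator
        ft <- f - sum(f * dg) / sum(dg)
        den <- sum(ft^2 * dg)
        num <- sum(ft * (dg * ft - as.vector(W %*% ft)))
        num / den
    })
    names(s) <- colnames(v)
    s <- .definite(s, "laplacianScore")
    .ranker_output("laplacian", s, "lower_better")
}

#' Spectral (SPEC) feature score (unsupervised)
#'
#' Smoothness of each feature with respect to the normalized Laplacian of
#' the same kNN heat-kernel graph as [laplacianScore()]: the feature is
#' degree-normalized (f_hat = D^{1/2} f / ||D^{1/2} f||) and scored as
#' f_hat' L_norm f_hat. Lower is better; the score is invariant to positive
#' rescaling of the feature. Constant features are assigned the worst score
#' with a warning (their degree-normalized form is the trivial eigenvector).
#'
#' @inheritParams laplacianScore
#' @return a [RankerOutput-class], orientation lower_better.
#' @export
specScore <- function(x, kNeighbors = 5, heatSigma = NULL) {
    v <- .as_values(x)
    W <- .knn_heat_graph(v, kNeighbors, heatSigma)
    dg <- rowSums(W)
    s <- apply(v, 2, function(f) {
        if (diff(range(f)) == 0) return(Inf)
        # f_hat' (I - D^-1/2 W D^-1/2) f_hat with f_hat = D^1/2 f / ||.||
        # expands to 1 - (f' W f) / (f' D f)
        den <- sum(dg * f^2)
        if (den == 0) return(Inf)
        1 - sum(f * as.vector(W %*% f)) / den
    })
    names(s) <- colnames(v)
    s <- .definite(s, "specScore")
    .ranker_output("spec", s, "lower_better")
}

#' Minimum-redundancy score (unsupervised)
#'
#' Rewards features exhibiting minimum correlation with the others:
#' score_j = -mean_{k != j} |Pearson(f_j, f_k)|. Constant features are
#' treated as correlation 0 with a warning. Higher is better.
#'
#' @param x samples-by-features matrix or [RadiomicsExperiment-class].
#' @return a [RankerOutput-class], orientation higher_better.
#' @export
redundancyScore <- function(x) {
    v <- .as_values(x)
    if (ncol(v) < 2) stop("need at least 2 features")
    sds <- apply(v, 2, sd)
    if (any(sds == 0))
        warning("constant feature(s) treated as correlation 0: ",
                paste(colnames(v)[sds == 0], collapse = ", "))
    C <- suppressWarnings(cor(v))
    C[!is.finite(C)] <- 0
    diag(C) <- NA
    s <- -rowMeans(abs(C), na.rm = TRUE)
    names(s) <- colnames(v)
    .ranker_output("redundancy", s, "higher_better")
}

#' Min-max-scaled variance score (unsupervised)
#'
#' Population variance of each feature after min-max scaling to [0, 1]
#' (constant features score 0). Higher is better; invariant to affine
#' rescaling of the raw feature.
#'
#' @param x samples-by-features matrix or [RadiomicsExperiment-class].
#' @return a [RankerOutput-class], orientation higher_better.
#' @export
varianceScore <- function(x) {
    v <- .as_values(x)
    s <- apply(v, 2, function(col) {
        r <- diff(range(col))
        if (r == 0) return(0)
        z <- (col - min(col)) / r
        mean((z - mean(z))^2)
    })
    names(s) <- colnames(v)
    .ranker_output("variance", s, "higher_better")
}
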