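test_that("Fisher score matches its formula on frozen and random cases", {
    # class means 0 and 1, population class variances 1, equal n:
    # sum n_c (mu_c - mu)^2 / sum n_c var_c = (n/4)/n = 0.25
    v <- cbind(f1 = c(-1, 1, 0, 2), f2 = c(5, 6, 5, 6))
    y <- c(0, 0, 1, 1)
    s <- fisherScore(v, y)@scores
    expect_equal(unname(s["f1"]), 0.25)
    expect_equal(unname(s["f2"]), 0)          # identical in both classes

    # independent brute-force recomputation, n = 6, 2 features
    set.seed(1)
    v2 <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
    y2 <- c(0, 0, 0, 1, 1, 1)
    brute <- vapply(1:2, function(j) {
        f <- v2[, j]; num <- 0; den <- 0
        for (cl in c(0, 1)) {
            fc <- f[y2 == cl]
            num <- num + length(fc) * (mean(fc) - mean(f))^2
            den <- den + length(fc) * mean((fc - mean(fc))^2)
        }
        num / den
    }, numeric(1))
    expect_equal(unname(fisherScore(v2, y2)@scores), brute)
})

test_that("Fisher score flags zero within-class variance", {
    v <- cbind(sep = rep(c(0, 1), each = 3), ok = rnorm(6))
    y <- rep(c(0, 1), each = 3)
    expect_warning(s <- fisherScore(v, y)@scores, "infinite")
    expect_true(s["sep"] > s["ok"])
    expect_true(all(is.finite(s)))
})

test_that("ReliefF matches a brute-force neighbor enumeration", {
    set.seed(21)
    n <- 20
    y <- rep_len(c(0L, 1L), n)
    v <- cbind(signal = y + rnorm(n, 0, 0.05),
               noise1 = rnorm(n), noise2 = rnorm(n))
    k <- 3
    out <- relieffScore(v, y, kNeighbors = k)@scores
    # brute force: explicit loops over anchors, hits and misses
    sc <- apply(v, 2, function(col) (col - min(col)) / diff(range(col)))
    w <- numeric(3)
    for (i in 1:n) {
        dd <- rowSums(abs(sweep(sc, 2, sc[i, ])))
        same <- setdiff(which(y == y[i]), i)
        oth <- which(y != y[i])
        hits <- same[order(dd[same], same)][1:k]
        miss <- oth[order(dd[oth], oth)][1:k]
        for (j in 1:3)
            w[j] <- w[j] + mean(abs(sc[miss, j] - sc[i, j])) -
                           mean(abs(sc[hits, j] - sc[i, j]))
    }
    expect_equal(unname(out), w / n, tolerance = 1e-12)
    # the separating feature attains the maximal weight
    expect_identical(names(which.max(out)), "signal")
})

test_that("ReliefF gives zero weight to constants, equal to duplicates", {
    set.seed(22)
    v <- cbind(a = rnorm(16), b = rep(2, 16))
    v <- cbind(v, a_dup = v[, "a"])
    y <- rep_len(c(0L, 1L), 16)
    s <- relieffScore(v, y, kNeighbors = 4)@scores
    expect_equal(unname(s["b"]), 0)
    expect_equal(unname(s["a"]), unname(s["a_dup"]))
})

test_that("mutual information matches label entropy and brute force", {
    y <- rep_len(c(0L, 1L), 12)
    v <- cbind(copy = as.numeric(y))
    expect_equal(unname(mutualInfoScore(v, y)@scores), log(2),
                 tolerance = 1e-12)

    # exhaustive contingency recomputation on 8 samples
    set.seed(23)
    v8 <- cbind(f = rnorm(8))
    y8 <- c(0, 1, 0, 1, 1, 0, 1, 0)
    b <- cut(v8[, 1], breaks = 10, include.lowest = TRUE)
    tab <- table(b, y8) / 8
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in 1:2)
        if (tab[i, j] > 0)
            mi <- mi + tab[i, j] *
                log(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
    expect_equal(unname(mutualInfoScore(v8, y8)@scores), mi,
                 tolerance = 1e-12)
})

test_that("mutual information of an independent feature vanishes", {
    set.seed(24)
    y <- rep_len(c(0L, 1L), 1000)
    v <- cbind(ind = rnorm(1000))
    expect_lt(mutualInfoScore(v, y)@scores[1], 0.02)
})

test_that("Laplacian score equals the hand-built graph formula on n = 4", {
    v <- matrix(c(0, 1, 10, 11,
                  5, 5, 5, 6), 4, 2,
                dimnames = list(NULL, c("f1", "f2")))
    k <- 1
    # hand-built graph: pairwise Euclidean distances, 1-NN union,
    # sigma = mean 1-NN distance, heat-kernel weights
    d <- as.matrix(dist(v))
    adj <- matrix(FALSE, 4, 4)
    nnd <- numeric(4)
    for (i in 1:4) {
        j <- setdiff(order(d[i, ]), i)[1]
        adj[i, j] <- TRUE
        nnd[i] <- d[i, j]
    }
    adj <- adj | t(adj)
    W <- exp(-d^2 / mean(nnd)^2) * adj
    D <- diag(rowSums(W)); L <- D - W
    one <- rep(1, 4)
    hand <- vapply(1:2, function(j) {
        f <- v[, j]
        ft <- f - as.numeric((t(f) %*% D %*% one) / (t(one) %*% D %*% one))
        as.numeric((t(ft) %*% L %*% ft) / (t(ft) %*% D %*% ft))
    }, numeric(1))
    out <- laplacianScore(v, kNeighbors = 1)@scores
    expect_equal(unname(out), hand, tolerance = 1e-12)
})

test_that("graph rankers prefer cluster-smooth features over noise", {
    m <- two_blob_matrix()
    ls <- laplacianScore(m, kNeighbors = 4)@scores
    ss <- specScore(m, kNeighbors = 4)@scores
    expect_lt(ls["smooth"], ls["noise"])      # lower is better
    expect_lt(ss["smooth"], ss["noise"])
})

test_that("SPEC score matches the hand normalized-Laplacian computation", {
    v <- matrix(c(0, 1, 10, 11,
                  2, 3, 4, 9), 4, 2, dimnames = list(NULL, c("f1", "f2")))
    d <- as.matrix(dist(v))
    adj <- matrix(FALSE, 4, 4); nnd <- numeric(4)
    for (i in 1:4) {
        j <- setdiff(order(d[i, ]), i)[1]
        adj[i, j] <- TRUE; nnd[i] <- d[i, j]
    }
    adj <- adj | t(adj)
    W <- exp(-d^2 / mean(nnd)^2) * adj
    D <- diag(rowSums(W))
    Lnorm <- diag(4) - solve(sqrt(D)) %*% W %*% solve(sqrt(D))
    hand <- vapply(1:2, function(j) {
        fh <- sqrt(diag(D)) * v[, j]
        fh <- fh / sqrt(sum(fh^2))
        as.numeric(t(fh) %*% Lnorm %*% fh)
    }, numeric(1))
    out <- specScore(v, kNeighbors = 1)@scores
    expect_equal(unname(out), hand, tolerance = 1e-10)
    # invariant to positive rescaling (degree normalization: scaling the
    # data leaves the graph, and every feature's score, unchanged)
    expect_equal(unname(specScore(7.5 * v, kNeighbors = 1)@scores),
                 unname(out), tolerance = 1e-12)
})

test_that("redundancy score matches the hand mean-|correlation|", {
    set.seed(26)
    base <- rnorm(50)
    v <- cbind(a = base, b = base + rnorm(50, 0, 0.1), c = rnorm(50))
    s <- redundancyScore(v)@scores
    C <- abs(cor(v))
    hand <- -c((C[1, 2] + C[1, 3]) / 2, (C[2, 1] + C[2, 3]) / 2,
               (C[3, 1] + C[3, 2]) / 2)
    expect_equal(unname(s), hand, tolerance = 1e-12)
    # the correlated pair scores below the independent feature
    expect_true(all(s[c("a", "b")] < s["c"]))
})

test_that("redundancy of independent features tends to zero", {
    set.seed(27)
    v <- matrix(rnorm(2000 * 5), 2000, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    expect_true(all(abs(redundancyScore(v)@scores) < 0.05))
})

test_that("variance score: constants, balanced binary, affine invariance", {
    v <- cbind(const = rep(3, 8), bin = rep(c(0, 1), 4), x = rnorm(8))
    s <- varianceScore(v)@scores
    expect_equal(unname(s["const"]), 0)
    expect_equal(unname(s["bin"]), 0.25)      # balanced 0/1 after scaling
    v2 <- v; v2[, "x"] <- 100 * v[, "x"] - 7
    expect_equal(varianceScore(v2)@scores["x"], s["x"], tolerance = 1e-12)
})

test_that("rankers are invariant to sample order and label swap", {
    set.seed(28)
    v <- matrix(rnorm(30 * 4), 30,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- rep_len(c(0L, 1L), 30)
    perm <- sample(30)
    for (fun in list(function(m) fisherScore(m, y[perm]),
                     function(m) relieffScore(m, y[perm], kNeighbors = 5),
                     function(m) mutualInfoScore(m, y[perm]),
                     function(m) laplacianScore(m),
                     function(m) specScore(m),
                     redundancyScore, varianceScore)) {
        ref <- fun(v[perm, , drop = FALSE])@scores
        expect_equal(ref, fun(v[perm, , drop = FALSE])@scores)
    }
    # permutation invariance (scores identical regardless of row order)
    expect_equal(fisherScore(v[perm, ], y[perm])@scores,
                 fisherScore(v, y)@scores)
    expect_equal(laplacianScore(v[perm, ])@scores, laplacianScore(v)@scores)
    expect_equal(specScore(v[perm, ])@scores, specScore(v)@scores)
    # label-swap invariance of the symmetric supervised scores
    expect_equal(fisherScore(v, y)@scores, fisherScore(v, 1L - y)@scores)
    expect_equal(mutualInfoScore(v, y)@scores,
                 mutualInfoScore(v, 1L - y)@scores)
    expect_equal(relieffScore(v, y, 5)@scores,
                 relieffScore(v, 1L - y, 5)@scores)
})

test_that("supervised rankers reject single-class labels", {
    v <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(fisherScore(v, rep(1, 6)), "class")
    expect_error(relieffScore(v, rep(0, 6)), "class")
    expect_error(mutualInfoScore(v, rep(1, 6)), "class")
})
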