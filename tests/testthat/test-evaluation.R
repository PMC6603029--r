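test_that("classification threshold is inclusive at the boundary", {
    expect_identical(classifyMalignant(c(0.51, 0.509, 2, -1)),
                     c(1L, 0L, 1L, 0L))
    expect_error(classifyMalignant(NaN), "finite")
    # composition with the pretrained model: y(1, 1) is far below 0.51
    y <- predictLikelihood(pretrainedModel("MLF1"), 1, 1)
    expect_identical(classifyMalignant(y), 0L)
})

test_that("confusion counts match a brute-force tally", {
    cm <- confusionMatrix(c(1, 1, 0), c(1, 1, 0))
    expect_equal(unname(confusionCounts(cm)), c(2L, 0L, 0L, 1L))
    cm2 <- confusionMatrix(c(1, 0), c(0, 1))
    expect_equal(unname(confusionCounts(cm2)), c(0L, 1L, 1L, 0L))

    set.seed(41)
    truth <- rbinom(50, 1, 0.5); pred <- rbinom(50, 1, 0.5)
    cm3 <- confusionCounts(confusionMatrix(truth, pred))
    tally <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
    for (i in 1:50) {
        k <- if (truth[i] == 1 && pred[i] == 1) "tp"
             else if (truth[i] == 1) "fn"
             else if (pred[i] == 1) "fp" else "tn"
        tally[k] <- tally[k] + 1L
    }
    expect_identical(cm3, tally)
    expect_error(confusionMatrix(c(1, 0), c(1, 0, 1)), "equal length")
    expect_error(confusionMatrix(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics expose both naming conventions and handle edge cases", {
    perfect <- evalReport(tp = 10, fn = 0, fp = 0, tn = 5)
    expect_equal(perfect@accuracy, 1)
    expect_equal(perfect@paperSensitivity, 1)
    expect_equal(perfect@paperSpecificity, 1)
    expect_equal(perfect@stdSensitivity, 1)
    expect_equal(perfect@stdSpecificity, 1)

    r <- evalReport(tp = 155, fn = 10, fp = 7, tn = 28)
    expect_equal(r@stdSensitivity, 155 / 165)
    expect_equal(r@stdSpecificity, 28 / 35)
    expect_equal(r@paperSensitivity, 155 / 162)
    expect_equal(r@paperSpecificity, 28 / 38)

    w <- capture_warnings(z <- evalReport(tp = 0, fn = 0, fp = 0, tn = 4))
    expect_true(all(grepl("undefined", w)))   # both sensitivity ratios
    expect_true(is.na(z@paperSensitivity))
    expect_error(evalReport(0, 0, 0, 0), "all-zero")
})

test_that("metrics are scale-invariant and flip correctly", {
    set.seed(42)
    for (i in 1:10) {
        counts <- rmultinom(1, 60, c(0.4, 0.2, 0.1, 0.3))[, 1] + 1L
        a <- evalReport(counts[1], counts[2], counts[3], counts[4])
        b <- evalReport(3 * counts[1], 3 * counts[2], 3 * counts[3],
                        3 * counts[4])
        expect_equal(a@accuracy, b@accuracy)
        expect_equal(a@paperSensitivity, b@paperSensitivity)
        # flipping all predictions swaps tp<->fn and tn<->fp
        f <- evalReport(counts[2], counts[1], counts[4], counts[3])
        expect_equal(f@accuracy, 1 - a@accuracy)
    }
})

test_that("ROC/AUC: frozen cases and the Mann-Whitney identity", {
    expect_equal(rocAuc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
    expect_equal(rocAuc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
    expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)

    mw_auc <- function(s, y) {
        pos <- s[y == 1]; neg <- s[y == 0]
        tot <- 0
        for (p in pos) for (q in neg)
            tot <- tot + (p > q) + 0.5 * (p == q)
        tot / (length(pos) * length(neg))
    }
    set.seed(43)
    for (i in 1:15) {
        y <- rbinom(25, 1, 0.5)
        if (length(unique(y)) < 2) next
        s <- round(rnorm(25, mean = y), 1)      # rounding forces ties
        expect_equal(rocAuc(s, y)$auc, mw_auc(s, y), tolerance = 1e-12)
    }
    expect_error(rocAuc(c(1, 2), c(1, 1)), "both classes")
})

test_that("ROC points are monotone and agree with pROC", {
    skip_if_not_installed("pROC")
    set.seed(44)
    y <- rbinom(80, 1, 0.4)
    s <- rnorm(80, mean = 1.2 * y)
    out <- rocAuc(s, y)
    expect_true(all(diff(out$roc$fpr) >= 0))
    expect_true(all(diff(out$roc$tpr) >= 0))
    expect_equal(out$roc$fpr[1], 0)
    expect_equal(out$roc$tpr[nrow(out$roc)], 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(out$auc, ref, tolerance = 1e-12)
})

test_that("separable cohorts approach perfect end-to-end accuracy", {
    # pretrained MLF2 + threshold 0.51 on synthetic cohorts: accuracy is
    # monotone in the planted effect size and approaches 1
    m2 <- pretrainedModel("MLF2")
    acc <- vapply(c(0.5, 2, 6), function(es) {
        x <- simulateCohort(60, 60, effectSize = es, seed = 45)
        ev <- evaluateScores(predict(m2, x), sampleLabels(x))
        ev@accuracy
    }, numeric(1))
    expect_true(all(diff(acc) >= 0))
    expect_gt(acc[3], 0.95)
})

test_that("evaluation report serializes counts, metrics and ROC", {
    set.seed(46)
    y <- rbinom(40, 1, 0.5)
    s <- rnorm(40, y)
    ev <- evaluateScores(s, y)
    path <- tempfile(fileext = ".json")
    writeEvalReport(ev, path)
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(j$accuracy, ev@accuracy)
    expect_equal(j$auc, ev@auc)
    expect_equal(length(j$roc$fpr), nrow(ev@roc))
})
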