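test_that("basis expansions match hand evaluations and guard domains", {
    expect_equal(drop(basisMLF1(1, 1)), c(a = 1, b = 0, c = 0, d = 1,
                                          e = 1, f = 1, g = 1))
    expect_equal(drop(basisMLF1(exp(1), 2)),
                 c(a = 1, b = 1, c = 2, d = 0.5, e = 0.25, f = 0.125,
                   g = 0.0625))
    expect_error(basisMLF1(0, 1), "x1 > 0")
    expect_error(basisMLF1(1, 0), "x2 != 0")

    expect_equal(drop(basisMLF2(0, 1)), c(a = 1, b = 0, c = 0, d = 0,
                                          e = 0, f = 0))
    expect_equal(drop(basisMLF2(2, exp(1))),
                 c(a = 1, b = 2, c = 4, d = 8, e = 16, f = 1))
    expect_error(basisMLF2(1, 0), "x2 > 0")
    # the printed ln(x1^2) term is literally 2 ln(x1)
    expect_equal(basisMLF1(7, 3)[, "c"], 2 * log(7), ignore_attr = TRUE)
    expect_equal(basisMLF1(7, 3, squaredLog = TRUE)[, "c"], log(7)^2,
                 ignore_attr = TRUE)
})

test_that("pretrained models carry the printed coefficients exactly", {
    m1 <- pretrainedModel("MLF1")
    m2 <- pretrainedModel("MLF2")
    expect_identical(unname(coef(m1)["a"]), -2.45226185349294)
    expect_identical(unname(coef(m1)["g"]), 9.40291849279405e-07)
    expect_identical(unname(coef(m2)["a"]), 0.747801694861307)
    expect_identical(unname(coef(m2)["f"]), 0.0128142101694647)
    expect_identical(residualSE(m1), 0.30)
    expect_identical(residualSE(m2), 0.20)
    expect_identical(m1@x1Feature, "shape_Volume")
    expect_identical(m2@x1Feature, "shape_SurfaceVolumeRatio")
    expect_error(pretrainedModel("MLF3"))
})

test_that("pretrained evaluation at x1 = x2 = 1 equals the coefficient sums", {
    # logs vanish and reciprocals are 1: MLF1 -> a+d+e+f+g, MLF2 -> a+..+e
    m1 <- pretrainedModel("MLF1"); m2 <- pretrainedModel("MLF2")
    hand1 <- sum(coef(m1)[c("a", "d", "e", "f", "g")])
    hand2 <- sum(coef(m2)[c("a", "b", "c", "d", "e")])
    expect_equal(predictLikelihood(m1, 1, 1), hand1, tolerance = 1e-12)
    expect_equal(predictLikelihood(m2, 1, 1), hand2, tolerance = 1e-12)
    expect_equal(hand1, -2.47559, tolerance = 1e-5)
    expect_equal(hand2, 0.29017, tolerance = 1e-5)
    expect_error(predictLikelihood(m1, -1, 1), "x1")
})

test_that("MLF1 depends on x1 only through ln x1 (scale-log property)", {
    m1 <- pretrainedModel("MLF1")
    b2c <- sum(coef(m1)["b"]) + 2 * sum(coef(m1)["c"])
    x2 <- 3.7
    expect_equal(predictLikelihood(m1, 200, x2) -
                 predictLikelihood(m1, 100, x2),
                 b2c * log(2), tolerance = 1e-12)
})

test_that("fit recovers MLF2 coefficients from noiseless data", {
    m2 <- pretrainedModel("MLF2")
    d <- simulateFromModel(m2, 200, c(0.1, 2.5), c(2, 8), seed = 101)
    f <- fitLikelihood("MLF2", d$x1, d$x2, d$y)
    expect_lt(max(abs(coef(f) - coef(m2))), 1e-8)
    expect_lt(residualSE(f), 1e-8)
})

test_that("MLF1 fit is prediction-equivalent despite the collinear basis", {
    m1 <- pretrainedModel("MLF1")
    d <- simulateFromModel(m1, 200, c(50, 5000), c(50, 400), seed = 102)
    f <- fitLikelihood("MLF1", d$x1, d$x2, d$y)
    expect_lt(max(abs(predictLikelihood(f, d$x1, d$x2) - d$y)), 1e-8)
    # only the combination b + 2c is identifiable; it is recovered
    expect_equal(unname(coef(f)["b"] + 2 * coef(f)["c"]),
                 unname(coef(m1)["b"] + 2 * coef(m1)["c"]),
                 tolerance = 1e-8)
})

test_that("fit is idempotent on its own predictions", {
    set.seed(103)
    x1 <- runif(60, 0.2, 2); x2 <- runif(60, 2, 7)
    y <- rbinom(60, 1, 0.6)
    f1 <- fitLikelihood("MLF2", x1, x2, y)
    yhat <- predictLikelihood(f1, x1, x2)
    f2 <- fitLikelihood("MLF2", x1, x2, yhat)
    expect_lt(max(abs(predictLikelihood(f2, x1, x2) - yhat)), 1e-10)
})

test_that("residual SE does not increase when an on-surface datum joins", {
    set.seed(104)
    x1 <- runif(40, 0.2, 2); x2 <- runif(40, 2, 7)
    y <- rbinom(40, 1, 0.5)
    f <- fitLikelihood("MLF2", x1, x2, y)
    newy <- predictLikelihood(f, 1.1, 3.3)
    f2 <- fitLikelihood("MLF2", c(x1, 1.1), c(x2, 3.3), c(y, newy))
    expect_lte(residualSE(f2), residualSE(f) + 1e-12)
})

test_that("fit rejects underdetermined or degenerate input", {
    expect_error(fitLikelihood("MLF2", runif(4), runif(4, 1, 2),
                               rep(1, 4)), "at least 6")
    expect_error(fitLikelihood("MLF1", runif(5, 1, 2), runif(5, 1, 2),
                               rep(0, 5)), "at least 7")
})

test_that("model JSON round-trips through read/write", {
    f <- fitLikelihood("MLF2", runif(20, 0.2, 2), runif(20, 2, 7),
                       rbinom(20, 1, 0.5),
                       x1Feature = "shape_SurfaceVolumeRatio",
                       x2Feature = "glcm_SumEntropy")
    path <- tempfile(fileext = ".json")
    writeLikelihoodModel(f, path)
    g <- readLikelihoodModel(path)
    expect_equal(coef(g), coef(f))
    expect_identical(formId(g), "MLF2")
    expect_equal(residualSE(g), residualSE(f))
    expect_identical(g@x1Feature, "shape_SurfaceVolumeRatio")
})

test_that("predict method binds model features from a table", {
    x <- simulateCohort(10, 10, effectSize = 2, seed = 105)
    m2 <- pretrainedModel("MLF2")
    y <- predict(m2, x)
    v <- featureValues(x)
    expect_equal(unname(y),
                 unname(predictLikelihood(m2, v[, "shape_SurfaceVolumeRatio"],
                                          v[, "glcm_SumEntropy"])))
    bad <- LikelihoodModel("MLF2", coef(m2), x1Feature = "shape_Missing",
                           x2Feature = "glcm_SumEntropy")
    expect_error(predict(bad, x), "shape_Missing")
})
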