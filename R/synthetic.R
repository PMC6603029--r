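## Synthetic radiomic cohorts: 105 features in the canonical class layout,
## four planted class-separated informative features (two shape, two
## texture), pure-noise distractors, test-retest replicates and
## model-generated (x1, x2, y) data.

.CLASS_LAYOUT <- c(shape = 13L, gldm = 14L, glcm = 23L, ngtdm = 5L,
                   firstorder = 18L, glszm = 16L, glrlm = 16L)

.INFORMATIVE <- c("shape_Volume", "shape_SurfaceVolumeRatio",
                  "glcm_SumEntropy",
                  "glszm_LargeAreaLowGrayLevelEmphasis")

.synth_feature_names <- function() {
    out <- character(0)
    for (cl in names(.CLASS_LAYOUT)) {
        n <- .CLASS_LAYOUT[[cl]]
        inf <- .INFORMATIVE[startsWith(.INFORMATIVE, paste0(cl, "_"))]
        filler <- sprintf("%s_Synth%02d", cl, seq_len(n - length(inf)))
        out <- c(out, inf, filler)
    }
    out
}

.rtruncnorm_pos <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
    x
}

#' Generate a synthetic two-class radiomic cohort
#'
#' Emulates a labeled lung-nodule feature table: 105 features in the
#' canonical class layout (shape 13, GLDM 14, GLCM 23, NGTDM 5, first
#' order 18, GLSZM 16, GLRLM 16). Four designated informative features
#' carry the class signal with standardized mean separation `effectSize`:
#' `shape_Volume` (log-normal; separation on the log scale; benign median
#' near 270 mm^3, i.e. an 8 mm nodule), `shape_SurfaceVolumeRatio`
#' (truncated normal; benign nodules above, malignant below the published
#' MLF II operating point of about 0.9, separating symmetrically),
#' `glcm_SumEntropy` and
#' `glszm_LargeAreaLowGrayLevelEmphasis` (truncated normal, higher in
#' malignant nodules). All remaining features are i.i.d. standard-normal
#' noise independent of the label (optionally equicorrelated via
#' `noiseCorrelation`, for redundancy-ranker studies). Deterministic given
#' `seed`.
#'
#' @param nMalignant,nBenign class sizes (defaults 165 / 35, the training
#'   cohort composition).
#' @param effectSize standardized class-mean separation of the informative
#'   features (default 2).
#' @param seed integer RNG seed.
#' @param noiseCorrelation equicorrelation of the noise features in
#'   [0, 1) (default 0, independent).
#' @return a labeled [RadiomicsExperiment-class] (malignant samples first).
#' @examples
#' simulateCohort(nMalignant = 20, nBenign = 10, effectSize = 3, seed = 1)
#' @export
simulateCohort <- function(nMalignant = 165, nBenign = 35, effectSize = 2,
                           seed = 1, noiseCorrelation = 0) {
    stopifnot(nMalignant >= 1, nBenign >= 1, effectSize >= 0,
              noiseCorrelation >= 0, noiseCorrelation < 1)
    set.seed(as.integer(seed))
    n <- nMalignant + nBenign
    lab <- c(rep(1L, nMalignant), rep(0L, nBenign))
    feats <- .synth_feature_names()
    m <- matrix(NA_real_, n, length(feats),
                dimnames = list(sprintf("s%03d", seq_len(n)), feats))

    # volume: log-normal, benign median 270 mm^3, sdlog 0.5, class shift
    # effectSize on the log scale (malignant larger)
    mu_b <- log(270); sdlog <- 0.5
    m[, "shape_Volume"] <-
        exp(rnorm(n, mu_b + (lab == 1L) * effectSize * sdlog, sdlog))
    # SVR: malignant nodules are larger hence less surface per volume;
    # the classes separate symmetrically about 0.9 so that growing
    # separation moves each class deeper into its side of the published
    # MLF II operating region
    m[, "shape_SurfaceVolumeRatio"] <-
        .rtruncnorm_pos(n, 0.9 + (0.5 - (lab == 1L)) * effectSize * 0.15,
                        0.15)
    # sum entropy: malignant texture more heterogeneous
    m[, "glcm_SumEntropy"] <-
        .rtruncnorm_pos(n, 3.5 + (lab == 1L) * effectSize * 0.4, 0.4)
    # LALGLE: large dark homogeneous zones more emphasized in malignancy
    m[, "glszm_LargeAreaLowGrayLevelEmphasis"] <-
        .rtruncnorm_pos(n, 150 + (lab == 1L) * effectSize * 40, 40)

    noise <- setdiff(feats, .INFORMATIVE)
    z <- matrix(rnorm(n * length(noise)), n, length(noise))
    if (noiseCorrelation > 0) {
        shared <- rnorm(n)
        z <- sqrt(noiseCorrelation) * shared +
            sqrt(1 - noiseCorrelation) * z
    }
    m[, noise] <- z
    RadiomicsExperiment(m, labels = lab)
}

#' Names of the planted informative features
#'
#' @return character vector of the four informative feature names used by
#'   [simulateCohort()] (two shape, two texture).
#' @export
informativeFeatures <- function() .INFORMATIVE

#' Generate a test-retest replicate of a feature table
#'
#' Adds independent Gaussian measurement noise with standard deviation
#' `retestNoiseSd` times the per-feature (sample) standard deviation.
#' Applying this twice to the same latent table with different seeds
#' produces a replicate pair whose theoretical CCC is
#' 1 / (1 + retestNoiseSd^2) per feature.
#'
#' @param x a [RadiomicsExperiment-class].
#' @param retestNoiseSd relative noise level, >= 0.
#' @param seed integer RNG seed.
#' @return a [RadiomicsExperiment-class] with the same ids and features.
#' @export
simulateRetest <- function(x, retestNoiseSd, seed = 1) {
    stopifnot(is(x, "RadiomicsExperiment"))
    if (retestNoiseSd < 0) stop("retestNoiseSd must be >= 0")
    set.seed(as.integer(seed))
    v <- featureValues(x)
    sds <- apply(v, 2, sd)
    noise <- matrix(rnorm(length(v)), nrow(v), ncol(v))
    v2 <- v + sweep(noise, 2, retestNoiseSd * sds, "*")
    RadiomicsExperiment(v2, labels = sampleLabels(x),
                        featureClasses = unname(featureClasses(x)))
}

#' Generate (x1, x2, y) data from a likelihood model
#'
#' x1 and x2 are uniform on the given ranges (which must lie within the
#' form's domain); y = model prediction + Gaussian noise.
#'
#' @param model a [LikelihoodModel-class].
#' @param n number of points.
#' @param x1Range,x2Range length-2 numeric intervals.
#' @param noiseSd standard deviation of the additive y noise (default 0).
#' @param seed integer RNG seed.
#' @return data.frame with columns x1, x2, y.
#' @export
simulateFromModel <- function(model, n, x1Range, x2Range, noiseSd = 0,
                              seed = 1) {
    stopifnot(is(model, "LikelihoodModel"), n >= 0, noiseSd >= 0,
              length(x1Range) == 2, length(x2Range) == 2,
              x1Range[1] <= x1Range[2], x2Range[1] <= x2Range[2])
    if (model@formId == "MLF1" && x1Range[1] <= 0)
        stop("x1Range must be positive for MLF1")
    if (x2Range[1] <= 0)
        stop("x2Range must be positive")
    set.seed(as.integer(seed))
    if (n == 0)
        return(data.frame(x1 = numeric(0), x2 = numeric(0),
                          y = numeric(0)))
    x1 <- runif(n, x1Range[1], x1Range[2])
    x2 <- runif(n, x2Range[1], x2Range[2])
    y <- predictLikelihood(model, x1, x2)
    if (noiseSd > 0) y <- y + rnorm(n, 0, noiseSd)
    data.frame(x1 = x1, x2 = x2, y = y)
}
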