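## End-to-end workflow: filter -> rank -> signature -> fit -> predict ->
## evaluate, with a validated flat config and per-stage artifacts, so a
## run is reproducible from one seed and each stage is re-creatable from
## the previous stage's files.

.PIPELINE_DEFAULTS <- list(
    table = NULL,            # cohort CSV; NULL -> simulate
    retest_a = NULL,         # optional paired retest CSVs
    retest_b = NULL,
    label_column = "label",
    n_malignant = 165, n_benign = 35, effect_size = 2,
    retest_noise_sd = 0.3,
    ccc_min = 0.85, alpha = 0.05,
    group = "supervised", top_k = 25,
    form = "MLF2", threshold = 0.51,
    clip_eps = NULL,
    seed = 1)

.validate_config <- function(config) {
    unknown <- setdiff(names(config), names(.PIPELINE_DEFAULTS))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config,
                             keep.null = TRUE)
    with(cfg, {
        if (!is.null(alpha) && (alpha <= 0 || alpha > 1))
            stop("alpha must be in (0, 1]")
        if (!is.null(ccc_min) && (ccc_min < -1 || ccc_min > 1))
            stop("ccc_min must be in [-1, 1]")
        if (!group %in% c("supervised", "unsupervised"))
            stop("group must be supervised or unsupervised")
        if (!form %in% c("MLF1", "MLF2"))
            stop("form must be MLF1 or MLF2")
        if (!is.finite(threshold)) stop("threshold must be finite")
        if (top_k < 2) stop("top_k must be >= 2")
        if (effect_size < 0) stop("effect_size must be >= 0")
    })
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value file mirroring the [runPipeline()] config list; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
    .validate_config(yaml::read_yaml(path))
}

.log_stage <- function(stage, msg, con = NULL) {
    line <- sprintf("[%s] %s", stage, msg)
    message(line)
    if (!is.null(con)) writeLines(line, con)
}

#' Run the full diagnostic pipeline
#'
#' Stages: load or simulate the cohort (and test-retest replicates);
#' reliability + discriminability filtering; consensus feature ranking of
#' the retained features; shape + texture signature selection; least-squares
#' fit of the chosen likelihood form (x1 = the signature's shape feature,
#' x2 = its texture feature) on the 0/1 labels; prediction; threshold
#' evaluation. Each stage writes its artifact into `outDir`
#' (`filter_report.csv`, `ranks.csv`, `signature.json`, `model.json`,
#' `scores.csv`, `eval_report.json`, plus `pipeline.log` recording the
#' parameters), so any stage can be re-run from the previous stage's file.
#' Outputs are byte-identical for identical config + seed.
#'
#' @param config list of pipeline settings (see the package vignette), or
#'   a path to a YAML file; unknown keys are rejected before any
#'   computation.
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the per-stage objects (cohort, report,
#'   ranking, signature, model, scores, evaluation).
#' @export
runPipeline <- function(config = list(), outDir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .validate_config(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logpath <- file.path(outDir, "pipeline.log")
    con <- file(logpath, "w")
    on.exit(close(con))
    writeLines(sprintf("config: %s",
                       jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                        null = "null")), con)

    # -- stage: data -------------------------------------------------
    if (is.null(cfg$table)) {
        cohort <- simulateCohort(cfg$n_malignant, cfg$n_benign,
                                 cfg$effect_size, seed = cfg$seed)
        retest <- simulateRetest(cohort, cfg$retest_noise_sd,
                                 seed = cfg$seed + 1L)
        .log_stage("data", sprintf("simulated cohort %d x %d (seed %d)",
                                   ncol(cohort), nrow(cohort), cfg$seed),
                   con)
    } else {
        cohort <- readFeatureTable(cfg$table, cfg$label_column)
        retest <- NULL
        if (!is.null(cfg$retest_a) && !is.null(cfg$retest_b)) {
            # paired replicate files: CCC computed between the two scans
            cohortA <- readFeatureTable(cfg$retest_a)
            retest <- readFeatureTable(cfg$retest_b)
            # reliability gate runs on scan A vs scan B below
            reliab_base <- cohortA
        }
        .log_stage("data", sprintf("read cohort %d x %d from %s",
                                   ncol(cohort), nrow(cohort), cfg$table),
                   con)
    }

    # -- stage: filter -----------------------------------------------
    base_for_ccc <- if (exists("reliab_base", inherits = FALSE)) {
        # external replicate pair: attach cohort labels where ids overlap
        reliab_base
    } else cohort
    report <- tryCatch({
        if (identical(base_for_ccc, cohort))
            reliabilityFilter(cohort, retest = retest,
                              cccMin = cfg$ccc_min, alpha = cfg$alpha)
        else {
            # CCC on the replicate pair, KW on the labeled cohort
            ccc_rep <- reliabilityFilter(base_for_ccc, retest = retest,
                                         cccMin = cfg$ccc_min,
                                         alpha = NULL)
            kw_rep <- reliabilityFilter(cohort, retest = NULL,
                                        alpha = cfg$alpha)
            merged <- merge(ccc_rep@results[c("feature", "ccc")],
                            kw_rep@results[c("feature", "kw_p")],
                            by = "feature", sort = FALSE)
            merged$retained <- !is.na(merged$ccc) &
                merged$ccc > cfg$ccc_min &
                !is.na(merged$kw_p) & merged$kw_p < cfg$alpha
            new("ReliabilityReport", results = merged,
                cccMin = cfg$ccc_min, alpha = cfg$alpha)
        }
    }, error = function(e) stop("stage 'filter' failed: ",
                                conditionMessage(e), call. = FALSE))
    writeReliabilityReport(report, file.path(outDir, "filter_report.csv"))
    kept <- retainedFeatures(report)
    .log_stage("filter", sprintf("%d of %d features retained -> %s",
                                 length(kept), nrow(report@results),
                                 "filter_report.csv"), con)
    if (length(kept) < 2)
        stop("stage 'filter' failed: fewer than 2 features retained",
             call. = FALSE)
    filtered <- cohort[kept, ]

    # -- stage: rank -------------------------------------------------
    ranking <- tryCatch(
        rankFeatures(filtered, group = cfg$group),
        error = function(e) stop("stage 'rank' failed: ",
                                 conditionMessage(e), call. = FALSE))
    writeRanking(ranking, file.path(outDir, "ranks.csv"))
    .log_stage("rank", sprintf("%s consensus over %s -> ranks.csv",
                               cfg$group,
                               paste(ranking@rankers, collapse = "+")),
               con)

    # -- stage: signature --------------------------------------------
    signature <- tryCatch(
        selectSignature(ranking, featureKinds(cohort), topK = cfg$top_k),
        error = function(e) stop("stage 'signature' failed: ",
                                 conditionMessage(e), call. = FALSE))
    jsonlite::write_json(
        list(shape_feature = signature@shapeFeature,
             texture_feature = signature@textureFeature,
             source_group = signature@sourceGroup),
        file.path(outDir, "signature.json"), auto_unbox = TRUE)
    .log_stage("signature", sprintf("shape = %s, texture = %s",
                                    signature@shapeFeature,
                                    signature@textureFeature), con)

    # -- stage: fit --------------------------------------------------
    lab <- sampleLabels(cohort)
    v <- assay(cohort, "features")
    x1 <- v[signature@shapeFeature, ]
    x2 <- v[signature@textureFeature, ]
    if (!is.null(cfg$clip_eps)) {
        x1 <- pmax(x1, cfg$clip_eps); x2 <- pmax(x2, cfg$clip_eps)
    }
    model <- tryCatch(
        fitLikelihood(cfg$form, x1, x2, lab,
                      x1Feature = signature@shapeFeature,
                      x2Feature = signature@textureFeature),
        error = function(e) stop("stage 'fit' failed: ",
                                 conditionMessage(e), call. = FALSE))
    writeLikelihoodModel(model, file.path(outDir, "model.json"))
    .log_stage("fit", sprintf("%s fitted, residual SE %.4f -> model.json",
                              cfg$form, model@residualSE), con)

    # -- stage: predict ----------------------------------------------
    scores <- predictLikelihood(model, x1, x2)
    pred <- classifyMalignant(scores, cfg$threshold)
    sc_df <- data.frame(sample_id = colnames(cohort),
                        y = .format_full(scores),
                        label_pred = pred, label_true = lab)
    write.csv(sc_df, file.path(outDir, "scores.csv"),
              row.names = FALSE, quote = FALSE)
    .log_stage("predict", "scores.csv written", con)

    # -- stage: evaluate ---------------------------------------------
    evaluation <- tryCatch(
        evaluateScores(scores, lab, threshold = cfg$threshold),
        error = function(e) stop("stage 'evaluate' failed: ",
                                 conditionMessage(e), call. = FALSE))
    writeEvalReport(evaluation, file.path(outDir, "eval_report.json"))
    .log_stage("evaluate",
               sprintf("accuracy %.4f, AUC %.4f -> eval_report.json",
                       evaluation@accuracy, evaluation@auc), con)

    invisible(list(cohort = cohort, report = report, ranking = ranking,
                   signature = signature, model = model, scores = scores,
                   evaluation = evaluation, config = cfg))
}
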