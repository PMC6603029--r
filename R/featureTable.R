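#' Infer radiomic feature class from a feature name
#'
#' Feature class is encoded PyRadiomics-style in the column-name prefix
#' before the first underscore ("class_Name"), matched case-insensitively
#' against the seven classes: shape, firstorder, glcm, gldm, glszm, glrlm,
#' ngtdm. Unknown prefixes fall back to `firstorder` (a texture class) with
#' a warning.
#'
#' @param names character vector of feature names.
#' @return character vector of feature classes, same length as `names`.
#' @examples
#' inferFeatureClass(c("shape_SurfaceVolumeRatio", "glcm_SumEntropy"))
#' @export
inferFeatureClass <- function(names) {
    stopifnot(is.character(names))
    prefix <- tolower(sub("_.*$", "", names))
    out <- ifelse(prefix %in% .FEATURE_CLASSES, prefix, NA_character_)
    if (anyNA(out)) {
        warning("unknown feature-class prefix for: ",
                paste(names[is.na(out)], collapse = ", "),
                "; defaulting to 'firstorder'")
        out[is.na(out)] <- "firstorder"
    }
    out
}

#' Construct a RadiomicsExperiment from a samples-by-features matrix
#'
#' @param values numeric matrix, samples in rows, features in columns
#'   (column names are the feature names; row names the sample ids). This is
#'   the orientation of the CSV exchange format; internally features are
#'   stored as rows per the SummarizedExperiment convention.
#' @param labels optional integer vector of 0/1 malignancy labels
#'   (0 = benign, 1 = malignant), one per sample.
#' @param featureClasses optional character vector of feature classes; by
#'   default inferred from the feature-name prefixes via
#'   [inferFeatureClass()].
#' @return a [RadiomicsExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("s", 1:3),
#'                             c("shape_Volume", "glcm_SumEntropy")))
#' RadiomicsExperiment(m, labels = c(0, 1, 1))
#' @export
RadiomicsExperiment <- function(values, labels = NULL, featureClasses = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(colnames(values))) {
        if (ncol(values) == 0) colnames(values) <- character(0)
        else stop("feature (column) names are required")
    }
    if (is.null(rownames(values)))
        rownames(values) <- paste0("sample", seq_len(nrow(values)))
    if (is.null(featureClasses))
        featureClasses <- if (ncol(values) == 0) character(0)
                          else inferFeatureClass(colnames(values))
    rd <- DataFrame(featureClass = featureClasses,
                    kind = ifelse(featureClasses == "shape",
                                  "shape", "texture"),
                    row.names = colnames(values))
    cd <- DataFrame(row.names = rownames(values))
    if (!is.null(labels)) {
        if (length(labels) != nrow(values))
            stop("labels must have one entry per sample")
        if (!all(labels %in% c(0, 1)))
            stop("labels must be binary 0/1")
        cd$label <- as.integer(labels)
    }
    se <- SummarizedExperiment(assays = SimpleList(features = t(values)),
                               rowData = rd, colData = cd)
    new("RadiomicsExperiment", se)
}

#' @rdname radiolik-generics
#' @export
setMethod("featureClasses", "RadiomicsExperiment", function(x)
    setNames(as.character(rowData(x)$featureClass), rownames(x)))

#' @rdname radiolik-generics
#' @export
setMethod("featureKinds", "RadiomicsExperiment", function(x)
    setNames(as.character(rowData(x)$kind), rownames(x)))

#' @rdname radiolik-generics
#' @export
setMethod("sampleLabels", "RadiomicsExperiment", function(x) {
    if (!"label" %in% colnames(colData(x))) return(NULL)
    setNames(as.integer(colData(x)$label), colnames(x))
})

#' @rdname radiolik-generics
#' @export
setMethod("featureValues", "RadiomicsExperiment", function(x)
    t(assay(x, "features")))

setMethod("show", "RadiomicsExperiment", function(object) {
    lab <- sampleLabels(object)
    cat("RadiomicsExperiment:", ncol(object), "samples x",
        nrow(object), "features\n")
    tab <- table(factor(featureClasses(object), levels = .FEATURE_CLASSES))
    cat("  classes:",
        paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    if (is.null(lab)) cat("  labels: absent\n")
    else cat(sprintf("  labels: %d malignant / %d benign\n",
                     sum(lab == 1L), sum(lab == 0L)))
})

.parse_numeric_cells <- function(df, path) {
    for (j in colnames(df)) {
        col <- df[[j]]
        if (is.numeric(col)) next
        parsed <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(parsed) & !is.na(col) & trimws(col) != "")
        if (length(bad))
            stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                         col[bad[1]], j, bad[1], basename(path)))
        df[[j]] <- parsed
    }
    df
}

#' Read a radiomic feature table from CSV
#'
#' Expects a header row with the sample id in the first column, an optional
#' 0/1 label column, and one numeric column per feature, named
#' "class_Feature" (UTF-8, "." decimal separator). Blank label cells are
#' allowed and yield a table without labels only if the whole column is
#' blank; otherwise they are rejected.
#'
#' @param path path to the CSV file.
#' @param labelColumn name of the label column, or NULL for an unlabeled
#'   table.
#' @return a [RadiomicsExperiment-class].
#' @export
readFeatureTable <- function(path, labelColumn = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(df) < 1) stop("CSV must have at least a sample-id column")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate sample ids in ", basename(path), ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    labels <- NULL
    if (!is.null(labelColumn)) {
        if (!labelColumn %in% colnames(df))
            stop("label column '", labelColumn, "' not found in ",
                 basename(path))
        raw <- trimws(df[[labelColumn]])
        raw[is.na(raw)] <- ""
        if (all(raw == "")) {
            labels <- NULL            # wholly blank label column: unlabeled
        } else {
            if (any(!raw %in% c("0", "1")))
                stop("label column '", labelColumn,
                     "' must contain only 0/1 values")
            labels <- as.integer(raw)
        }
        df[[labelColumn]] <- NULL
    }
    feat <- df[, -1, drop = FALSE]
    feat <- .parse_numeric_cells(feat, path)
    m <- as.matrix(feat)
    rownames(m) <- ids
    RadiomicsExperiment(m, labels = labels)
}

# repr-faithful decimal serialization so that read(write(x)) is bit-identical
.format_full <- function(v) {
    out <- vapply(v, function(z) {
        s <- formatC(z, digits = 15, format = "g")
        if (as.numeric(s) == z) s else formatC(z, digits = 17, format = "g")
    }, character(1))
    out
}

#' Write a radiomic feature table to CSV
#'
#' Values are serialized with repr-faithful decimal precision so that
#' [readFeatureTable()] reproduces them bit-identically.
#'
#' @param x a [RadiomicsExperiment-class].
#' @param path output CSV path.
#' @param labelColumn name used for the label column when labels are
#'   present.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(x, path, labelColumn = "label") {
    stopifnot(is(x, "RadiomicsExperiment"))
    v <- featureValues(x)
    out <- data.frame(sample_id = colnames(x), check.names = FALSE,
                      stringsAsFactors = FALSE)
    lab <- sampleLabels(x)
    if (!is.null(lab)) out[[labelColumn]] <- lab
    for (j in seq_len(ncol(v)))
        out[[colnames(v)[j]]] <- .format_full(v[, j])
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
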