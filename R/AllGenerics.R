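#' Accessor generics
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name radiolik-generics
NULL

#' @rdname radiolik-generics
#' @export
setGeneric("featureClasses", function(x) standardGeneric("featureClasses"))

#' @rdname radiolik-generics
#' @export
setGeneric("featureKinds", function(x) standardGeneric("featureKinds"))

#' @rdname radiolik-generics
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname radiolik-generics
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname radiolik-generics
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))

#' @rdname radiolik-generics
#' @export
setGeneric("consensusScores", function(x) standardGeneric("consensusScores"))

#' @rdname radiolik-generics
#' @export
setGeneric("shapeFeature", function(x) standardGeneric("shapeFeature"))

#' @rdname radiolik-generics
#' @export
setGeneric("textureFeature", function(x) standardGeneric("textureFeature"))

#' @rdname radiolik-generics
#' @export
setGeneric("formId", function(x) standardGeneric("formId"))

#' @rdname radiolik-generics
#' @export
setGeneric("residualSE", function(x) standardGeneric("residualSE"))

#' @rdname radiolik-generics
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
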