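#' @export
setGeneric("entropyMap", function(x, ...) standardGeneric("entropyMap"))

#' @export
setGeneric("predictProb", function(model, image, ...)
  standardGeneric("predictProb"))

#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))

#' @export
setGeneric("sampleTruth", function(x) standardGeneric("sampleTruth"))

#' @export
setGeneric("graderMask", function(x, which) standardGeneric("graderMask"))

#' @export
setGeneric("modelVariant", function(x) standardGeneric("modelVariant"))

#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))
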