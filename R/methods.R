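# Accessors and show methods.

#' Accessors for uncertSeg objects
#'
#' `mapValues()` extracts the numeric matrix behind a probability or entropy
#' map; `sampleImage()`, `sampleTruth()`, `graderMask()` and `sampleId()`
#' extract the rasters and identifier of a synthetic sample; `modelVariant()`,
#' `modelWeights()` and `nParameters()` describe a built model.
#'
#' @param x the object.
#' @param which grader index, 1 or 2.
#' @return the corresponding slot value; `nParameters()` returns the total
#'   count of kernel and bias parameters.
#' @name accessors
#' @aliases mapValues sampleId sampleImage sampleTruth graderMask
#'   modelVariant modelWeights nParameters
NULL

#' @rdname accessors
#' @export
setMethod("mapValues", "ProbabilityMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "EntropyMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleId", "EnFaceSample", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleImage", "EnFaceSample", function(x) x@image)

#' @rdname accessors
#' @export
setMethod("sampleTruth", "EnFaceSample", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("graderMask", "EnFaceSample", function(x, which) {
  stopIf(!which %in% 1:2, "grader index must be 1 or 2")
  if (which == 1) x@grader1 else x@grader2
})

#' @rdname accessors
#' @export
setMethod("modelVariant", "ModelConfig", function(x) x@variant)

#' @rdname accessors
#' @export
setMethod("modelVariant", "SegModel", function(x) x@config@variant)

#' @rdname accessors
#' @export
setMethod("modelWeights", "SegModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("nParameters", "SegModel", function(x) {
  sum(vapply(x@weights, function(ly) length(ly$w) + length(ly$b), numeric(1)))
})

#' @export
setMethod("dim", "EnFaceSample", function(x) dim(x@image))

#' @export
setMethod("dim", "ProbabilityMap", function(x) dim(x@values))

#' @export
setMethod("dim", "EntropyMap", function(x) dim(x@values))

setMethod("show", "EnFaceSample", function(object) {
  d <- dim(object@image)
  cat("EnFaceSample '", object@sampleId, "': ", d[1], "x", d[2], " pixels, ",
      d[3], " channel(s)\n", sep = "")
  cat("  lesion fraction: truth ", signif(mean(object@truth), 3),
      ", grader1 ", signif(mean(object@grader1), 3),
      ", grader2 ", signif(mean(object@grader2), 3), "\n", sep = "")
})

setMethod("show", "SegModel", function(object) {
  cfg <- object@config
  cat("SegModel (", cfg@variant, " variant): depth ", cfg@depth,
      ", base channels ", cfg@baseChannels, ", input channels ",
      cfg@inputChannels, "\n", sep = "")
  cat("  ", length(object@weights), " convolution layers, ",
      nParameters(object), " parameters, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@values)
  cat("ProbabilityMap ", d[1], "x", d[2], " (", object@provenance,
      ", ", object@nRuns, " run(s))\n", sep = "")
  cat("  range [", signif(min(object@values), 3), ", ",
      signif(max(object@values), 3), "]\n", sep = "")
})

setMethod("show", "EntropyMap", function(object) {
  d <- dim(object@values)
  cat("EntropyMap ", d[1], "x", d[2], " bits (unit: ", object@thresholdUnit,
      ")\n", sep = "")
  cat("  mean entropy ", signif(mean(object@values), 3), ", max ",
      signif(max(object@values), 3), "\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: ", object@imageHeight, "x", object@imageWidth, "x",
      object@nChannels, ", lesions ", object@nLesionsRange[1], "-",
      object@nLesionsRange[2], " of radius ", object@lesionRadiusRange[1],
      "-", object@lesionRadiusRange[2], " px, seed ", object@seed, "\n",
      sep = "")
})
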