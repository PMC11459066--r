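# ---- synthetic data ---------------------------------------------------------

#' Configuration for the synthetic en face generator
#'
#' Describes the geometry and noise model of seeded synthetic en-face-like
#' images: bright, irregular lesion blobs on a noisy darker background, plus
#' two simulated graders that agree in lesion cores but disagree at boundaries
#' and on small satellite lesions.
#'
#' @slot imageHeight,imageWidth image size in pixels; each must be divisible
#'   by 16 so that four exact 2x downsamplings exist.
#' @slot nChannels number of image channels (3 emulates pseudo-color).
#' @slot nLesionsRange integer interval for the number of lesions per image.
#' @slot lesionRadiusRange pixel interval for the lesion ellipse semi-axes.
#' @slot boundaryRoughness dimensionless amplitude (>= 0) of the smooth radial
#'   deformation applied to each lesion ellipse.
#' @slot backgroundIntensity,lesionIntensity mean pixel intensity outside /
#'   inside lesions, both in [0,1]; lesions must be brighter (they emulate
#'   hypertransmission defects).
#' @slot noiseSD additive Gaussian pixel noise standard deviation in [0,1].
#' @slot graderBoundarySD standard deviation, in pixels, of the smooth random
#'   boundary displacement applied per grader.
#' @slot graderSatelliteFlipProb probability that a grader deletes a small
#'   satellite component, or adds a spurious one, per image.
#' @slot satelliteMaxArea components at or below this pixel area count as
#'   satellites for the grader flip model.
#' @slot seed base seed; all generator output is a pure function of
#'   (config, seed).
#' @seealso [syntheticConfig()], [generateDataset()]
#' @export
setClass("SyntheticConfig", representation(
  imageHeight = "integer", imageWidth = "integer", nChannels = "integer",
  nLesionsRange = "integer", lesionRadiusRange = "numeric",
  boundaryRoughness = "numeric", backgroundIntensity = "numeric",
  lesionIntensity = "numeric", noiseSD = "numeric",
  graderBoundarySD = "numeric", graderSatelliteFlipProb = "numeric",
  satelliteMaxArea = "numeric", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@imageHeight %% 16L != 0L || object@imageWidth %% 16L != 0L)
    msg <- c(msg, "imageHeight and imageWidth must each be divisible by 16")
  if (object@imageHeight < 16L || object@imageWidth < 16L)
    msg <- c(msg, "image dimensions must be at least 16")
  if (length(object@nLesionsRange) != 2L ||
      any(object@nLesionsRange < 0L) || diff(object@nLesionsRange) < 0L)
    msg <- c(msg, "nLesionsRange must be a non-decreasing pair of counts >= 0")
  if (length(object@lesionRadiusRange) != 2L ||
      any(object@lesionRadiusRange <= 0) || diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be a non-decreasing pair of positive radii")
  if (object@boundaryRoughness < 0)
    msg <- c(msg, "boundaryRoughness must be >= 0")
  probs <- c(object@backgroundIntensity, object@lesionIntensity,
             object@noiseSD, object@graderSatelliteFlipProb)
  if (any(probs < 0) || any(probs > 1))
    msg <- c(msg, "intensities, noiseSD and flip probability must lie in [0,1]")
  if (object@lesionIntensity <= object@backgroundIntensity)
    msg <- c(msg, "lesionIntensity must exceed backgroundIntensity")
  if (object@graderBoundarySD < 0)
    msg <- c(msg, "graderBoundarySD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One synthetic sample: image, ground truth, and two grader masks
#'
#' @slot image numeric array (height x width x channels) with values in [0,1].
#' @slot truth,grader1,grader2 binary matrices (0/1) of the same height and
#'   width as the image.
#' @slot sampleId character identifier, unique within a dataset.
#' @seealso [generateDataset()]
#' @export
setClass("EnFaceSample", representation(
  image = "array", truth = "matrix", grader1 = "matrix", grader2 = "matrix",
  sampleId = "character"
))

setValidity("EnFaceSample", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L) msg <- c(msg, "image must be a 3-d array (H x W x C)")
  for (nm in c("truth", "grader1", "grader2")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d[1:2]))
      msg <- c(msg, paste0(nm, " dimensions must match the image"))
    if (!isBinary(m)) msg <- c(msg, paste0(nm, " must be strictly binary (0/1)"))
  }
  if (any(object@image < 0) || any(object@image > 1))
    msg <- c(msg, "image values must lie in [0,1]")
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

# ---- model ------------------------------------------------------------------

#' Architecture configuration of the segmentation network
#'
#' The network is an encoder/decoder U-Net variant: `depth + 1` convolutional
#' blocks (two 3x3 convolutions, each followed by a rectified linear unit)
#' alternate with `depth` 2x2 stride-2 max-pools; channel width starts at
#' `baseChannels` and doubles at each downsampling. Each decoder step
#' bilinearly upsamples 2x, concatenates the *remainder* of the matching
#' encoder level (see [remainderSkip()]), and applies a convolutional block.
#' The head is a dropout layer (`baseDropoutP`), a 3x3 convolution to
#' `finalHiddenChannels` with rectified linear activation, and a 3x3
#' convolution to one channel through the bounded [finalActivation()].
#' The `"drop"` variant adds dropout with probability `extraDropoutP` after
#' the last three encoder blocks and the first two decoder blocks, and keeps
#' all dropout active at inference for Monte Carlo sampling.
#'
#' @slot inputChannels number of image channels the network accepts.
#' @slot baseChannels channel width of the first encoder block (study value 32).
#' @slot depth number of downsampling steps (study value 4).
#' @slot finalHiddenChannels channels of the penultimate convolution (8).
#' @slot baseDropoutP drop probability of the head dropout layer (0.2).
#' @slot extraDropoutP drop probability of the drop-variant layers (0.5).
#' @slot variant `"standard"` or `"drop"`.
#' @seealso [modelConfig()], [buildModel()]
#' @export
setClass("ModelConfig", representation(
  inputChannels = "integer", baseChannels = "integer", depth = "integer",
  finalHiddenChannels = "integer", baseDropoutP = "numeric",
  extraDropoutP = "numeric", variant = "character"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@inputChannels < 1L) msg <- c(msg, "inputChannels must be >= 1")
  if (object@finalHiddenChannels < 1L)
    msg <- c(msg, "finalHiddenChannels must be >= 1")
  if (!object@variant %in% c("standard", "drop"))
    msg <- c(msg, "variant must be 'standard' or 'drop'")
  for (p in c(object@baseDropoutP, object@extraDropoutP))
    if (p < 0 || p >= 1) msg <- c(msg, "dropout probabilities must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' A segmentation network with weights
#'
#' @slot config a [ModelConfig-class].
#' @slot weights named list of layers, each `list(w = array(3,3,cin,cout),
#'   b = numeric(cout))`, in forward order.
#' @slot seed the seed the weights were initialized (and possibly trained)
#'   under.
#' @seealso [buildModel()], [predictProb()]
#' @export
setClass("SegModel", representation(
  config = "ModelConfig", weights = "list", seed = "integer"
))

setValidity("SegModel", function(object) {
  expected <- layerNames(object@config)
  if (!identical(names(object@weights), expected))
    return(paste0("weights must be named: ", paste(expected, collapse = ", ")))
  for (nm in expected) {
    ly <- object@weights[[nm]]
    if (!is.list(ly) || !all(c("w", "b") %in% names(ly)))
      return(paste0("layer ", nm, " must be list(w, b)"))
    dw <- dim(ly$w)
    if (length(dw) != 4L || dw[1] != 3L || dw[2] != 3L)
      return(paste0("layer ", nm, " kernel must have dim (3,3,cin,cout)"))
    if (length(ly$b) != dw[4])
      return(paste0("layer ", nm, " bias length must equal cout"))
  }
  TRUE
})

# ---- training ---------------------------------------------------------------

#' Geometric and photometric augmentation settings
#'
#' The same geometric transform (flips, 90-degree rotations, small integer
#' translations) is applied to the image and all masks of a sample;
#' photometric jitter (multiplicative contrast, additive brightness) is
#' applied to the image only. All probabilities zero gives the identity.
#'
#' @slot pFlipH,pFlipV,pRot90 probabilities of each geometric transform.
#' @slot maxShift maximum absolute translation in pixels (vacated pixels are
#'   zero-filled).
#' @slot brightnessSD,contrastSD standard deviations of the photometric
#'   jitter (additive offset; multiplicative log-scale factor).
#' @seealso [augmentConfig()], [augmentSample()]
#' @export
setClass("AugmentConfig", representation(
  pFlipH = "numeric", pFlipV = "numeric", pRot90 = "numeric",
  maxShift = "integer", brightnessSD = "numeric", contrastSD = "numeric"
))

setValidity("AugmentConfig", function(object) {
  p <- c(object@pFlipH, object@pFlipV, object@pRot90)
  if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0,1]")
  if (object@maxShift < 0L) return("maxShift must be >= 0")
  if (object@brightnessSD < 0 || object@contrastSD < 0)
    return("jitter standard deviations must be >= 0")
  TRUE
})

#' Optimization settings
#'
#' Training minimizes Dice loss plus `hoyerCoefficient` times the
#' Hoyer-Square measure of the convolution kernels, with Adam at a learning
#' rate decayed multiplicatively each epoch (study values: initial 1e-4,
#' decay 0.999, coefficient 1e-3, 5000 epochs; the package's desk-scale
#' presets train far fewer epochs).
#'
#' @slot initialLR initial learning rate (> 0).
#' @slot lrDecay multiplicative decay applied at the start of each epoch,
#'   in (0,1].
#' @slot epochs number of training epochs (>= 1).
#' @slot hoyerCoefficient weight of the Hoyer-Square regularizer (>= 0).
#' @slot batchSize full-image minibatch size.
#' @slot diceEpsilon smoothing constant of the Dice loss (guards empty masks).
#' @slot augment an [AugmentConfig-class].
#' @slot seed training seed (shuffling, augmentation draws, dropout masks).
#' @seealso [trainConfig()], [trainModel()]
#' @export
setClass("TrainConfig", representation(
  initialLR = "numeric", lrDecay = "numeric", epochs = "integer",
  hoyerCoefficient = "numeric", batchSize = "integer", diceEpsilon = "numeric",
  augment = "AugmentConfig", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@initialLR <= 0) msg <- c(msg, "initialLR must be > 0")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msg <- c(msg, "lrDecay must lie in (0,1]")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@hoyerCoefficient < 0) msg <- c(msg, "hoyerCoefficient must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@diceEpsilon < 0) msg <- c(msg, "diceEpsilon must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---- inference --------------------------------------------------------------

#' Per-pixel lesion probability map
#'
#' @slot values numeric matrix of probabilities in [0,1], same height/width
#'   as the source image.
#' @slot provenance `"single"`, `"ensemble"` or `"mc_dropout"`.
#' @slot nRuns number of forward passes averaged (1, ensemble size K, or
#'   Monte Carlo sample count T).
#' @slot sourceIds identifiers of the contributing models/runs.
#' @seealso [predictProb()], [ensemblePredict()], [mcDropoutPredict()]
#' @export
setClass("ProbabilityMap", representation(
  values = "matrix", provenance = "character", nRuns = "integer",
  sourceIds = "character"
))

setValidity("ProbabilityMap", function(object) {
  if (any(object@values < 0) || any(object@values > 1))
    return("probabilities must lie in [0,1]")
  if (!object@provenance %in% c("single", "ensemble", "mc_dropout"))
    return("provenance must be single, ensemble or mc_dropout")
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  TRUE
})

#' Per-pixel Shannon entropy map
#'
#' Binary-class Shannon entropy of a [ProbabilityMap-class], in bits; values
#' lie in [0,1] with the maximum of 1 bit at probability 0.5. Entropy
#' thresholds throughout the package are expressed on this scale, i.e. as a
#' fraction of the 1-bit maximum.
#'
#' @slot values numeric matrix of entropies in [0,1] bits.
#' @slot thresholdUnit documentation string for the threshold scale.
#' @seealso [entropyMap()], [thresholdSweep()]
#' @export
setClass("EntropyMap", representation(
  values = "matrix", thresholdUnit = "character"
))

setValidity("EntropyMap", function(object) {
  if (any(object@values < -1e-12) || any(object@values > 1 + 1e-12))
    return("entropy values must lie in [0,1] bits")
  TRUE
})
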