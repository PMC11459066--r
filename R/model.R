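# Segmentation network: a U-Net-style encoder/decoder with remainder skip
# connections, a bounded algebraic output activation, and optional Monte
# Carlo dropout layers. Convolution / pooling / upsampling primitives are
# compiled (see src/ops.cpp); the network orchestration, activations and
# dropout live here.

#' Create a model configuration
#'
#' Defaults reproduce the study architecture (base width 32, depth 4, an
#' 8-channel penultimate convolution, head dropout 0.2, drop-variant dropout
#' 0.5). `variant = "drop"` adds dropout after the last three encoder blocks
#' and the first two decoder blocks; these layers stay active at inference so
#' repeated forward passes sample the approximate posterior.
#'
#' @param inputChannels number of channels of the input image.
#' @param baseChannels channel width of the first encoder block.
#' @param depth number of 2x downsampling steps.
#' @param finalHiddenChannels output channels of the penultimate convolution.
#' @param baseDropoutP drop probability of the head dropout layer.
#' @param extraDropoutP drop probability of the drop-variant layers.
#' @param variant `"standard"` or `"drop"`.
#' @return a [ModelConfig-class] object.
#' @examples
#' modelConfig(baseChannels = 8L)
#' @export
modelConfig <- function(inputChannels = 3L, baseChannels = 32L, depth = 4L,
                        finalHiddenChannels = 8L, baseDropoutP = 0.2,
                        extraDropoutP = 0.5, variant = c("standard", "drop")) {
  variant <- match.arg(variant)
  new("ModelConfig", inputChannels = as.integer(inputChannels),
      baseChannels = as.integer(baseChannels), depth = as.integer(depth),
      finalHiddenChannels = as.integer(finalHiddenChannels),
      baseDropoutP = baseDropoutP, extraDropoutP = extraDropoutP,
      variant = variant)
}

# Ordered layer table: name, input channels, output channels.
layerSpec <- function(config) {
  d <- config@depth
  base <- config@baseChannels
  spec <- list()
  for (i in seq_len(d + 1L)) {
    cin1 <- if (i == 1L) config@inputChannels else base * 2L^(i - 2L)
    cout <- base * 2L^(i - 1L)
    spec[[paste0("enc", i, "_conv1")]] <- c(cin1, cout)
    spec[[paste0("enc", i, "_conv2")]] <- c(cout, cout)
  }
  for (j in seq_len(d)) {
    upC <- base * 2L^(d - j + 1L)
    remC <- base * 2L^(d - j)
    spec[[paste0("dec", j, "_conv1")]] <- c(upC + remC, remC)
    spec[[paste0("dec", j, "_conv2")]] <- c(remC, remC)
  }
  spec[["head_conv1"]] <- c(base, config@finalHiddenChannels)
  spec[["head_conv2"]] <- c(config@finalHiddenChannels, 1L)
  spec
}

layerNames <- function(config) names(layerSpec(config))

# Encoder blocks followed by extra (drop-variant) dropout: the last three.
encDropBlocks <- function(config) {
  n <- config@depth + 1L
  seq.int(max(1L, n - 2L), n)
}

# Decoder blocks followed by extra dropout: the first two.
decDropBlocks <- function(config) seq_len(min(2L, config@depth))

#' Build a segmentation model with seeded random initialization
#'
#' Kernels are drawn with the He (Kaiming) uniform initialization,
#' \eqn{U[-\sqrt{6/f}, \sqrt{6/f}]} with \eqn{f = 9 \cdot c_{in}} the kernel
#' fan-in, which preserves activation variance through rectified-linear
#' convolution stacks; biases start at zero. Two builds with the same
#' configuration and seed are identical; ensembles rely on distinct seeds
#' (and training folds) for member diversity.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer initialization seed.
#' @return an untrained [SegModel-class].
#' @examples
#' m <- buildModel(modelConfig(baseChannels = 4L, depth = 2L), seed = 1L)
#' nParameters(m)
#' @export
buildModel <- function(config, seed) {
  validObject(config)
  seed <- as.integer(seed)
  spec <- layerSpec(config)
  weights <- withSeed(seed, {
    lapply(spec, function(cc) {
      cin <- cc[1]; cout <- cc[2]
      bound <- sqrt(6 / (9 * cin))
      list(w = array(runif(9 * cin * cout, -bound, bound), c(3, 3, cin, cout)),
           b = numeric(cout))
    })
  })
  new("SegModel", config = config, weights = weights, seed = seed)
}

#' Remainder skip connection
#'
#' The quantity concatenated at each decoder level:
#' \deqn{rem(x) = x - upsample(downsample(x))}
#' where downsample is the 2x2 stride-2 max-pool and upsample is 2x bilinear
#' interpolation. It isolates the high-frequency content that pooling
#' discards. The bilinear convention uses half-pixel centers with edge
#' clamping, under which upsampling a 1x1 map is constant; the remainder of
#' any constant map is therefore identically zero.
#'
#' @param x a numeric matrix or a height x width x channels array with even
#'   spatial dimensions.
#' @return an object of the same shape as `x`.
#' @examples
#' remainderSkip(matrix(c(1, 3, 2, 4), 2, 2))
#' @export
remainderSkip <- function(x) {
  isMat <- is.matrix(x)
  if (isMat) dim(x) <- c(dim(x), 1L)
  stopIf(length(dim(x)) != 3L, "x must be a matrix or 3-d array")
  stopIf(any(dim(x)[1:2] %% 2L != 0L), "spatial dimensions must be even")
  stopIf(!all(is.finite(x)), "x must be finite")
  out <- x - upsample2Forward(maxpool2Forward(x)$y)
  if (isMat) dim(out) <- dim(out)[1:2]
  out
}

#' Bounded output activation
#'
#' Elementwise \deqn{final(x) = \frac{1}{2}\left(\frac{x}{\sqrt{x^2+1}} +
#' 1\right),} a strictly increasing sigmoid-like map of the reals onto the
#' open interval (0,1) with `final(0) = 0.5` and the symmetry
#' `final(-x) = 1 - final(x)`. Used after the last convolution so the output
#' is interpretable as a per-pixel lesion probability.
#'
#' @param x finite numeric vector, matrix or array.
#' @return object of the same shape with values in (0,1).
#' @examples
#' finalActivation(c(-1, 0, 1))
#' @export
finalActivation <- function(x) {
  stopIf(!all(is.finite(x)), "input must be finite")
  0.5 * (x / sqrt(x^2 + 1) + 1)
}

# Derivative of the output activation, for backpropagation.
finalActivationGrad <- function(x) 0.5 * (x^2 + 1)^(-1.5)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Inverted dropout: scales kept units by 1/(1-p) so expectations match the
# deterministic pass. Draws from the current RNG stream.
dropoutMask <- function(d, p) {
  if (p <= 0) return(NULL)
  array((runif(prod(d)) >= p) / (1 - p), d)
}

applyMask <- function(x, mask) if (is.null(mask)) x else x * mask

# Full forward pass. x is an (H, W, C) array. When stochastic = TRUE every
# dropout layer present in the architecture draws a fresh mask from the
# current RNG stream; otherwise all dropout layers are identity. Returns
# list(out = H x W probability matrix, cache) where cache holds every
# intermediate needed by nnBackward.
nnForward <- function(model, x, stochastic = FALSE, keepCache = FALSE) {
  cfg <- model@config
  w <- model@weights
  d <- cfg@depth
  stopIf(length(dim(x)) != 3L, "input must be an (H, W, C) array")
  stopIf(dim(x)[3] != cfg@inputChannels,
         "input channel count does not match the model configuration")
  stopIf(any(dim(x)[1:2] %% 2L^d != 0L),
         "spatial dimensions must be divisible by 2^depth")

  extraAt <- if (cfg@variant == "drop") encDropBlocks(cfg) else integer()
  extraDecAt <- if (cfg@variant == "drop") decDropBlocks(cfg) else integer()

  enc <- vector("list", d + 1L)
  pools <- vector("list", d)
  encOut <- vector("list", d + 1L)
  a <- x
  for (i in seq_len(d + 1L)) {
    e <- list(x1 = a)
    e$z1 <- conv3x3Forward(a, w[[paste0("enc", i, "_conv1")]]$w,
                           w[[paste0("enc", i, "_conv1")]]$b)
    e$x2 <- relu(e$z1)
    e$z2 <- conv3x3Forward(e$x2, w[[paste0("enc", i, "_conv2")]]$w,
                           w[[paste0("enc", i, "_conv2")]]$b)
    a2 <- relu(e$z2)
    e$mask <- if (stochastic && i %in% extraAt)
      dropoutMask(dim(a2), cfg@extraDropoutP) else NULL
    a2 <- applyMask(a2, e$mask)
    encOut[[i]] <- a2
    if (keepCache) enc[[i]] <- e
    if (i <= d) {
      mp <- maxpool2Forward(a2)
      a <- mp$y
      if (keepCache) pools[[i]] <- mp$idx
    } else a <- a2
  }

  dec <- vector("list", d)
  for (j in seq_len(d)) {
    s <- list(uIn = a)
    u <- upsample2Forward(a)
    level <- d - j + 1L
    remIn <- encOut[[level]]
    mpR <- maxpool2Forward(remIn)
    r <- remIn - upsample2Forward(mpR$y)
    cu <- dim(u)[3]; cr <- dim(r)[3]
    cat <- array(0, c(dim(u)[1:2], cu + cr))
    cat[, , seq_len(cu)] <- u
    cat[, , cu + seq_len(cr)] <- r
    s$remIdx <- mpR$idx
    s$catX <- cat
    s$z1 <- conv3x3Forward(cat, w[[paste0("dec", j, "_conv1")]]$w,
                           w[[paste0("dec", j, "_conv1")]]$b)
    s$x2 <- relu(s$z1)
    s$z2 <- conv3x3Forward(s$x2, w[[paste0("dec", j, "_conv2")]]$w,
                           w[[paste0("dec", j, "_conv2")]]$b)
    a <- relu(s$z2)
    s$mask <- if (stochastic && j %in% extraDecAt)
      dropoutMask(dim(a), cfg@extraDropoutP) else NULL
    a <- applyMask(a, s$mask)
    if (keepCache) dec[[j]] <- s
  }

  head <- list()
  head$mask <- if (stochastic) dropoutMask(dim(a), cfg@baseDropoutP) else NULL
  hIn <- applyMask(a, head$mask)
  head$x1 <- hIn
  head$z1 <- conv3x3Forward(hIn, w[["head_conv1"]]$w, w[["head_conv1"]]$b)
  head$x2 <- relu(head$z1)
  head$z2 <- conv3x3Forward(head$x2, w[["head_conv2"]]$w, w[["head_conv2"]]$b)
  zfin <- head$z2
  out <- finalActivation(zfin)
  dim(out) <- dim(out)[1:2]

  cache <- if (keepCache)
    list(enc = enc, pools = pools, dec = dec, head = head, zfin = zfin)
  else NULL
  list(out = out, cache = cache)
}

# Backpropagation through the cached forward pass. gOut is dLoss/dOutput as
# an H x W matrix. Returns a named list of gradients matching the weight
# layout.
nnBackward <- function(model, cache, gOut) {
  cfg <- model@config
  w <- model@weights
  d <- cfg@depth
  grads <- list()

  convBack <- function(name, xin, gy) {
    bk <- conv3x3Backward(xin, w[[name]]$w, gy)
    grads[[name]] <<- list(w = bk$gw, b = bk$gb)
    bk$gx
  }

  gz <- gOut * finalActivationGrad(cache$zfin[, , 1])
  dim(gz) <- c(dim(gz), 1L)
  g <- convBack("head_conv2", cache$head$x2, gz)
  g <- g * (cache$head$z1 > 0)
  g <- convBack("head_conv1", cache$head$x1, g)
  g <- applyMask(g, cache$head$mask)

  # g is now the gradient w.r.t. the last decoder block's output
  gEncOut <- vector("list", d + 1L)
  for (j in rev(seq_len(d))) {
    s <- cache$dec[[j]]
    g <- applyMask(g, s$mask)
    g <- g * (s$z2 > 0)
    g <- convBack(paste0("dec", j, "_conv2"), s$x2, g)
    g <- g * (s$z1 > 0)
    gCat <- convBack(paste0("dec", j, "_conv1"), s$catX, g)
    cu <- dim(s$uIn)[3]
    gU <- gCat[, , seq_len(cu), drop = FALSE]
    gR <- gCat[, , cu + seq_len(dim(gCat)[3] - cu), drop = FALSE]
    # remainder: r = e - up(pool(e))
    level <- d - j + 1L
    gEncOut[[level]] <- gR - maxpool2Backward(upsample2Adjoint(gR), s$remIdx)
    g <- upsample2Adjoint(gU)
  }

  # g is the gradient flowing into the bottleneck encoder block's output
  for (i in rev(seq_len(d + 1L))) {
    e <- cache$enc[[i]]
    gBlock <- if (i == d + 1L) g
      else maxpool2Backward(g, cache$pools[[i]])
    if (!is.null(gEncOut[[i]])) gBlock <- gBlock + gEncOut[[i]]
    gBlock <- applyMask(gBlock, e$mask)
    gBlock <- gBlock * (e$z2 > 0)
    gBlock <- convBack(paste0("enc", i, "_conv2"), e$x2, gBlock)
    gBlock <- gBlock * (e$z1 > 0)
    g <- convBack(paste0("enc", i, "_conv1"), e$x1, gBlock)
  }

  grads[layerNames(cfg)]
}

#' Run a forward pass and return a probability map
#'
#' With `dropoutActive = FALSE` the output is a deterministic function of the
#' weights and the image. With `dropoutActive = TRUE` every dropout layer in
#' the architecture samples a fresh mask, and the output is deterministic
#' given `seed`.
#'
#' @param model a [SegModel-class].
#' @param image an (H, W, C) numeric array or an [EnFaceSample-class]; spatial
#'   dimensions must be divisible by `2^depth`.
#' @param dropoutActive sample dropout masks at inference?
#' @param seed RNG seed for the dropout masks (ignored when inactive); `NULL`
#'   uses the current RNG stream.
#' @return a [ProbabilityMap-class] with provenance `"single"`.
#' @examples
#' m <- buildModel(modelConfig(inputChannels = 1L, baseChannels = 2L,
#'                             depth = 2L), seed = 1L)
#' p <- predictProb(m, array(runif(16 * 16), c(16, 16, 1)))
#' range(mapValues(p))
#' @export
setMethod("predictProb", "SegModel",
  function(model, image, dropoutActive = FALSE, seed = NULL) {
    if (is(image, "EnFaceSample")) image <- image@image
    run <- function() nnForward(model, image, stochastic = dropoutActive)$out
    out <- if (dropoutActive && !is.null(seed)) withSeed(seed, run()) else run()
    new("ProbabilityMap", values = out, provenance = "single", nRuns = 1L,
        sourceIds = paste0("model_seed_", model@seed))
  })

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the architecture configuration,
#' all weights, and the model seed.
#'
#' @param model a [SegModel-class].
#' @param path checkpoint file path.
#' @return `loadModel()` returns the restored [SegModel-class];
#'   `saveModel()` returns `path` invisibly.
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  saveRDS(list(
    config = list(inputChannels = cfg@inputChannels,
                  baseChannels = cfg@baseChannels, depth = cfg@depth,
                  finalHiddenChannels = cfg@finalHiddenChannels,
                  baseDropoutP = cfg@baseDropoutP,
                  extraDropoutP = cfg@extraDropoutP, variant = cfg@variant),
    weights = model@weights, seed = model@seed), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(modelConfig, ck$config)
  new("SegModel", config = cfg, weights = ck$weights, seed = ck$seed)
}
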