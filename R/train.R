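# Training: Dice loss with Hoyer-Square regularization, Adam with
# multiplicative learning-rate decay, paired geometric/photometric
# augmentation, k-fold splits and ensemble training.

#' Create an augmentation configuration
#'
#' @param pFlipH,pFlipV,pRot90 probabilities of horizontal flip, vertical
#'   flip, and a 90/180/270-degree rotation.
#' @param maxShift maximum absolute integer translation in pixels.
#' @param brightnessSD additive brightness jitter standard deviation.
#' @param contrastSD log-scale multiplicative contrast jitter standard
#'   deviation.
#' @return an [AugmentConfig-class].
#' @export
augmentConfig <- function(pFlipH = 0.5, pFlipV = 0.5, pRot90 = 0.5,
                          maxShift = 4L, brightnessSD = 0.05,
                          contrastSD = 0.05) {
  new("AugmentConfig", pFlipH = pFlipH, pFlipV = pFlipV, pRot90 = pRot90,
      maxShift = as.integer(maxShift), brightnessSD = brightnessSD,
      contrastSD = contrastSD)
}

#' Create a training configuration
#'
#' Defaults follow the study's optimization settings (Adam at 1e-4 with
#' multiplicative decay 0.999 per epoch, Dice loss, Hoyer-Square coefficient
#' 1e-3) at a desk-scale epoch count; the study itself trained for 5000
#' epochs. The learning rate used during epoch `e` (1-based) is
#' `initialLR * lrDecay^e`.
#'
#' @param initialLR initial learning rate.
#' @param lrDecay per-epoch multiplicative decay.
#' @param epochs number of epochs.
#' @param hoyerCoefficient weight of the Hoyer-Square penalty on convolution
#'   kernels.
#' @param batchSize full-image minibatch size.
#' @param diceEpsilon Dice-loss smoothing constant; keeps the loss defined on
#'   empty masks.
#' @param augment an [AugmentConfig-class].
#' @param seed training seed (shuffling, augmentation, dropout).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(initialLR = 1e-4, lrDecay = 0.999, epochs = 50L,
                        hoyerCoefficient = 1e-3, batchSize = 8L,
                        diceEpsilon = 1, augment = augmentConfig(),
                        seed = 1L) {
  new("TrainConfig", initialLR = initialLR, lrDecay = lrDecay,
      epochs = as.integer(epochs), hoyerCoefficient = hoyerCoefficient,
      batchSize = as.integer(batchSize), diceEpsilon = diceEpsilon,
      augment = augment, seed = as.integer(seed))
}

#' Dice loss
#'
#' One minus the smoothed Dice coefficient between a probability map and a
#' binary target:
#' \deqn{L = 1 - \frac{2\sum p t + \epsilon}{\sum p + \sum t + \epsilon}.}
#' The smoothing constant keeps the loss defined (and its gradient bounded)
#' when both masks are empty.
#'
#' @param prob numeric matrix/array of probabilities.
#' @param target binary mask of the same shape.
#' @param epsilon smoothing constant (default 1).
#' @return a scalar in [0,1].
#' @examples
#' diceLoss(matrix(0.5, 4, 4), matrix(rep(0:1, each = 8), 4, 4), epsilon = 0)
#' @export
diceLoss <- function(prob, target, epsilon = 1) {
  stopIf(!identical(dim(prob), dim(target)), "shape mismatch")
  stopIf(!isBinary(target), "target must be binary")
  1 - (2 * sum(prob * target) + epsilon) / (sum(prob) + sum(target) + epsilon)
}

# Gradient of diceLoss with respect to prob.
diceLossGrad <- function(prob, target, epsilon = 1) {
  num <- 2 * sum(prob * target) + epsilon
  den <- sum(prob) + sum(target) + epsilon
  -(2 * target * den - num) / den^2
}

#' Hoyer-Square sparsity measure
#'
#' \deqn{HS(w) = \frac{(\sum_i |w_i|)^2}{\sum_i w_i^2},} a scale-invariant
#' sparsity measure bounded between 1 (one nonzero entry) and `length(w)`
#' (all entries equal in magnitude). The all-zero vector is assigned 0 by
#' convention. During training the penalty is computed per convolution
#' kernel array (biases excluded) and summed.
#'
#' @param w numeric vector or array of weights.
#' @return a nonnegative scalar.
#' @examples
#' hoyerSquare(c(3, -4))  # 49/25
#' @export
hoyerSquare <- function(w) {
  s2 <- sum(w^2)
  if (s2 == 0) return(0)
  sum(abs(w))^2 / s2
}

# Gradient of hoyerSquare.
hoyerSquareGrad <- function(w) {
  s1 <- sum(abs(w)); s2 <- sum(w^2)
  if (s2 == 0) return(w * 0)
  2 * s1 * sign(w) / s2 - 2 * s1^2 * w / s2^2
}

# Total Hoyer-Square penalty over a model's convolution kernels.
hoyerPenalty <- function(weights) sum(vapply(weights, function(ly)
  hoyerSquare(ly$w), numeric(1)))

#' Split a dataset into k folds
#'
#' Seeded shuffle followed by round-robin assignment; fold sizes differ by at
#' most one.
#'
#' @param dataset list of [EnFaceSample-class] objects (or anything with
#'   length and, optionally, `sampleId`s).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return an integer vector of fold indices in 1..k, named by sample id
#'   where available, with attribute `k`.
#' @examples
#' makeFolds(as.list(1:10), k = 5, seed = 1)
#' @export
makeFolds <- function(dataset, k, seed) {
  n <- length(dataset)
  stopIf(n < k, "dataset must contain at least k samples")
  ord <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  ids <- tryCatch(vapply(dataset, sampleId, character(1)),
                  error = function(e) NULL)
  if (!is.null(ids)) names(fold) <- ids
  attr(fold, "k") <- as.integer(k)
  fold
}

# Integer translation with zero fill.
shiftMatrix <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  H <- nrow(m); W <- ncol(m)
  rs <- max(1, 1 + dy):min(H, H + dy)
  cs <- max(1, 1 + dx):min(W, W + dx)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

rot90Matrix <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Apply paired augmentation to an image and its masks
#'
#' Draws one geometric transform (flips, optional 90-degree rotation for
#' square rasters, small integer translation) and applies it identically to
#' the image and every mask; photometric jitter (multiplicative contrast and
#' additive brightness, clipped to [0,1]) is applied to the image only.
#' All-zero probabilities and shift give the identity. Draws come from the
#' current RNG stream unless `seed` is given.
#'
#' @param image (H, W, C) array.
#' @param masks list of binary matrices.
#' @param config an [AugmentConfig-class].
#' @param seed optional seed.
#' @return `list(image, masks)` with the same shapes.
#' @export
augmentSample <- function(image, masks, config, seed = NULL) {
  run <- function() {
    H <- dim(image)[1]; W <- dim(image)[2]
    stopIf(!all(vapply(masks, function(m) identical(dim(m), c(H, W)),
                       logical(1))), "mask dimensions must match the image")
    doFlipH <- runif(1) < config@pFlipH
    doFlipV <- runif(1) < config@pFlipV
    rotK <- if (runif(1) < config@pRot90 && H == W) runifInt(1L, 3L) else 0L
    dy <- if (config@maxShift > 0) runifInt(-config@maxShift, config@maxShift) else 0L
    dx <- if (config@maxShift > 0) runifInt(-config@maxShift, config@maxShift) else 0L
    geom <- function(m) {
      if (doFlipH) m <- m[, ncol(m):1, drop = FALSE]
      if (doFlipV) m <- m[nrow(m):1, , drop = FALSE]
      if (rotK > 0) m <- rot90Matrix(m, rotK)
      if (dy != 0 || dx != 0) m <- shiftMatrix(m, dy, dx)
      m
    }
    img <- array(0, dim(image))
    for (c in seq_len(dim(image)[3])) img[, , c] <- geom(image[, , c])
    cFac <- if (config@contrastSD > 0) exp(rnorm(1, 0, config@contrastSD)) else 1
    bOff <- if (config@brightnessSD > 0) rnorm(1, 0, config@brightnessSD) else 0
    img <- clip01(img * cFac + bOff)
    list(image = img, masks = lapply(masks, geom))
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

# One Adam update over the named gradient list; state lives in an
# environment so the optimizer persists across steps.
adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    for (part in c("w", "b")) {
      g <- grads[[nm]][[part]]
      key <- paste0(nm, ".", part)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / c1
      vhat <- state$v[[key]] / c2
      weights[[nm]][[part]] <- weights[[nm]][[part]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  weights
}

# Deterministic validation Dice (probabilities binarized at `cutoff`).
validationDice <- function(model, valSet, target = "truth", cutoff = 0.5) {
  if (length(valSet) == 0) return(NA_real_)
  mean(vapply(valSet, function(s) {
    p <- nnForward(model, s@image)$out
    diceBinary(p >= cutoff, slot(s, target))
  }, numeric(1)))
}

#' Train a segmentation model
#'
#' Minimizes per-batch `mean(Dice loss) + hoyerCoefficient * HS(kernels)`
#' with Adam. The learning rate during epoch `e` is
#' `initialLR * lrDecay^e`. Augmentation and dropout draws, and the epoch
#' shuffles, all derive from `config@seed`, so training is reproducible
#' bit-for-bit. Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an initialized [SegModel-class].
#' @param trainSet,valSet lists of [EnFaceSample-class] objects; `valSet` may
#'   be empty.
#' @param config a [TrainConfig-class].
#' @param target which mask to fit: `"truth"` (default), `"grader1"` or
#'   `"grader2"`.
#' @return `list(model, log)` where `log` is a per-epoch data frame with
#'   columns `epoch`, `lr`, `loss_dice`, `loss_hoyer`, `loss_total`,
#'   `val_dice`.
#' @export
trainModel <- function(model, trainSet, valSet = list(), config,
                       target = c("truth", "grader1", "grader2")) {
  target <- match.arg(target)
  stopIf(length(trainSet) == 0, "training set must be nonempty")
  validObject(config)
  weights <- model@weights
  state <- new.env(parent = emptyenv())
  state$t <- 0; state$m <- list(); state$v <- list()
  n <- length(trainSet)
  log <- vector("list", config@epochs)

  withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      lr <- config@initialLR * config@lrDecay^epoch
      ord <- sample.int(n)
      starts <- seq(1, n, by = config@batchSize)
      epDice <- 0; epHoyer <- 0; nBatch <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config@batchSize - 1, n)]
        acc <- NULL
        batchDice <- 0
        for (i in idx) {
          smp <- trainSet[[i]]
          aug <- augmentSample(smp@image, list(slot(smp, target)),
                               config@augment)
          cur <- model
          cur@weights <- weights
          fw <- nnForward(cur, aug$image, stochastic = TRUE, keepCache = TRUE)
          ld <- diceLoss(fw$out, aug$masks[[1]], config@diceEpsilon)
          stopIf(!is.finite(ld),
                 "training diverged: non-finite loss at epoch ", epoch)
          batchDice <- batchDice + ld
          gOut <- diceLossGrad(fw$out, aug$masks[[1]], config@diceEpsilon)
          gr <- nnBackward(cur, fw$cache, gOut)
          if (is.null(acc)) acc <- gr
          else for (nm in names(acc)) {
            acc[[nm]]$w <- acc[[nm]]$w + gr[[nm]]$w
            acc[[nm]]$b <- acc[[nm]]$b + gr[[nm]]$b
          }
        }
        nb <- length(idx)
        hs <- hoyerPenalty(weights)
        for (nm in names(acc)) {
          acc[[nm]]$w <- acc[[nm]]$w / nb +
            config@hoyerCoefficient * hoyerSquareGrad(weights[[nm]]$w)
          acc[[nm]]$b <- acc[[nm]]$b / nb
        }
        weights <- adamStep(weights, acc, state, lr)
        epDice <- epDice + batchDice / nb
        epHoyer <- epHoyer + hs
        nBatch <- nBatch + 1
      }
      cur <- model
      cur@weights <- weights
      log[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, loss_dice = epDice / nBatch,
        loss_hoyer = epHoyer / nBatch,
        loss_total = epDice / nBatch +
          config@hoyerCoefficient * epHoyer / nBatch,
        val_dice = validationDice(cur, valSet, target = "truth"))
    }
  })

  model@weights <- weights
  list(model = model, log = do.call(rbind, log))
}

#' Train an ensemble by k-fold cross-validation
#'
#' The dataset is split into `k` folds; member `j` is validated on fold `j`
#' and trained on the others, from a distinct seeded initialization — the
#' study's recipe for its five-member ensemble. Member 1 doubles as the
#' single-model baseline.
#'
#' @param dataset list of [EnFaceSample-class] objects.
#' @param modelCfg a [ModelConfig-class] shared by all members.
#' @param trainCfg a [TrainConfig-class]; member seeds are derived from
#'   `trainCfg@seed`.
#' @param k number of folds (default 5).
#' @param members which members to train (default all `k`).
#' @param target training target mask.
#' @return `list(models, logs, folds)`: trained members (named `UNet-j`),
#'   their training logs, and the fold assignment.
#' @export
trainEnsemble <- function(dataset, modelCfg, trainCfg, k = 5L,
                          members = seq_len(k), target = "truth") {
  folds <- makeFolds(dataset, k, seed = seedHash(trainCfg@seed, 555L))
  models <- list(); logs <- list()
  for (j in members) {
    init <- buildModel(modelCfg, seed = seedHash(trainCfg@seed, j, 101L))
    cfgJ <- trainCfg
    cfgJ@seed <- seedHash(trainCfg@seed, j, 202L)
    fit <- trainModel(init, dataset[folds != j], dataset[folds == j],
                      cfgJ, target = target)
    models[[paste0("UNet-", j)]] <- fit$model
    logs[[paste0("UNet-", j)]] <- fit$log
  }
  list(models = models, logs = logs, folds = folds)
}
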