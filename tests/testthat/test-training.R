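test_that("dice loss matches hand arithmetic and a scalar oracle", {
  t4 <- matrix(rep(c(1, 0), each = 8), 4, 4)
  expect_equal(diceLoss(t4, t4, epsilon = 0), 0)          # perfect overlap
  expect_equal(diceLoss(t4 * 0, t4, epsilon = 0), 1)      # no overlap
  # p = 0.5 everywhere against a half-full target: 1 - (2*4)/(8+8) = 0.5
  expect_equal(diceLoss(matrix(0.5, 4, 4), t4, epsilon = 0), 0.5)
  set.seed(1)
  for (rep in 1:10) {
    p <- matrix(runif(36), 6, 6)
    t <- matrix(rbinom(36, 1, 0.4), 6, 6)
    expect_equal(diceLoss(p, t, epsilon = 1), naiveDiceLoss(p, t, 1),
                 tolerance = 1e-12)
  }
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("dice loss gradient agrees with finite differences", {
  set.seed(2)
  p <- matrix(runif(16, 0.1, 0.9), 4, 4)
  t <- matrix(rbinom(16, 1, 0.5), 4, 4)
  g <- uncertSeg:::diceLossGrad(p, t, epsilon = 1)
  for (i in c(1, 7, 16)) {
    p2 <- p; p2[i] <- p[i] + 1e-7
    expect_equal(g[i], (diceLoss(p2, t, 1) - diceLoss(p, t, 1)) / 1e-7,
                 tolerance = 1e-5)
  }
})

test_that("Hoyer-Square matches its closed form, bounds and scale invariance", {
  expect_equal(hoyerSquare(5), 1)                 # single nonzero weight
  expect_equal(hoyerSquare(c(1, 1)), 2)
  expect_equal(hoyerSquare(c(3, -4)), 1.96)
  expect_equal(hoyerSquare(numeric(3)), 0)        # all-zero convention
  set.seed(3)
  for (rep in 1:20) {
    w <- rnorm(1 + rep %% 7 * 10)
    expect_equal(hoyerSquare(w), naiveHoyerSquare(w), tolerance = 1e-10)
    expect_gte(hoyerSquare(w), 1)
    expect_lte(hoyerSquare(w), length(w))
    expect_equal(hoyerSquare(w * 3.7), hoyerSquare(w), tolerance = 1e-12)
  }
})

test_that("fold assignment partitions the data with balanced sizes", {
  f10 <- makeFolds(as.list(1:10), k = 5, seed = 1)
  expect_identical(as.vector(table(f10)), rep(2L, 5))
  expect_identical(f10, makeFolds(as.list(1:10), k = 5, seed = 1))
  f11 <- makeFolds(as.list(1:11), k = 5, seed = 2)
  expect_identical(sort(as.vector(table(f11))), c(2L, 2L, 2L, 2L, 3L))
  expect_error(makeFolds(as.list(1:3), k = 5, seed = 1), "at least k")
  # named by sample id when available
  ds <- generateDataset(tinySynConfig(), 4)
  fd <- makeFolds(ds, k = 2, seed = 3)
  expect_identical(names(fd), vapply(ds, sampleId, character(1)))
})

test_that("augmentation applies one geometric transform to image and masks alike", {
  img <- array(runif(32 * 32 * 2), c(32, 32, 2))
  mask <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  idCfg <- augmentConfig(pFlipH = 0, pFlipV = 0, pRot90 = 0, maxShift = 0L,
                         brightnessSD = 0, contrastSD = 0)
  out <- augmentSample(img, list(mask), idCfg, seed = 1L)
  expect_identical(out$image, img)                      # identity limit
  expect_identical(out$masks[[1]], mask)
  # a forced horizontal flip is an involution
  flipCfg <- augmentConfig(pFlipH = 1, pFlipV = 0, pRot90 = 0, maxShift = 0L,
                           brightnessSD = 0, contrastSD = 0)
  once <- augmentSample(img, list(mask), flipCfg, seed = 2L)
  twice <- augmentSample(once$image, once$masks, flipCfg, seed = 3L)
  expect_identical(twice$image, img)
  expect_identical(twice$masks[[1]], mask)
  # flips/rotations preserve mask area exactly; translations only crop
  areaCfg <- augmentConfig(maxShift = 0L, brightnessSD = 0, contrastSD = 0)
  for (s in 1:50) {
    out <- augmentSample(img, list(mask), areaCfg, seed = 100L + s)
    expect_identical(sum(out$masks[[1]]), sum(mask))
    expect_true(all(out$masks[[1]] %in% c(0, 1)))
  }
  shiftCfg <- augmentConfig(pFlipH = 0, pFlipV = 0, pRot90 = 0,
                            maxShift = 4L, brightnessSD = 0, contrastSD = 0)
  for (s in 1:50) {
    out <- augmentSample(img, list(mask), shiftCfg, seed = 200L + s)
    a <- sum(out$masks[[1]])
    expect_lte(a, sum(mask))
    expect_gte(a, sum(mask) - 4 * (32 + 32))  # at most the cropped border
  }
})

test_that("training follows the decayed LR schedule and decomposed loss", {
  ds <- generateDataset(tinySynConfig(seed = 21L), 4)
  cfg <- tinyModelConfig()
  cfg@inputChannels <- 3L
  m <- buildModel(cfg, seed = 1L)
  tc <- trainConfig(epochs = 10L, batchSize = 2L, seed = 4L)
  fit <- trainModel(m, ds, list(), tc)
  # closed-form schedule: lr at logged epoch e is 1e-4 * 0.999^e
  expect_equal(fit$log$lr[10], 1e-4 * 0.999^10, tolerance = 1e-12)
  expect_equal(fit$log$lr / c(1e-4, fit$log$lr[-10]), rep(0.999, 10),
               tolerance = 1e-12)
  # recorded total loss decomposes exactly
  expect_equal(fit$log$loss_total,
               fit$log$loss_dice + tc@hoyerCoefficient * fit$log$loss_hoyer,
               tolerance = 1e-8)
  expect_identical(nrow(fit$log), 10L)
})

test_that("training is reproducible and reduces the loss on an easy task", {
  ds <- generateDataset(tinySynConfig(seed = 33L), 8)
  cfg <- modelConfig(inputChannels = 3L, baseChannels = 4L, depth = 2L)
  tc <- trainConfig(initialLR = 3e-4, epochs = 10L, batchSize = 1L, seed = 6L)
  f1 <- trainModel(buildModel(cfg, 2L), ds, list(), tc)
  f2 <- trainModel(buildModel(cfg, 2L), ds, list(), tc)
  expect_identical(f1$model@weights, f2$model@weights)   # bit reproducible
  expect_identical(f1$log, f2$log)
  expect_lt(f1$log$loss_dice[10], f1$log$loss_dice[1])   # training progress
})

test_that("ensemble members train on complementary folds with distinct seeds", {
  ds <- generateDataset(tinySynConfig(seed = 44L), 6)
  mCfg <- modelConfig(inputChannels = 3L, baseChannels = 2L, depth = 2L)
  tCfg <- trainConfig(initialLR = 3e-4, epochs = 2L, batchSize = 2L, seed = 8L)
  ens <- trainEnsemble(ds, mCfg, tCfg, k = 3L)
  expect_named(ens$models, c("UNet-1", "UNet-2", "UNet-3"))
  expect_identical(sort(as.vector(table(ens$folds))), c(2L, 2L, 2L))
  expect_false(identical(ens$models[["UNet-1"]]@weights,
                         ens$models[["UNet-2"]]@weights))
  # reproducible end to end
  ens2 <- trainEnsemble(ds, mCfg, tCfg, k = 3L)
  expect_identical(ens$models[["UNet-3"]]@weights,
                   ens2$models[["UNet-3"]]@weights)
})
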