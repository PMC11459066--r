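test_that("lesion mask generation is deterministic and respects the count range", {
  cfg <- syntheticConfig(seed = 3L)
  expect_identical(generateLesionMask(cfg, 17L), generateLesionMask(cfg, 17L))
  # no lesions forces an empty mask
  cfg0 <- syntheticConfig(nLesionsRange = c(0L, 0L))
  expect_true(all(generateLesionMask(cfg0, 1L) == 0))
  # 3 requested lesions on 128x128: between 1 and 3 components (merging
  # allowed), foreground strictly between 0 and half the image
  cfg3 <- syntheticConfig(nLesionsRange = c(3L, 3L),
                          lesionRadiusRange = c(10, 20))
  for (s in 1:100) {
    m <- generateLesionMask(cfg3, s)
    nc <- countComponents(m)
    expect_gte(nc, 1); expect_lte(nc, 3)
    f <- mean(m)
    expect_gt(f, 0); expect_lt(f, 0.5)
  }
  expect_error(syntheticConfig(imageHeight = 100L), "divisible by 16")
})

test_that("rendering places the configured intensities with Gaussian noise", {
  cfg <- syntheticConfig(noiseSD = 0)
  empty <- matrix(0, 128, 128)
  imgE <- renderEnface(empty, cfg, 1L)
  expect_true(all(imgE == cfg@backgroundIntensity))
  full <- matrix(1, 128, 128)
  imgF <- renderEnface(full, cfg, 1L)
  expect_true(all(imgF == cfg@lesionIntensity))
  # noisy case: per-region means within 3 standard errors of their targets
  cfgN <- syntheticConfig(noiseSD = 0.05)
  half <- matrix(rep(c(0, 1), each = 128 * 64), 128, 128)
  img <- renderEnface(half, cfgN, 2L)
  for (ch in 1:3) {
    nReg <- 128 * 64
    se <- 3 * 0.05 / sqrt(nReg)
    expect_lt(abs(mean(img[, 1:64, ch]) - cfgN@backgroundIntensity), se)
    expect_lt(abs(mean(img[, 65:128, ch]) - cfgN@lesionIntensity),
              se + 1e-3)  # clipping at 1 nudges the lesion mean slightly
  }
  expect_error(renderEnface(matrix(0, 64, 64), cfg, 1L), "dimensions")
})

test_that("grader simulation perturbs boundaries but preserves cores", {
  cfg <- syntheticConfig(graderBoundarySD = 0, graderSatelliteFlipProb = 0)
  truth <- generateLesionMask(cfg, 5L)
  expect_identical(simulateGrader(truth, cfg, 1L), truth)   # identity limit
  zero <- matrix(0, 128, 128)
  expect_true(all(simulateGrader(zero, cfg, 1L) == 0))
  # a displaced disk stays close to the original: Dice in (0.8, 1] always
  cfg2 <- syntheticConfig(graderBoundarySD = 2, graderSatelliteFlipProb = 0)
  disk <- diskTruth <- matrix(0, 128, 128)
  disk[(row(disk) - 64)^2 + (col(disk) - 64)^2 <= 20^2] <- 1
  for (s in 1:50) {
    g <- simulateGrader(disk, cfg2, s)
    d <- plainDice(disk, g)
    expect_gt(d, 0.8); expect_lte(d, 1)
  }
})

test_that("grader fidelity degrades monotonically with boundary displacement", {
  sds <- c(0, 1, 2, 4)
  meanDice <- vapply(sds, function(sd) {
    cfg <- syntheticConfig(imageHeight = 64L, imageWidth = 64L,
                           nLesionsRange = c(1L, 2L),
                           lesionRadiusRange = c(5, 12),
                           graderBoundarySD = sd,
                           graderSatelliteFlipProb = 0)
    mean(vapply(1:20, function(s) {
      truth <- generateLesionMask(cfg, s)
      plainDice(truth, simulateGrader(truth, cfg, 1000L + s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanDice) <= 0))
})

test_that("datasets are reproducible, prefix-stable, and internally consistent", {
  cfg <- tinySynConfig(seed = 9L, size = 64L)
  d1 <- generateDataset(cfg, 5)
  d2 <- generateDataset(cfg, 5)
  for (i in 1:5) {
    expect_identical(d1[[i]]@image, d2[[i]]@image)
    expect_identical(d1[[i]]@grader2, d2[[i]]@grader2)
  }
  # appending samples never changes earlier ones
  d8 <- generateDataset(cfg, 8)
  expect_identical(d8[[3]]@image, d1[[3]]@image)
  # shapes/binarity enforced by the class validity
  expect_true(validObject(d1[[1]]))
  expect_error(generateDataset(cfg, 0), "nSamples")
  # graders agree well but not perfectly under the default perturbations
  cfgD <- syntheticConfig(seed = 2L)
  ds <- generateDataset(cfgD, 20)
  inter <- mean(vapply(ds, function(s) plainDice(s@grader1, s@grader2),
                       numeric(1)))
  expect_gt(inter, 0.7); expect_lt(inter, 1)
})
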