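test_that("entropy map implements binary Shannon entropy in bits", {
  expect_equal(entropyMap(c(0, 1)), c(0, 0))
  expect_equal(entropyMap(0.5), 1)
  expect_equal(entropyMap(0.25), -(0.25 * log2(0.25) + 0.75 * log2(0.75)),
               tolerance = 1e-15)
  p <- seq(0.001, 0.999, length.out = 10000)
  expect_equal(entropyMap(p), -(p * log2(p) + (1 - p) * log2(1 - p)),
               tolerance = 1e-12)
  # symmetry p <-> 1-p (up to the rounding of 1-p itself)
  expect_equal(entropyMap(p), entropyMap(1 - p), tolerance = 1e-14)
  # concavity on random pairs
  set.seed(4)
  a <- runif(200); b <- runif(200)
  expect_true(all(entropyMap((a + b) / 2) >=
                  (entropyMap(a) + entropyMap(b)) / 2 - 1e-12))
  expect_error(entropyMap(1.2), "lie in")
  # S4 path wraps the same values
  pm <- new("ProbabilityMap", values = matrix(c(0.25, 0.5, 0, 1), 2, 2),
            provenance = "single", nRuns = 1L, sourceIds = "m")
  em <- entropyMap(pm)
  expect_s4_class(em, "EntropyMap")
  expect_equal(mapValues(em), matrix(entropyMap(c(0.25, 0.5, 0, 1)), 2, 2))
})

test_that("Monte Carlo dropout averaging is seeded and shrinks with T", {
  m <- buildModel(tinyModelConfig("drop"), seed = 2L)
  x <- array(runif(16 * 16), c(16, 16, 1))
  # T = 1 equals a single dropout-active forward with the derived seed
  one <- mcDropoutPredict(m, x, T = 1L, seed = 10L)
  direct <- predictProb(m, x, dropoutActive = TRUE,
                        seed = uncertSeg:::seedHash(10L, 1L))
  expect_identical(mapValues(one), mapValues(direct))
  # reproducible for fixed (seed, T)
  a <- mcDropoutPredict(m, x, T = 4L, seed = 11L)
  b <- mcDropoutPredict(m, x, T = 4L, seed = 11L)
  expect_identical(mapValues(a), mapValues(b))
  expect_identical(a@nRuns, 4L)
  expect_identical(a@provenance, "mc_dropout")
  # standard-variant models cannot be sampled
  ms <- buildModel(tinyModelConfig("standard"), seed = 2L)
  expect_error(mcDropoutPredict(ms, x, T = 2L), "drop-variant")
})

test_that("ensemble averaging reduces to its members correctly", {
  cfg <- tinyModelConfig()
  m1 <- buildModel(cfg, seed = 1L)
  m2 <- buildModel(cfg, seed = 2L)
  x <- array(runif(16 * 16), c(16, 16, 1))
  # K = 1: exactly the single model's output
  expect_identical(mapValues(ensemblePredict(list(m1), x)),
                   mapValues(predictProb(m1, x)))
  # identical members: exactly the single model's output
  same <- ensemblePredict(list(m1, m1, m1, m1, m1), x)
  expect_equal(mapValues(same), mapValues(predictProb(m1, x)),
               tolerance = 1e-15)
  expect_identical(same@provenance, "ensemble")
  # hand arithmetic at a pixel: mean of member probabilities
  p1 <- mapValues(predictProb(m1, x)); p2 <- mapValues(predictProb(m2, x))
  avg <- mapValues(ensemblePredict(list(m1, m2), x))
  expect_equal(avg, (p1 + p2) / 2, tolerance = 1e-15)
  # member order does not matter
  expect_equal(mapValues(ensemblePredict(list(m2, m1), x)), avg,
               tolerance = 1e-12)
  expect_error(ensemblePredict(list(), x), "at least one")
  m3 <- buildModel(modelConfig(inputChannels = 2L, baseChannels = 2L,
                               depth = 2L), seed = 3L)
  expect_error(ensemblePredict(list(m1, m3), x), "input specification")
})

test_that("run order does not change a Monte Carlo average", {
  m <- buildModel(tinyModelConfig("drop"), seed = 6L)
  x <- array(runif(16 * 16), c(16, 16, 1))
  runs <- lapply(1:6, function(t)
    mapValues(predictProb(m, x, dropoutActive = TRUE,
                          seed = uncertSeg:::seedHash(31L, t))))
  fwd <- Reduce(`+`, runs) / 6
  rev6 <- Reduce(`+`, rev(runs)) / 6
  expect_equal(fwd, rev6, tolerance = 1e-12)
  expect_equal(mapValues(mcDropoutPredict(m, x, T = 6L, seed = 31L)), fwd,
               tolerance = 1e-12)
})
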