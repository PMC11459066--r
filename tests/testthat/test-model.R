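test_that("remainder skip matches hand-computed and oracle values", {
  # maxpool of [[1,2],[3,4]]-style block is 4; upsampling a 1x1 is constant
  expect_identical(remainderSkip(matrix(c(1, 3, 2, 4), 2, 2)),
                   matrix(c(-3, -1, -2, 0), 2, 2))
  # remainder of any constant array is identically zero
  for (c in c(-2, 0, 7.5))
    expect_equal(max(abs(remainderSkip(matrix(c, 8, 8)))), 0)
  # exact agreement with the naive loop implementation on random inputs
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(rnorm(64), 8, 8)
    expect_equal(remainderSkip(x), naiveRemainder(x), tolerance = 1e-14)
    expect_equal(remainderSkip(remainderSkip(x)),
                 naiveRemainder(naiveRemainder(x)), tolerance = 1e-13)
  }
  # multi-channel arrays are handled per channel
  a <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  r <- remainderSkip(a)
  for (ch in 1:3) expect_equal(r[, , ch], naiveRemainder(a[, , ch]),
                               tolerance = 1e-14)
  expect_error(remainderSkip(matrix(0, 3, 4)), "even")
})

test_that("final activation is the bounded algebraic sigmoid", {
  expect_identical(finalActivation(0), 0.5)
  expect_equal(finalActivation(sqrt(3)), 0.5 * (sqrt(3) / 2 + 1),
               tolerance = 1e-15)
  x <- seq(-30, 30, length.out = 2001)
  y <- finalActivation(x)
  expect_true(all(diff(y) > 0))                      # strictly increasing
  expect_true(all(y > 0 & y < 1))
  expect_equal(finalActivation(-x), 1 - y, tolerance = 1e-12)
  # deep negative tail: 1/(4 x^2) asymptotics
  expect_true(finalActivation(-1e6) > 0)
  expect_true(finalActivation(-1e6) < 1e-10)
  expect_error(finalActivation(c(1, Inf)), "finite")
})

test_that("model building is deterministic and counts parameters correctly", {
  cfg <- tinyModelConfig()
  m1 <- buildModel(cfg, seed = 7L)
  m2 <- buildModel(cfg, seed = 7L)
  expect_identical(m1@weights, m2@weights)
  m3 <- buildModel(cfg, seed = 8L)
  expect_false(identical(m1@weights, m3@weights))
  # closed-form hand tally of the study architecture (base 32, depth 4,
  # 3 input channels, 8 hidden head channels): kernels 7,846,056 plus
  # 2,953 biases
  big <- buildModel(modelConfig(), seed = 1L)
  expect_identical(nParameters(big), 7846056 + 2953)
})

test_that("forward pass preserves shape and stays strictly inside (0,1)", {
  cfg <- modelConfig(inputChannels = 2L, baseChannels = 2L, depth = 4L,
                     finalHiddenChannels = 2L)
  m <- buildModel(cfg, seed = 3L)
  for (sz in c(16L, 32L, 64L, 128L)) {
    x <- array(runif(sz * sz * 2), c(sz, sz, 2))
    p <- mapValues(predictProb(m, x))
    expect_identical(dim(p), c(sz, sz))
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(predictProb(m, array(0, c(24, 24, 2))), "divisible")
  expect_error(predictProb(m, array(0, c(16, 16, 3))), "channel")
})

test_that("dropout-active inference is seeded and actually stochastic", {
  m <- buildModel(tinyModelConfig("drop"), seed = 5L)
  x <- array(runif(16 * 16), c(16, 16, 1))
  det1 <- mapValues(predictProb(m, x))
  det2 <- mapValues(predictProb(m, x))
  expect_identical(det1, det2)
  s1 <- mapValues(predictProb(m, x, dropoutActive = TRUE, seed = 21L))
  s1b <- mapValues(predictProb(m, x, dropoutActive = TRUE, seed = 21L))
  s2 <- mapValues(predictProb(m, x, dropoutActive = TRUE, seed = 22L))
  expect_identical(s1, s1b)
  expect_false(identical(s1, s2))
  expect_false(identical(s1, det1))
})

test_that("checkpoints round-trip through a single file", {
  m <- buildModel(tinyModelConfig("drop"), seed = 9L)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@weights, m@weights)
  expect_identical(modelVariant(m2), "drop")
  x <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(mapValues(predictProb(m, x)),
                   mapValues(predictProb(m2, x)))
})
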