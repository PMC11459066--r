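test_that("retention and percent removed follow the threshold exactly", {
  e <- matrix(c(0.05, 0.5, 0.95, 0.0), 2, 2)
  expect_true(all(retainedPixels(e, 1.0)))
  expect_identical(retainedPixels(e, 0.10), e <= 0.10)
  expect_true(all(retainedPixels(matrix(0, 3, 3), 0.01)))
  expect_error(retainedPixels(e, 0), "threshold")
  expect_equal(percentRemoved(e, 1.0), 0)
  expect_equal(percentRemoved(matrix(0.5, 4, 4), 0.10), 100)
  expect_equal(percentRemoved(matrix(c(0, 0.2, 0.6, 1), 2, 2), 0.5), 50)
  expect_error(percentRemoved(matrix(numeric(0), 0, 0), 0.5), "nonempty")
})

test_that("masked Dice matches hand arithmetic and documents conventions", {
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(maskedDice(g, g), 1)                    # prediction == grader
  disj <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(maskedDice(disj, g), 0)                 # disjoint, nonempty
  # 4-pixel printed case: P = {1,1,0,0}, G = {1,0,1,0} -> 2*1/(2+2)
  P <- matrix(c(1, 1, 0, 0), 2, 2); G <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(maskedDice(P, G), 0.5)
  # both empty on the retained pixels -> 1 by convention
  keep <- matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2)
  expect_equal(maskedDice(matrix(0, 2, 2), matrix(c(1, 0, 1, 0), 2, 2), keep), 1)
  # empty retention -> undefined
  expect_true(is.na(maskedDice(P, G, matrix(FALSE, 2, 2))))
  # agreement with the scalar loop oracle on random cases
  set.seed(5)
  for (rep in 1:20) {
    p <- matrix(runif(64), 8, 8)
    g <- matrix(rbinom(64, 1, 0.3), 8, 8)
    keep <- matrix(runif(64) < 0.8, 8, 8)
    expect_identical(maskedDice(p, g, keep), naiveMaskedDice(p, g, keep))
  }
})

test_that("threshold sweep reproduces a fully hand-computed fixture table", {
  fx <- sweepFixture()
  grid <- c(0.01, 0.10, 0.50, 1.00)
  sweep <- thresholdSweep(list(modelA = fx$probs), fx$samples, grid = grid,
                          nBoot = 200L, seed = 9L)
  rec <- sweep$records
  # oracle: recompute every record with scalar loops
  for (r in seq_len(nrow(rec))) {
    si <- match(rec$sample_id[r], c("F001", "F002"))
    p <- fx$probs[[si]]
    ent <- -(pmin(pmax(p, 1e-12), 1 - 1e-12) *
               log2(pmin(pmax(p, 1e-12), 1 - 1e-12)) +
             (1 - pmin(pmax(p, 1e-12), 1 - 1e-12)) *
               log2(1 - pmin(pmax(p, 1e-12), 1 - 1e-12)))
    keep <- ent <= rec$threshold[r]
    d1 <- naiveMaskedDice(p, fx$samples[[si]]@grader1, keep)
    d2 <- naiveMaskedDice(p, fx$samples[[si]]@grader2, keep)
    expect_identical(rec$dice_vs_grader1[r], d1)
    expect_identical(rec$dice_vs_grader2[r], d2)
    expect_identical(rec$dice_mean[r], (d1 + d2) / 2)
    expect_identical(rec$percent_removed[r], 100 * sum(ent > rec$threshold[r]) / 64)
  }
  # retained sets are nested: percent removed non-increasing in threshold
  for (sid in c("F001", "F002")) {
    pr <- rec$percent_removed[rec$sample_id == sid]
    expect_true(all(diff(pr) <= 0))
  }
  expect_equal(rec$percent_removed[abs(rec$threshold - 1) < 1e-12],
               c(0, 0))
  # aggregate means over defined records
  agg <- sweep$aggregate
  expect_identical(nrow(agg), length(grid))
  a10 <- agg[abs(agg$threshold - 0.10) < 1e-12, ]
  r10 <- rec[abs(rec$threshold - 0.10) < 1e-12, ]
  expect_equal(a10$dice_mean, mean(r10$dice_mean))
  expect_identical(a10$n_defined, 2L)
})

test_that("sweep aggregation counts undefined records instead of hiding them", {
  # a probability map with every pixel maximally uncertain retains nothing
  # at low thresholds
  s <- sweepFixture()$samples[[1]]
  flat <- matrix(0.5, 8, 8)
  sweep <- thresholdSweep(list(m = list(flat)), list(s),
                          grid = c(0.10, 1.00), nBoot = 100L, seed = 1L)
  expect_true(is.na(sweep$records$dice_mean[1]))
  expect_identical(sweep$aggregate$n_undefined, c(1L, 0L))
  expect_identical(sweep$aggregate$n_defined, c(0L, 1L))
  expect_true(is.na(sweep$aggregate$dice_mean[1]))
})

test_that("paired Wilcoxon matches exact-null enumeration and flags degeneracy", {
  # identical scores: no signal
  x <- seq(0.5, 0.9, length.out = 8)
  r0 <- wilcoxonPaired(x, x)
  expect_equal(r0$p, 1)
  expect_false(r0$significant)
  expect_identical(r0$note, "all differences zero")
  # uniform improvement: statistic is the sum of all positive ranks
  set.seed(6)
  b <- runif(20, 0.5, 0.8)
  r1 <- wilcoxonPaired(b + 0.1, b)
  expect_equal(r1$statistic, 20 * 21 / 2)
  expect_true(r1$p < 0.001)
  # exact p equals brute-force enumeration over sign patterns (n <= 10)
  for (rep in 1:5) {
    d <- round(runif(8, -0.2, 0.3), 7)
    d <- d[d != 0]
    d <- d + seq_along(d) * 1e-9   # break any |d| ties

    a2 <- runif(length(d)); b2 <- a2 - d
    expect_equal(wilcoxonPaired(a2, b2)$p, enumSignedRankP(d),
                 tolerance = 1e-12)
  }
  # Bonferroni: significance judged at alpha / nComparisons
  r2 <- wilcoxonPaired(b + 0.1, b, nComparisons = 1000000L)
  expect_false(r2$significant)
  expect_identical(r1$p, r2$p)
})

test_that("Pearson tradeoff correlation matches the closed formula", {
  agg <- data.frame(model_id = "m", threshold = seq(0.1, 0.5, 0.1),
                    dice_mean = c(1, 2, 3, 4, 5),
                    percent_removed = c(2, 4, 5, 4, 5))
  r <- pearsonTradeoff(agg, "m")
  expect_equal(r$rho, 0.7745966692, tolerance = 1e-9)
  # perfect affine relation
  agg2 <- data.frame(model_id = "m", dice_mean = 1:5,
                     percent_removed = 2 * (1:5) + 3)
  expect_equal(pearsonTradeoff(agg2, "m")$rho, 1)
  # zero variance is flagged, not fabricated
  agg3 <- data.frame(model_id = "m", dice_mean = rep(0.8, 5),
                     percent_removed = 1:5)
  r3 <- pearsonTradeoff(agg3, "m")
  expect_true(is.na(r3$rho))
  expect_identical(r3$note, "zero variance")
})
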