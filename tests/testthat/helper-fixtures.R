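# Small shared fixtures, built in code at test time.

tinyModelConfig <- function(variant = "standard")
  modelConfig(inputChannels = 1L, baseChannels = 2L, depth = 2L,
              finalHiddenChannels = 2L, variant = variant)

tinySynConfig <- function(seed = 11L, size = 32L)
  syntheticConfig(imageHeight = size, imageWidth = size,
                  nLesionsRange = c(1L, 2L), lesionRadiusRange = c(3, 7),
                  satelliteMaxArea = 30, seed = seed)

# Hand-built two-sample 8x8 fixture for the sweep oracle: structured
# probability maps plus grader masks that disagree on one border pixel.
# Entropies: H(0.005) ~ 0.045, H(0.01) = H(0.99) ~ 0.081 (retained at the
# 10% threshold), H(0.45/0.55) ~ 0.993 (removed everywhere below 100%);
# nothing survives the 1% threshold, exercising the undefined-Dice path.
sweepFixture <- function() {
  p1 <- matrix(0.005, 8, 8); p1[2:5, 2:5] <- 0.99; p1[5, 5] <- 0.55
  p2 <- matrix(0.01, 8, 8); p2[4:7, 3:6] <- 0.99; p2[4, 3] <- 0.45
  g1a <- matrix(0, 8, 8); g1a[2:5, 2:5] <- 1
  g1b <- g1a; g1b[5, 5] <- 0; g1b[6, 2] <- 1
  g2a <- matrix(0, 8, 8); g2a[4:7, 3:6] <- 1
  g2b <- g2a; g2b[4, 3] <- 0
  img <- function() array(0.5, c(8, 8, 1))
  s1 <- new("EnFaceSample", image = img(), truth = g1a, grader1 = g1a,
            grader2 = g1b, sampleId = "F001")
  s2 <- new("EnFaceSample", image = img(), truth = g2a, grader1 = g2a,
            grader2 = g2b, sampleId = "F002")
  list(samples = list(s1, s2), probs = list(p1, p2))
}
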