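# Seeded synthetic en face data: bright irregular lesion blobs on a noisy
# background, plus two simulated graders that agree in lesion cores and
# disagree at boundaries and on small satellites. Everything is a pure
# function of (config, seed).

#' Create a synthetic-data configuration
#'
#' Defaults emulate the qualitative structure of pseudo-color en face images
#' of geographic atrophy: one to three bright lesions (hypertransmission
#' brightening) with irregular borders on a darker noisy background, at a
#' desk-scale 128x128x3 raster. Image dimensions must be divisible by 16 so
#' the segmentation network's four 2x downsamplings are exact.
#'
#' @param imageHeight,imageWidth image size in pixels (divisible by 16).
#' @param nChannels number of channels (3 emulates pseudo-color).
#' @param nLesionsRange integer interval for the lesion count per image.
#' @param lesionRadiusRange pixel interval for the lesion semi-axes.
#' @param boundaryRoughness relative amplitude of the smooth radial boundary
#'   deformation; 0 gives exact ellipses, 0.3 gives visibly irregular blobs.
#' @param backgroundIntensity,lesionIntensity mean intensities in [0,1]
#'   outside/inside lesions; lesions must be brighter.
#' @param noiseSD additive Gaussian noise standard deviation.
#' @param graderBoundarySD standard deviation (pixels) of the smooth boundary
#'   displacement field used by the simulated graders.
#' @param graderSatelliteFlipProb probability that a grader deletes a small
#'   satellite component (per component) or adds a spurious one (per image).
#' @param satelliteMaxArea area (pixels) at or below which a component counts
#'   as a satellite.
#' @param seed base seed from which all per-sample and per-grader seeds are
#'   derived.
#' @return a [SyntheticConfig-class].
#' @examples
#' syntheticConfig(imageHeight = 64L, imageWidth = 64L)
#' @export
syntheticConfig <- function(imageHeight = 128L, imageWidth = 128L,
                            nChannels = 3L, nLesionsRange = c(1L, 3L),
                            lesionRadiusRange = c(8, 20),
                            boundaryRoughness = 0.3,
                            backgroundIntensity = 0.25, lesionIntensity = 0.75,
                            noiseSD = 0.08, graderBoundarySD = 1.5,
                            graderSatelliteFlipProb = 0.3,
                            satelliteMaxArea = 100, seed = 1L) {
  new("SyntheticConfig", imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth), nChannels = as.integer(nChannels),
      nLesionsRange = as.integer(nLesionsRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      boundaryRoughness = boundaryRoughness,
      backgroundIntensity = backgroundIntensity,
      lesionIntensity = lesionIntensity, noiseSD = noiseSD,
      graderBoundarySD = graderBoundarySD,
      graderSatelliteFlipProb = graderSatelliteFlipProb,
      satelliteMaxArea = satelliteMaxArea, seed = as.integer(seed))
}

# Uniform integer in [lo, hi] from the current RNG stream (sample() is
# avoided because sample(x, 1) misbehaves for scalar x).
runifInt <- function(lo, hi) as.integer(floor(runif(1) * (hi - lo + 1))) + lo

# Rasterize one deformed ellipse into a logical H x W matrix. The radial
# deformation is a low-order Fourier series normalized to max |f| = 1, so
# `roughness` directly bounds the relative boundary modulation.
rasterizeLesion <- function(H, W, cx, cy, a, b, theta, roughness) {
  K <- 2:6
  ak <- rnorm(length(K)) / K
  bk <- rnorm(length(K)) / K
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  row <- matrix(seq_len(H), H, W)
  dx <- col - cx
  dy <- row - cy
  u <- (cos(theta) * dx + sin(theta) * dy) / a
  v <- (-sin(theta) * dx + cos(theta) * dy) / b
  rr <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  f <- matrix(0, H, W)
  for (m in seq_along(K)) f <- f + ak[m] * cos(K[m] * phi) + bk[m] * sin(K[m] * phi)
  fbound <- max(sum(abs(ak)) + sum(abs(bk)), 1e-9)  # bound on max |f|
  rho <- pmax(1 + roughness * f / fbound, 0.25)
  rr <= rho
}

#' Generate a ground-truth lesion mask
#'
#' Draws a lesion count from `nLesionsRange`, places that many randomly
#' oriented ellipses with semi-axes in `lesionRadiusRange`, deforms each
#' boundary with a smooth random radial field scaled by `boundaryRoughness`,
#' and returns the union. Deterministic given `(config, sampleSeed)`.
#'
#' @param config a [SyntheticConfig-class].
#' @param sampleSeed integer seed for this mask.
#' @return a binary (0/1) matrix of size `imageHeight` x `imageWidth`.
#' @export
generateLesionMask <- function(config, sampleSeed) {
  validObject(config)
  H <- config@imageHeight; W <- config@imageWidth
  withSeed(sampleSeed, {
    n <- runifInt(config@nLesionsRange[1], config@nLesionsRange[2])
    mask <- matrix(0, H, W)
    for (i in seq_len(n)) {
      a <- runif(1, config@lesionRadiusRange[1], config@lesionRadiusRange[2])
      b <- runif(1, config@lesionRadiusRange[1], config@lesionRadiusRange[2])
      theta <- runif(1, 0, 2 * pi)
      m <- 0.8 * max(a, b)
      cx <- if (W - m > 1 + m) runif(1, 1 + m, W - m) else (W + 1) / 2
      cy <- if (H - m > 1 + m) runif(1, 1 + m, H - m) else (H + 1) / 2
      mask[rasterizeLesion(H, W, cx, cy, a, b, theta,
                           config@boundaryRoughness)] <- 1
    }
    mask
  })
}

#' Render a synthetic en face image from a lesion mask
#'
#' Each channel is `backgroundIntensity` outside and `lesionIntensity` inside
#' the lesions, plus independent Gaussian noise of standard deviation
#' `noiseSD`, clipped to [0,1]. Deterministic given `(config, sampleSeed)`.
#'
#' @param truth binary lesion mask matching the configured image size.
#' @param config a [SyntheticConfig-class].
#' @param sampleSeed integer seed for the noise.
#' @return an (H, W, C) numeric array in [0,1].
#' @export
renderEnface <- function(truth, config, sampleSeed) {
  H <- config@imageHeight; W <- config@imageWidth; C <- config@nChannels
  stopIf(!identical(dim(truth), c(H, W)), "mask dimensions do not match config")
  stopIf(!isBinary(truth), "truth must be binary")
  base <- config@backgroundIntensity +
    (config@lesionIntensity - config@backgroundIntensity) * truth
  withSeed(sampleSeed, {
    img <- array(rep(base, C), c(H, W, C))
    if (config@noiseSD > 0)
      img <- img + array(rnorm(H * W * C, 0, config@noiseSD), c(H, W, C))
    clip01(img)
  })
}

# Smooth random scalar field with (approximately) the target pointwise sd:
# a sum of K random low-frequency sinusoids, each with wavelength 16-48 px.
smoothField <- function(H, W, targetSD, K = 6L) {
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  row <- matrix(seq_len(H), H, W)
  f <- matrix(0, H, W)
  amp <- targetSD * sqrt(2 / K)
  for (k in seq_len(K)) {
    lambda <- runif(1, 16, 48)
    psi <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    f <- f + amp * sin(2 * pi * (col * cos(psi) + row * sin(psi)) / lambda + phase)
  }
  f
}

# Rasterize a plain disk (used for added satellite components).
diskMask <- function(H, W, cx, cy, r) {
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  row <- matrix(seq_len(H), H, W)
  (col - cx)^2 + (row - cy)^2 <= r^2
}

#' Simulate a grader's annotation of a ground-truth mask
#'
#' Applies two perturbations that mirror how human graders differ on en face
#' geographic atrophy: (a) the lesion boundary is warped by a smooth random
#' displacement field with per-axis standard deviation `graderBoundarySD`,
#' with the displacement norm clamped at twice that value so pixels at least
#' `2 * graderBoundarySD` inside a boundary are always preserved; and (b)
#' each connected component no larger than `satelliteMaxArea` pixels is
#' deleted with probability `graderSatelliteFlipProb`, and with the same
#' probability one small spurious satellite is added. Deterministic given
#' `(truth, config, graderSeed)`; with zero displacement and zero flip
#' probability the output equals the input.
#'
#' @param truth binary ground-truth mask.
#' @param config a [SyntheticConfig-class].
#' @param graderSeed integer seed for this grader.
#' @return a binary (0/1) matrix of the same size as `truth`.
#' @export
simulateGrader <- function(truth, config, graderSeed) {
  stopIf(!isBinary(truth), "truth must be binary")
  H <- nrow(truth); W <- ncol(truth)
  bsd <- config@graderBoundarySD
  p <- config@graderSatelliteFlipProb
  withSeed(graderSeed, {
    warped <- truth
    if (bsd > 0) {
      dx <- smoothField(H, W, bsd)
      dy <- smoothField(H, W, bsd)
      nrm <- sqrt(dx^2 + dy^2)
      sc <- pmin(1, (2 * bsd) / pmax(nrm, 1e-9))
      dx <- dx * sc; dy <- dy * sc
      col <- matrix(seq_len(W), H, W, byrow = TRUE)
      row <- matrix(seq_len(H), H, W)
      srcRow <- pmin(pmax(round(row + dy), 1), H)
      srcCol <- pmin(pmax(round(col + dx), 1), W)
      warped <- matrix(truth[cbind(as.vector(srcRow), as.vector(srcCol))], H, W)
    }
    if (p > 0) {
      lab <- EBImage::bwlabel(warped)
      nComp <- max(lab)
      if (nComp > 0) {
        areas <- tabulate(lab[lab > 0], nbins = nComp)
        for (k in seq_len(nComp)) {
          if (areas[k] <= config@satelliteMaxArea && runif(1) < p)
            warped[lab == k] <- 0
        }
      }
      if (runif(1) < p) {
        r <- runif(1, 2, 5)
        cx <- runif(1, 1 + r, W - r)
        cy <- runif(1, 1 + r, H - r)
        warped[diskMask(H, W, cx, cy, r)] <- 1
      }
    }
    warped
  })
}

# Role labels in the seed-derivation scheme.
.roleMask <- 1L; .roleImage <- 2L; .roleGrader1 <- 3L; .roleGrader2 <- 4L

#' Generate a seeded synthetic dataset
#'
#' Produces `nSamples` samples, each with an image, ground-truth mask and two
#' independent grader masks. Per-sample, per-role seeds are derived by
#' hashing `(config@seed, sample index, role)`, so the first `n` samples are
#' identical no matter how many more are generated.
#'
#' @param config a [SyntheticConfig-class].
#' @param nSamples number of samples (>= 1).
#' @return a list of [EnFaceSample-class] objects.
#' @examples
#' cfg <- syntheticConfig(imageHeight = 64L, imageWidth = 64L, seed = 7L)
#' ds <- generateDataset(cfg, 2)
#' ds[[1]]
#' @export
generateDataset <- function(config, nSamples) {
  validObject(config)
  stopIf(nSamples < 1, "nSamples must be >= 1")
  lapply(seq_len(nSamples), function(i) {
    truth <- generateLesionMask(config, seedHash(config@seed, i, .roleMask))
    img <- renderEnface(truth, config, seedHash(config@seed, i, .roleImage))
    g1 <- simulateGrader(truth, config, seedHash(config@seed, i, .roleGrader1))
    g2 <- simulateGrader(truth, config, seedHash(config@seed, i, .roleGrader2))
    new("EnFaceSample", image = img, truth = truth, grader1 = g1,
        grader2 = g2, sampleId = sprintf("S%03d", i))
  })
}
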