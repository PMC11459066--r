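# Raster and tabular I/O, configuration round-trips, and the red/blue
# certainty overlay. Images are stored on disk in the usual x/y (width,
# height) orientation; in memory the package uses (row = y, col = x), so
# reads and writes transpose.

#' Read and write en face images
#'
#' Images are (H, W, C) arrays in [0,1] in memory and 8-bit PNG rasters on
#' disk (quantization error at most 1/510 per pixel; float maps that must
#' round-trip exactly go through [writeFloatTIFF()] instead).
#'
#' @param image (H, W, C) array in [0,1].
#' @param path file path (`.png`).
#' @return `readEnfaceImage()` returns an (H, W, C) array;
#'   `writeEnfaceImage()` returns `path` invisibly.
#' @export
writeEnfaceImage <- function(image, path) {
  stopIf(length(dim(image)) != 3L, "image must be (H, W, C)")
  img <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @rdname writeEnfaceImage
#' @export
readEnfaceImage <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  aperm(a, c(2, 1, 3))
}

#' Read and write binary masks
#'
#' Masks are 0/1 matrices in memory and 0/255 8-bit PNG on disk.
#'
#' @param mask binary matrix.
#' @param path file path (`.png`).
#' @return `readMaskPNG()` returns a 0/1 matrix; `writeMaskPNG()` returns
#'   `path` invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  stopIf(!isBinary(mask), "mask must be binary")
  EBImage::writeImage(t(mask), path, bits = 8L)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(a)
  (m > 0.5) * 1
}

#' Write a float map as 32-bit TIFF (with optional PNG preview)
#'
#' Probability and entropy maps are stored losslessly as single-channel
#' 32-bit float TIFF; an 8-bit PNG preview can be written alongside.
#'
#' @param values numeric matrix in [0,1].
#' @param path file path (`.tif`/`.tiff`).
#' @param preview optional path of an 8-bit PNG preview.
#' @return `readFloatTIFF()` returns the matrix; the writer returns `path`
#'   invisibly.
#' @export
writeFloatTIFF <- function(values, path, preview = NULL) {
  tiff::writeTIFF(t(values), path, bits.per.sample = 32L, reduce = FALSE)
  if (!is.null(preview))
    EBImage::writeImage(t(clip01(values)), preview, bits = 8L)
  invisible(path)
}

#' @rdname writeFloatTIFF
#' @export
readFloatTIFF <- function(path) {
  t(tiff::readTIFF(path))
}

#' Render a red/blue certainty overlay
#'
#' Mirrors the study's visualization: saturated red where the model is
#' certain of lesion (probability 1, entropy 0), saturated blue where it is
#' certain of background, fading towards the neutral white midpoint as the
#' entropy rises; a pixel at probability 0.5 (entropy 1 bit) is pure white.
#' Deterministic in its inputs.
#'
#' @param image (H, W, C) array (currently unused except for shape checking,
#'   kept so callers can blend with the underlying anatomy).
#' @param prob [ProbabilityMap-class] or probability matrix.
#' @param entropy [EntropyMap-class] or entropy matrix in bits; computed
#'   from `prob` when missing.
#' @param blend weight in [0,1] mixing the grayscale image into the overlay
#'   (0 = pure colormap).
#' @return an (H, W, 3) RGB array in [0,1].
#' @export
renderOverlay <- function(image, prob, entropy = NULL, blend = 0) {
  p <- if (is(prob, "ProbabilityMap")) prob@values else prob
  if (is.null(entropy)) entropy <- binaryEntropy(p)
  e <- entropyValues(entropy)
  stopIf(!identical(dim(p), dim(e)), "probability/entropy shape mismatch")
  stopIf(!identical(dim(image)[1:2], dim(p)), "image shape mismatch")
  s <- 1 - e                      # saturation: certainty
  lesion <- p >= 0.5
  out <- array(1, c(dim(p), 3L))
  out[, , 1][!lesion] <- (1 - s)[!lesion]   # certain background: blue
  out[, , 2] <- 1 - s                       # green fades with certainty
  out[, , 3][lesion] <- (1 - s)[lesion]     # certain lesion: red
  if (blend > 0) {
    gray <- apply(image, c(1, 2), mean)
    for (c in 1:3) out[, , c] <- (1 - blend) * out[, , c] + blend * gray
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Each sample becomes one PNG image and three PNG masks
#' (truth, grader 1, grader 2); a manifest CSV maps sample ids to file
#' paths, and the generator configuration is stored as YAML.
#'
#' @param samples list of [EnFaceSample-class] objects.
#' @param dir output directory (created if needed).
#' @param config the [SyntheticConfig-class] that generated the samples.
#' @return the manifest data frame, invisibly.
#' @export
writeDataset <- function(samples, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    id <- sampleId(s)
    paths <- file.path(dir, paste0(id, c("_image.png", "_truth.png",
                                         "_grader1.png", "_grader2.png")))
    writeEnfaceImage(s@image, paths[1])
    writeMaskPNG(s@truth, paths[2])
    writeMaskPNG(s@grader1, paths[3])
    writeMaskPNG(s@grader2, paths[4])
    data.frame(sample_id = id, image = basename(paths[1]),
               truth = basename(paths[2]), grader1 = basename(paths[3]),
               grader2 = basename(paths[4]))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(config))
    writeConfigYAML(syntheticConfigToList(config),
                    file.path(dir, "config.yaml"))
  invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return a list of [EnFaceSample-class] objects.
#' @export
readDataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    new("EnFaceSample",
        image = readEnfaceImage(file.path(dir, manifest$image[i])),
        truth = readMaskPNG(file.path(dir, manifest$truth[i])),
        grader1 = readMaskPNG(file.path(dir, manifest$grader1[i])),
        grader2 = readMaskPNG(file.path(dir, manifest$grader2[i])),
        sampleId = manifest$sample_id[i])
  })
}

syntheticConfigToList <- function(config) {
  list(imageHeight = config@imageHeight, imageWidth = config@imageWidth,
       nChannels = config@nChannels,
       nLesionsRange = as.integer(config@nLesionsRange),
       lesionRadiusRange = as.numeric(config@lesionRadiusRange),
       boundaryRoughness = config@boundaryRoughness,
       backgroundIntensity = config@backgroundIntensity,
       lesionIntensity = config@lesionIntensity, noiseSD = config@noiseSD,
       graderBoundarySD = config@graderBoundarySD,
       graderSatelliteFlipProb = config@graderSatelliteFlipProb,
       satelliteMaxArea = config@satelliteMaxArea, seed = config@seed)
}

#' Configuration YAML round-trip
#'
#' @param config a named list (e.g. from `syntheticConfigToList()` or a
#'   pipeline run configuration).
#' @param path YAML file path.
#' @return `readConfigYAML()` returns the list; the writer returns `path`
#'   invisibly.
#' @export
writeConfigYAML <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) yaml::read_yaml(path)
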