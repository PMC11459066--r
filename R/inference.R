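# Approximate Bayesian inference: Monte Carlo dropout averaging, ensemble
# averaging, and Shannon-entropy uncertainty maps.

# Binary Shannon entropy in bits. Probabilities are clamped away from 0/1
# before the logs; exact 0 and 1 are assigned entropy 0 (the 0*log 0 = 0
# convention), so no non-finite intermediates can leak out.
binaryEntropy <- function(p) {
  q <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  h <- -(q * log2(q) + (1 - q) * log2(1 - q))
  h[p == 0 | p == 1] <- 0
  h
}

#' Pixel-wise Shannon entropy of a probability map
#'
#' For the binary lesion/background case the per-pixel entropy is
#' \deqn{H(p) = -[p \log_2 p + (1-p)\log_2(1-p)]}
#' in bits: 0 where the model is certain (p of 0 or 1) and maximal (1 bit)
#' at p = 0.5. Entropy is computed from the *averaged* predictive
#' probability — the final output of single, ensemble or Monte Carlo dropout
#' inference — not from per-run entropies. Thresholds elsewhere in the
#' package are fractions of the 1-bit maximum.
#'
#' @param x a [ProbabilityMap-class], or a numeric vector/matrix/array of
#'   probabilities in [0,1].
#' @param ... unused.
#' @return an [EntropyMap-class] for a [ProbabilityMap-class] input;
#'   otherwise a numeric object of the same shape.
#' @examples
#' entropyMap(c(0, 0.25, 0.5, 1))
#' @rdname entropyMap
#' @export
setMethod("entropyMap", "ProbabilityMap", function(x, ...) {
  new("EntropyMap", values = binaryEntropy(x@values),
      thresholdUnit = "fraction of 1 bit")
})

#' @rdname entropyMap
#' @export
setMethod("entropyMap", "ANY", function(x, ...) {
  stopIf(!is.numeric(x), "x must be numeric or a ProbabilityMap")
  stopIf(any(x < 0) || any(x > 1), "probabilities must lie in [0,1]")
  binaryEntropy(x)
})

#' Monte Carlo dropout prediction
#'
#' Runs `T` forward passes with all dropout layers active — each pass with a
#' deterministically derived seed — and averages the per-pixel
#' probabilities. This is the dropout analogue of posterior predictive
#' averaging; the study's UNet-Drop64 is `T = 64`. Increasing `T` shrinks the
#' Monte Carlo variance of the averaged map.
#'
#' @param model a drop-variant [SegModel-class].
#' @param image (H, W, C) array or [EnFaceSample-class].
#' @param T number of stochastic forward passes (>= 1).
#' @param seed base seed; run `t` uses a seed derived from `(seed, t)`, so
#'   the result is reproducible and run order is immaterial.
#' @return a [ProbabilityMap-class] with provenance `"mc_dropout"`.
#' @export
mcDropoutPredict <- function(model, image, T = 64L, seed = 1L) {
  stopIf(modelVariant(model) != "drop",
         "Monte Carlo dropout requires a drop-variant model")
  stopIf(T < 1, "T must be >= 1")
  if (is(image, "EnFaceSample")) image <- image@image
  acc <- NULL
  for (t in seq_len(T)) {
    out <- withSeed(seedHash(seed, t),
                    nnForward(model, image, stochastic = TRUE)$out)
    acc <- if (is.null(acc)) out else acc + out
  }
  new("ProbabilityMap", values = acc / T, provenance = "mc_dropout",
      nRuns = as.integer(T), sourceIds = paste0("run_", seq_len(T)))
}

#' Ensemble prediction
#'
#' Averages the deterministic (dropout-inactive) per-pixel probabilities of
#' several independently trained models — the study's UNet-Avg. With a
#' single model, or identical members, the result equals the single-model
#' output exactly.
#'
#' @param models nonempty list of [SegModel-class] objects with identical
#'   input specifications.
#' @param image (H, W, C) array or [EnFaceSample-class].
#' @return a [ProbabilityMap-class] with provenance `"ensemble"` (or
#'   `"single"` when only one model is given).
#' @export
ensemblePredict <- function(models, image) {
  stopIf(length(models) < 1, "at least one model is required")
  specs <- vapply(models, function(m)
    paste(m@config@inputChannels, m@config@depth), character(1))
  stopIf(length(unique(specs)) != 1,
         "ensemble members must share the input specification")
  if (is(image, "EnFaceSample")) image <- image@image
  acc <- NULL
  for (m in models) {
    out <- nnForward(m, image)$out
    acc <- if (is.null(acc)) out else acc + out
  }
  K <- length(models)
  ids <- if (!is.null(names(models))) names(models)
         else paste0("member_", seq_len(K))
  new("ProbabilityMap", values = acc / K,
      provenance = if (K == 1) "single" else "ensemble",
      nRuns = as.integer(K), sourceIds = ids)
}
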