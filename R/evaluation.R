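# Entropy-threshold sweep evaluation: masked Dice against two graders,
# percent of image removed, paired significance tests, and the
# Dice-vs-removal tradeoff correlation.

#' Entropy threshold grid
#'
#' The selective-prediction sweep uses thresholds expressed as fractions of
#' the 1-bit entropy maximum, starting just below 1% and increasing by 10%
#' up to 100%: 0.01, 0.10, 0.20, ..., 1.00 by default.
#'
#' @param start first threshold (default 0.01).
#' @param steps remaining thresholds (default `seq(0.1, 1, 0.1)`).
#' @return a strictly increasing numeric vector with values in (0,1].
#' @export
entropyThresholdGrid <- function(start = 0.01, steps = seq(0.1, 1, 0.1)) {
  g <- c(start, steps)
  stopIf(any(g <= 0) || any(g > 1), "thresholds must lie in (0,1]")
  stopIf(any(diff(g) <= 0), "thresholds must be strictly increasing")
  g
}

entropyValues <- function(entropy) {
  if (is(entropy, "EntropyMap")) entropy@values else entropy
}

#' Pixels retained at an entropy threshold
#'
#' A pixel is retained when its entropy is at or below
#' `threshold * (1 bit)`. Retained sets are nested: raising the threshold
#' never removes a retained pixel.
#'
#' @param entropy an [EntropyMap-class] or numeric matrix of entropies in
#'   bits.
#' @param threshold fraction of the 1-bit maximum, in (0,1].
#' @return a logical matrix.
#' @export
retainedPixels <- function(entropy, threshold) {
  stopIf(threshold <= 0 || threshold > 1, "threshold must lie in (0,1]")
  entropyValues(entropy) <= threshold
}

#' Percent of the image removed at an entropy threshold
#'
#' 100 times the fraction of pixels whose entropy exceeds the threshold —
#' the pixels excluded from the masked Dice evaluation.
#'
#' @inheritParams retainedPixels
#' @return a percentage in [0,100].
#' @export
percentRemoved <- function(entropy, threshold) {
  v <- entropyValues(entropy)
  stopIf(length(v) == 0, "entropy map must be nonempty")
  stopIf(threshold <= 0 || threshold > 1, "threshold must lie in (0,1]")
  100 * sum(v > threshold) / length(v)
}

#' Masked Dice score against a grader
#'
#' Binarizes the probability map at `cutoff`, restricts both the prediction
#' and the grader mask to the retained pixels, and computes
#' \eqn{2|P \cap G| / (|P| + |G|)}. When prediction and grader are both
#' empty on the retained pixels the score is 1 by convention; when no pixel
#' is retained the score is undefined and `NA` is returned (such records are
#' counted but excluded from aggregates).
#'
#' @param prob a [ProbabilityMap-class] or numeric probability matrix.
#' @param grader binary grader mask.
#' @param retained logical retention mask (default: all pixels).
#' @param cutoff binarization cutoff for the probabilities (default 0.5;
#'   pixels with probability >= cutoff count as lesion).
#' @return a Dice score in [0,1], or `NA` if nothing is retained.
#' @export
maskedDice <- function(prob, grader, retained = NULL, cutoff = 0.5) {
  p <- if (is(prob, "ProbabilityMap")) prob@values else prob
  stopIf(!identical(dim(p), dim(grader)), "shape mismatch")
  if (is.null(retained)) retained <- array(TRUE, dim(p))
  stopIf(!identical(dim(retained), dim(p)), "retention mask shape mismatch")
  if (!any(retained)) return(NA_real_)
  P <- (p >= cutoff)[retained]
  G <- (grader == 1)[retained]
  diceBinary(P, G, bothEmpty = 1)
}

# Seeded percentile bootstrap CI of the mean.
bootstrapCI <- function(x, nBoot = 2000L, seed = 1L, level = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(c(NA_real_, NA_real_))
  means <- withSeed(seed, vapply(seq_len(nBoot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1)))
  unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Entropy-threshold sweep
#'
#' For every model, sample and threshold: retain the pixels with entropy at
#' or below the threshold, compute Dice against each of the two graders on
#' the retained pixels, average the two scores, and record the percent of
#' the image removed. Aggregates average per-sample values over the samples
#' with a defined Dice and attach seeded percentile-bootstrap 95% confidence
#' intervals.
#'
#' @param probMaps named list over models; each element is a list of
#'   [ProbabilityMap-class] objects aligned with `samples`.
#' @param samples list of [EnFaceSample-class] objects carrying the two
#'   grader masks.
#' @param grid threshold grid from [entropyThresholdGrid()].
#' @param cutoff probability binarization cutoff.
#' @param nBoot,seed bootstrap replicates and seed for the aggregate
#'   confidence intervals.
#' @return `list(records, aggregate)`: per-(sample, model, threshold)
#'   records, and per-(model, threshold) aggregates with columns
#'   `dice_mean`, `dice_lo`, `dice_hi`, `percent_removed`, `n_defined`,
#'   `n_undefined`.
#' @export
thresholdSweep <- function(probMaps, samples, grid = entropyThresholdGrid(),
                           cutoff = 0.5, nBoot = 2000L, seed = 1L) {
  stopIf(!is.list(probMaps) || is.null(names(probMaps)),
         "probMaps must be a named list over models")
  ids <- vapply(samples, sampleId, character(1))
  rec <- list()
  for (modelId in names(probMaps)) {
    maps <- probMaps[[modelId]]
    stopIf(length(maps) != length(samples),
           "probability maps misaligned with samples for model ", modelId)
    for (si in seq_along(samples)) {
      pm <- maps[[si]]
      ent <- binaryEntropy(if (is(pm, "ProbabilityMap")) pm@values else pm)
      for (thr in grid) {
        keep <- retainedPixels(ent, thr)
        d1 <- maskedDice(pm, samples[[si]]@grader1, keep, cutoff)
        d2 <- maskedDice(pm, samples[[si]]@grader2, keep, cutoff)
        rec[[length(rec) + 1L]] <- data.frame(
          sample_id = ids[si], model_id = modelId, threshold = thr,
          dice_vs_grader1 = d1, dice_vs_grader2 = d2,
          dice_mean = (d1 + d2) / 2,
          percent_removed = percentRemoved(ent, thr))
      }
    }
  }
  records <- do.call(rbind, rec)
  aggregate <- aggregateSweep(records, nBoot = nBoot, seed = seed)
  list(records = records, aggregate = aggregate)
}

#' Aggregate sweep records over samples
#'
#' @param records the per-record table from [thresholdSweep()].
#' @param nBoot,seed bootstrap replicates and seed.
#' @return one row per (model, threshold) with sample means and bootstrap
#'   confidence intervals.
#' @export
aggregateSweep <- function(records, nBoot = 2000L, seed = 1L) {
  keys <- unique(records[c("model_id", "threshold")])
  keys <- keys[order(keys$model_id, keys$threshold), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$model_id == keys$model_id[i] &
                   records$threshold == keys$threshold[i], ]
    def <- !is.na(sub$dice_mean)
    ci <- bootstrapCI(sub$dice_mean[def], nBoot, seedHash(seed, i))
    data.frame(
      model_id = keys$model_id[i], threshold = keys$threshold[i],
      dice_mean = if (any(def)) mean(sub$dice_mean[def]) else NA_real_,
      dice_lo = ci[1], dice_hi = ci[2],
      percent_removed = mean(sub$percent_removed),
      n_defined = sum(def), n_undefined = sum(!def))
  })
  do.call(rbind, rows)
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-sided signed-rank test on per-sample paired Dice scores
#' (zero-difference pairs dropped, per the test's convention), with
#' significance judged at `alpha / nComparisons`. The exact null
#' distribution is used for 25 or fewer non-zero pairs without ties, the
#' normal approximation otherwise. The statistic is the sum of ranks of
#' positive differences.
#'
#' @param diceA,diceB equal-length per-sample score vectors, paired by
#'   sample.
#' @param nComparisons number of comparisons for the Bonferroni correction.
#' @param alpha family-wise significance level.
#' @return `list(statistic, p, significant, note)`; `note` flags degenerate
#'   inputs (all differences zero).
#' @export
wilcoxonPaired <- function(diceA, diceB, nComparisons = 1L, alpha = 0.05) {
  stopIf(length(diceA) != length(diceB), "inputs must be paired")
  stopIf(length(diceA) < 5, "need at least 5 pairs")
  d <- diceA - diceB
  if (all(d == 0))
    return(list(statistic = 0, p = 1, significant = FALSE,
                note = "all differences zero"))
  wt <- suppressWarnings(wilcox.test(diceA, diceB, paired = TRUE,
                                     exact = sum(d != 0) <= 25))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < alpha / nComparisons, note = NA_character_)
}

#' Dice versus percent-removed tradeoff correlation
#'
#' Pearson correlation between the aggregate Dice score and the aggregate
#' percent of image removed for one model, across the entropy threshold
#' grid (the reading of the study's tradeoff figure; set
#' `across = "samples"` with per-sample records at a fixed threshold for the
#' alternative).
#'
#' @param aggregate the aggregate table from [thresholdSweep()], or any data
#'   frame with `model_id`, `dice_mean` and `percent_removed`.
#' @param modelId which model to correlate.
#' @return `list(rho, p, note)`; zero variance in either vector yields `NA`
#'   with a note.
#' @export
pearsonTradeoff <- function(aggregate, modelId) {
  sub <- aggregate[aggregate$model_id == modelId & !is.na(aggregate$dice_mean), ]
  stopIf(nrow(sub) < 3, "need at least 3 thresholds with defined aggregates")
  if (sd(sub$dice_mean) == 0 || sd(sub$percent_removed) == 0)
    return(list(rho = NA_real_, p = NA_real_, note = "zero variance"))
  ct <- cor.test(sub$dice_mean, sub$percent_removed, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, note = NA_character_)
}
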