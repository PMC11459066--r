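---
title: "Uncertainty-aware segmentation of geographic atrophy: models and methods"
author: "uncertSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware segmentation of geographic atrophy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Geographic atrophy (GA) is the late atrophic stage of dry age-related
macular degeneration: photoreceptors, retinal pigment epithelium and
choriocapillaris are lost, and on sub-RPE en face slabs of swept-source OCT
volumes the atrophic regions appear as bright hypertransmission defects.
Deep segmentation networks delineate these lesions well on average, but a
conventionally trained network emits a hard per-pixel decision with no
notion of its own confidence — it is typically *overconfident*, including
where it is wrong, and lesion borders are exactly where human graders
disagree too.

`uncertSeg` implements a complete pipeline for quantifying the *epistemic*
(model) uncertainty of GA segmentation with two approximate Bayesian
techniques:

* **Monte Carlo dropout** — train a network with dropout layers, keep them
  active at inference, and average `T` stochastic forward passes;
* **deep ensembles** — train `K` networks from different seeded
  initializations on different cross-validation folds and average their
  outputs.

Both produce a per-pixel predictive probability whose binary Shannon
entropy serves as an uncertainty map, and both are compared against the
single-model baseline through a selective-prediction analysis: sweep an
entropy threshold, discard pixels above it, and score the retained pixels
against two graders.

Aleatoric (data) uncertainty — label noise, acquisition artifacts — is out
of scope; so are alternative backbones and 3-D volumes.

## The network

All models share one U-Net-style encoder/decoder (`modelConfig()`,
`buildModel()`):

* an encoder of `depth + 1` convolutional blocks — each two 3×3
  convolutions, each followed by a rectified linear unit — alternating with
  `depth` 2×2 stride-2 max-pools; channel width starts at `baseChannels`
  (32 in the study configuration) and doubles after each pool, so the
  default encoder runs 32, 64, 128, 256, 512;
* a decoder of `depth` steps: 2× bilinear upsampling, concatenation with
  the **remainder** of the matching encoder level, and a convolutional
  block;
* a head of one dropout layer (p = 0.2), a 3×3 convolution to 8 channels
  with rectified linear activation, and a 3×3 convolution to one channel
  through the bounded final activation.

The remainder skip (`remainderSkip()`) differs from the classical copy
skip: what is concatenated is

$$\mathrm{rem}(x) = x - \mathrm{upsample}(\mathrm{downsample}(x)),$$

with `downsample` the 2×2 max-pool and `upsample` 2× bilinear
interpolation — the high-frequency content that pooling discards, i.e.
exactly the information the decoder cannot recover from the coarser path.

The final activation is the algebraic sigmoid

$$\mathrm{final}(x) = \tfrac{1}{2}\!\left(\frac{x}{\sqrt{x^2+1}} + 1\right),$$

strictly increasing, symmetric (`final(-x) = 1 - final(x)`), and mapping
the reals onto the open interval (0, 1), so every output pixel is
interpretable as a lesion probability and is never exactly 0 or 1. Its
polynomial (rather than exponential) tails mean extreme confidence
requires very large pre-activations; in practice this keeps desk-scale
models modest in their certainty, which is the regime the entropy analysis
is about.

The **drop variant** adds dropout with p = 0.5 after the last three
encoder blocks and the first two decoder blocks. At inference these layers
(and the head dropout) stay active for Monte Carlo sampling; the standard
variant is deterministic at inference.

### Numerical conventions

Choices the architecture description leaves open, fixed once and pinned by
oracle tests:

* **Bilinear convention.** Half-pixel centers with edge clamping (the
  upsample of a 1×1 map is constant). Under this convention the remainder
  of any constant map is identically zero, which is the property that
  makes "remainder" meaningful.
* **Max-pool ties** break toward the first element in column-major order;
  gradient routing follows the stored argmax.
* **Concatenation order**: upsampled features first, remainder second.
  This only permutes learned channels.
* **Initialization**: He (Kaiming) uniform for kernels
  (bound $\sqrt{6/f}$, $f = 9c_{in}$), zero biases. The variant
  $1/\sqrt{f}$ was rejected: it shrinks activation variance roughly
  six-fold per convolution, and through the ~20 convolutions of this
  architecture leaves the output glued to 0.5 at desk scale. Ensembles
  need only *distinct* seeded initializations, which either scheme gives.
* **No normalization layers** anywhere: the architecture lists none.

## Training

`trainModel()` minimizes, per batch,

$$\mathcal{L} = \underbrace{1 - \frac{2\sum_i p_i t_i + \epsilon}
{\sum_i p_i + \sum_i t_i + \epsilon}}_{\text{Dice loss}}
\; + \; \lambda \sum_{\text{kernels } w} \frac{(\sum_j |w_j|)^2}{\sum_j w_j^2},$$

with Adam. Defaults follow the study: initial learning rate $10^{-4}$
multiplied by 0.999 at each epoch (the rate used during epoch $e$ is
$10^{-4} \cdot 0.999^{\,e}$), Hoyer-Square coefficient
$\lambda = 10^{-3}$. The Hoyer-Square term is a scale-invariant sparsity
measure, bounded between 1 and the kernel size; it is computed per
convolution kernel array and summed, biases excluded. The Dice smoothing
constant is $\epsilon = 1$ (configurable): it keeps loss and gradient
defined when an augmented crop contains no lesion. All-zero kernels are
assigned Hoyer-Square 0 by convention.

Augmentation (`augmentSample()`) applies one geometric transform —
horizontal/vertical flips, a 90° rotation for square rasters, an integer
translation of at most `maxShift` pixels with zero fill — identically to
the image and every mask, plus image-only photometric jitter
(multiplicative contrast on a log scale, additive brightness, clipped to
[0, 1]). Masks therefore stay strictly binary.

Cross-validation (`makeFolds()`, `trainEnsemble()`) is a seeded shuffle
with round-robin assignment; member *j* trains on all folds but *j* from a
distinct derived seed. Member 1 doubles as the single-model baseline, as
in the study. Model selection uses the last epoch (logged per epoch:
learning rate, Dice loss, Hoyer-Square value, their exact sum, validation
Dice); no early stopping.

### Desk-scale schedule

The study trained for 5000 epochs on 8 GPUs. This package's `"desk"`
preset (`pipelinePreset()`) exercises the identical pipeline on one CPU:
64×64×3 images, base width 8, a 3-member ensemble, 30 epochs of
single-image batches, 16 Monte Carlo runs. Two presets differ in one
optimizer setting: the desk schedule uses an initial learning rate of
$3 \times 10^{-4}$. The study's $10^{-4}$ is tied to its 5000-epoch run;
over the ~1000 Adam steps of the desk schedule it cannot move
He-initialized weights appreciably, while rates at $10^{-3}$ and above
drive small-lesion Dice training into the well-known all-background
attractor. $3 \times 10^{-4}$ sits between those regimes; it is a
schedule-matching choice, not a tuning target, and the `"paper"` preset
records the study's own values.

## Bayesian inference and entropy

`mcDropoutPredict()` averages `T` dropout-active forward passes, each with
a deterministically derived seed (so the result is reproducible and
independent of run order); `ensemblePredict()` averages the deterministic
outputs of the ensemble members. Uncertainty is the binary Shannon entropy
of the *averaged* predictive probability,

$$H(p) = -\left[p \log_2 p + (1-p)\log_2(1-p)\right] \in [0, 1]\ \text{bits},$$

not the average of per-run entropies: the entropy is a property of the
final predictive distribution. Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ before the logarithms; exact 0 and 1 take the
$0 \log 0 = 0$ convention. Entropy thresholds are expressed as fractions
of the 1-bit maximum throughout.

Averaging more Monte Carlo runs shrinks the run-to-run variance of the
averaged map (`mcDropoutVariance()` measures this directly), which is the
mechanism behind the study's improvement from 4-run to 64-run averaging.

## Evaluation

For each model, sample and threshold `thresholdSweep()` computes:

* the **retained set**: pixels with entropy at or below the threshold
  (nested as the threshold grows);
* **percent removed**: 100 × the complementary fraction — monotone
  non-increasing in the threshold, 0 at threshold 1;
* **masked Dice**: probabilities binarized at 0.5 (configurable), Dice
  $2|P\cap G|/(|P|+|G|)$ against each of two graders on the retained
  pixels, then the mean of the two scores — per-sample first, averaged
  over graders, then over samples. Pooling pixels across samples before
  scoring was considered and rejected: it would let large lesions dominate
  and break pairing with the significance tests.

Degenerate cases are conventions, surfaced rather than hidden: if
prediction and grader are both empty on the retained set the Dice is 1; if
nothing is retained the record is undefined (`NA`), excluded from
aggregates and counted in `n_undefined`. Aggregates carry seeded
percentile-bootstrap 95% confidence intervals (2000 resamples; the study
reports intervals without naming a method).

The default threshold grid starts just below 1% (0.01) and steps by 10% up
to 100%. Significance between paired per-sample Dice vectors uses the
two-sided Wilcoxon signed-rank test (zero differences dropped; exact null
up to 25 non-zero pairs without ties, normal approximation otherwise) with
Bonferroni correction, via `stats::wilcox.test`; an independent exact-null
enumeration over all sign patterns cross-checks it in the test suite. The
Dice-versus-percent-removed correlation (`pearsonTradeoff()`) is a Pearson
correlation across the threshold grid — the reading of the study's
tradeoff figure; correlating across images at a fixed threshold is left as
an option since the study does not state which was used.

## The synthetic generator

The study's clinical SS-OCT dataset is private, so `generateDataset()`
produces a stand-in with the statistical structure the analysis needs:

* **lesions**: a random count of randomly oriented ellipses with semi-axes
  in `lesionRadiusRange`, each boundary deformed by a smooth low-order
  Fourier radial field whose relative amplitude is `boundaryRoughness` —
  bright, irregular, possibly merging blobs;
* **images**: lesion interior at `lesionIntensity`, background at
  `backgroundIntensity` (lesions brighter, emulating hypertransmission),
  plus independent Gaussian noise per channel, clipped to [0, 1];
* **graders**: each grader warps the true boundary with a smooth random
  displacement field (per-axis standard deviation `graderBoundarySD`, norm
  clamped at twice that, so lesion cores more than `2·graderBoundarySD`
  inside the boundary are always preserved) and flips small satellite
  components — deleting each with probability `graderSatelliteFlipProb`
  and adding a spurious one with the same probability. The two graders use
  independent seeds: they agree on cores and disagree at borders and on
  satellites, the qualitative pattern described for the clinical graders.

Everything is a pure function of `(config, seed)`; per-sample and per-role
seeds are derived by hashing `(seed, index, role)`, so extending a dataset
never changes existing samples. Defaults (128×128×3; 1–3 lesions of radius
8–20 px; roughness 0.3; intensities 0.25/0.75; noise 0.08; grader
displacement 1.5 px; flip probability 0.3) were chosen once for visual
plausibility; the study reports no quantitative inter-grader statistic to
calibrate against. The desk preset scales geometry down with the raster
(1–2 lesions of radius 5–12 px at 64×64).

What the generator does **not** emulate: SS-OCT physics, slab extraction,
pseudo-color channel semantics (channels here share one intensity
profile), real GA morphology statistics, or spatially correlated grader
biases. Consequently, passing the package's end-to-end checks shows that
the *pipeline mechanics* — training, Bayesian averaging, entropy
filtering, the Dice-versus-removal tradeoff — behave as described on data
with the assumed structure; it does not certify clinical performance on
OCT images.

## Reproducibility

Every source of randomness — generator, initialization, shuffling,
augmentation, dropout, bootstrap — derives from explicit seeds, and
`runPipeline()` re-run with the same seed reproduces its metric CSVs byte
for byte. The scaled experiment behind `scripts/acceptance.R` (40
cross-validation samples and 10 test samples at 64×64, the desk schedule
above) finishes in minutes on one CPU; the problem sizes are stated here
as the package's desk-scale choice.

## Known limitations

* The desk-scale network is far from the study's training regime; its
  absolute Dice values and removal percentages are not comparable to the
  clinical numbers, only the orderings and mechanisms are.
* The Hoyer-Square term is summed over kernels of very different sizes, so
  large decoder kernels dominate the penalty; whether the study normalized
  per layer is unstated.
* The Wilcoxon normal approximation (used above 25 pairs) applies the
  standard tie correction but no continuity-corrected exact fallback with
  ties.
* Single-image batches make the training loss trace noisier than the
  study's batched equivalent; the logged per-epoch loss is the mean over
  the epoch's batches.
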