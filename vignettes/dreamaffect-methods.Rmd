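---
title: "Methods: synthesis, image properties, and the rating-study simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesis, image properties, and the rating-study simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamaffect)
```

## Overview

`dreamaffect` implements the computational chain of a visual-psychophysics
paradigm in which abstract, semantics-free stimuli are synthesized by
*activation maximization* ("deep dreaming") of individual layers of a
convolutional network, and human affective reactions to those stimuli —
self-reported arousal and valence on 0–100 sliders — are analyzed at the
layer level. The package covers five stages: stimulus synthesis, global
image properties, a simulator of the acquisition protocol, the statistical
analyses, and a pipeline orchestrator.

## Stimulus synthesis

The synthesis loop maximizes the summed activations of one named layer of a
differentiable image model. Starting from a uniform gray 800 × 800 base
image (gray level 128) with added i.i.d. Gaussian noise (mean 0, SD 12.75
intensity units, drawn from a fixed seed), each iteration

1. computes the gradient `g` of the summed target activations with respect
   to the pixels,
2. updates the image by `step_size * g / mean(|g|)` with a fixed step size
   of 2 intensity units, and
3. clips to [0, 255] and rounds to integers (halves away from zero).

Iteration stops when the quantized image is identical on two consecutive
passes — a true fixed point of the integer dynamics — or at a cap of 1000
iterations (reported as unconverged with a warning rather than an error).
The full design synthesizes five images (seeds 0–4) for each of the 144
layer names in the packaged Inception-style inventory, i.e. 720 stimuli.

Design choices that the protocol leaves open, fixed here as follows:

* **Gradient normalization.** Raw gradient magnitudes vary by orders of
  magnitude across layers, so the gradient is divided by its mean absolute
  value (plus `1e-8`) before scaling. This is standard deep-dream practice
  and keeps the step size meaningful in pixel-intensity units; a zero
  gradient leaves the image unchanged.
* **Base gray 128 and half-away-from-zero rounding**, making quantization
  bit-reproducible across platforms (base R's `round()` is half-to-even).
* **No octaves, jitter, or smoothness regularization** — the loop is the
  plain single-scale procedure.
* **Model-agnostic engine.** The model is supplied through a
  `model_adapter` contract (ordered layer names, activations, gradient of
  their sum). The packaged `tiny_cnn_adapter()` is a seeded two-block CNN
  with hand-implemented forward/backward passes so tests need no
  pretrained download; `pixel_sum_adapter()` gives a closed-form saturation
  oracle (every pixel climbs one step per iteration until clipped at 255).
* **Layer inventory.** The packaged 144-name list follows GoogLeNet-style
  naming (stem `conv2d0` … `maxpool1`, nine `mixed*` inception modules
  with their sub-layers, head nodes). It is a replication-style inventory
  constructed to the published naming pattern, not a verbatim copy of any
  particular pretrained graph.

## The six image properties

For every stimulus the package computes:

* **Mean hue, saturation, brightness** in the 8-bit HSV dialect
  (H in [0, 180) half-degrees, S and V in [0, 255]), means rounded to three
  decimals at the reporting boundary. The dialect matters: hue means are
  convention-dependent, so it is part of the feature definition. Hue is
  averaged arithmetically; a circular mean would be the alternative near
  the wrap-around.
* **JPEG compression percentage**: encoded byte count at quality 80 as a
  percentage of the idealized raw size `H × W × 3` bytes (1,920,000 bytes
  at 800 × 800). Byte counts differ slightly across encoders, so tests
  assert ordering and integrality properties rather than exact bytes.
* **Feature Congestion** and **Sub-band Entropy**, two visual-clutter
  measures implemented in the package from their published constructions
  (no R implementation exists). Both work on CIELab channels and a 3-level
  Gaussian pyramid with separable filters and edge-replicating padding, so
  a constant image scores exactly zero. Feature Congestion combines, per
  pixel and scale, the local chroma covariance volume, a
  difference-of-Gaussians luminance-contrast energy, and the spread of
  oriented energy over four steered second-derivative orientations, pooled
  by means (Minkowski order 1). The default weights (contrast upweighted
  3:1) bring the three feature maps to comparable magnitudes on 8-bit
  imagery and are configurable.

Sub-band Entropy sums, over 3 scales × 4 orientations × 3 channels, the
Shannon entropy of each band's coefficient histogram (luminance weight 1,
chrominance weight 0.0625). Binning uses **8 equal-width bins spanning each
band's own coefficient range**. An earlier design used quantile-based bins;
that choice is degenerate — quantile bins equalize probabilities by
construction, so every continuous band scores exactly 3 bits and the
measure cannot vary across stimuli. Range-anchored equal-width bins keep
the intended invariance to affine rescaling of coefficients while letting
the histogram *shape* (peaked vs. spread) drive the value. Points landing
exactly on an interior bin edge are split half/half between the adjacent
bins, which makes the statistic exactly mirror-symmetric; both clutter
measures are invariant to horizontal flips (asserted to 1e-6).

On sparse-structured imagery both measures rise, on average, with added
noise amplitude; the property suite verifies this on an edge-structured
base image across 20 noise seeds at SDs 5/20/50. Note that on *pure-noise*
images Sub-band Entropy is flat by design (its bins scale with the
coefficients), which is why the monotonicity check uses a structured base.

## The rating-study simulator

The human-response dataset behind the original analyses is license-gated,
so the package ships a simulator that reproduces the acquisition protocol's
statistical shape, making every downstream stage testable:

* a roster of 153 recruited participants, 3 of whom do not complete the
  study (so 150 analyzable), with demographics drawn to match the reported
  sample (about 65% female, age mean 26.16, SD 9.137, truncated at 18) and
  attitude (3 levels) / self-esteem (5 levels) covariates sampled
  independently of the ratings — matching the null ANOVA findings the
  protocol reported; an effect hook exists for power studies;
* the 144 layers split into three equal groups (contiguous blocks by
  default — the original split is unstated — with a random-partition
  option), one group per participant, one of the five images per layer
  drawn uniformly, presentation order a uniform permutation: 48 ratings
  per complete participant;
* ratings generated as `intercept + X beta + participant intercept +
  Gaussian noise`, clipped to [0, 100] (slider semantics; the clipped
  fraction is logged and stays below 1% under default calibration).
  Participant heterogeneity is a Gaussian random intercept only — the
  analysis model has no participant × feature slopes. Named layers can
  override the linear rule with a two-component Gaussian mixture in the
  arousal–valence plane to emulate polarized responses.

The key calibration device is `rsq_to_noise_sd()`: given coefficients, a
feature table and a target population R², it returns the closed-form
residual SD `sqrt(Var(X beta) (1 − R²) / R²)`. This lets simulations target
the reported population R² values exactly, and parameter-recovery tests
confirm that the six-predictor OLS stage recovers them: the mean adjusted
R² over ≥ 500 replicates at n = 144 sits within ±0.02 of the calibrated
value for both the arousal-model (0.370) and valence-model (0.033)
settings. The Gaussian slider model is a stated assumption, not a claim
about real response distributions, which are bounded and possibly bimodal;
passing tests demonstrate correctness of the analysis chain, not fidelity
of real human data.

## Statistical analyses

All analyses operate at the **layer level** (144 cases): regressions and
correlations relate per-layer mean ratings to per-layer mean features,
consistent with an error degrees-of-freedom of 137 for six predictors.
Specifics:

* `ols_fit()` wraps ordinary least squares with classical inference; the
  algebraic identities `F = (R²/k)/((1−R²)/(n−k−1))` and (for two groups)
  `F = t²` are asserted exactly in the test suite, and coefficients match
  a normal-equations oracle to 1e-10.
* `one_way_anova()` gives the standard between/within decomposition; a
  zero between-group sum of squares (all-identical data) reports F = 0.
* `neutrality_test()` uses one-sample Wilcoxon signed-rank tests against
  the midpoint 50 — rank tests are preferred because slider outputs are
  bounded and non-normal; the underlying test in the original analysis is
  unstated. Raw and Benjamini–Hochberg-adjusted p values are both
  reported; the original is silent on multiplicity.
* `group_compare()` pools ratings into layer families selected by name
  patterns (e.g. `mixed*_pool` vs. `mixed*_{3,5}x{3,5}_pre_relu`) and runs
  two-sample Mann–Whitney tests.
* `joint_density()` builds a 101 × 101 histogram over [0, 100]², smooths
  with a Gaussian kernel of SD 4 rating units (smoothing was reported
  without a bandwidth; 4 units is a visually reasonable default, and the
  raw histogram is recovered as the bandwidth goes to 0), renormalizes to
  sum 1, and `density_entropy()` scores it in bits. Entropy is computed on
  the normalized smoothed grid, not on plot pixel intensities.
* `rank_layers_by_entropy()` returns the minimum-entropy layer (most
  repeatable response), maximum-entropy layer (most diverse), and a
  balanced case minimizing the mean of min-max-normalized entropy and
  min-max-normalized distance of the mean point from (50, 50) — min-max
  normalization is the package's choice, as no scale for combining the two
  criteria is given. Ties break by inventory order.
* `nearest_to_anchors()` matches layers to the four corners and four edge
  midpoints of the affect plane by the per-layer **median** point
  (means are also available via `stat = "mean"`); the original figures mark
  both statistics.

Bimodal joint distributions are *emulated* by the simulator but not
auto-detected; identifying them remains a qualitative judgment.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant columns in correlation
tables warn and return NA; rank-deficient regression designs error naming
the collinear columns; layers with all ratings at the midpoint report
p = 1; zero bandwidth recovers the raw histogram; maxpool gradient ties
route to the first maximum in a fixed scan order.

The test suite exercises synthesis on 8–16 px fixture images with the
seeded CNN, clutter properties on 32 px images over 20 noise seeds,
regression recovery at the full layer-level size (n = 144, 500+
replicates), the neutrality type-I error over 1000 replicates, and the
end-to-end pipeline at fixture scale (6 layers × 2 seeds, 24 simulated
participants). These sizes keep the whole suite under a minute while every
statistical check runs at the design's true n where it matters (n = 144
cases for regression, 153/150 for the protocol counts).

## Known limitations

* The clutter measures follow the published constructions but are not
  bit-compatible with the original Matlab library (whose exact version and
  parameters are unstated); comparisons should rely on orderings, not raw
  values.
* Hue averaging is arithmetic in the 8-bit dialect; distributions
  straddling the circular wrap are summarized conservatively.
* The simulator makes no attempt to model presentation-order or fatigue
  effects, and its Gaussian slider noise is an assumption.
* `tiny_cnn_adapter()` is a fixture: synthesis on it demonstrates the
  engine's contracts (determinism, fixed points, ascent), not the visual
  character of stimuli from a pretrained Inception graph, whose weights
  are not distributed with the package.
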