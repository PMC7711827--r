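---
title: "scintnet: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scintnet: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what is being
modeled, which conventions the numbers follow, and where the design was
genuinely open and a choice had to be made.

## 1. The classification problem

Whole-body bone scintigrams of prostate-cancer patients fall into three
classes: *normal*, *malignant* (focal metastatic uptake, solitary or
multiple), and *degenerative* (benign joint and spine uptake that mimics
metastases).  The reference clinical dataset behind this problem — 778
planar views of 1024 x 256 px, 328 malignant / 271 degenerative / 179
normal — is private.  Everything in this package is therefore exercised on
a synthetic phantom that emulates that composition, and the package's
accuracy claims are about the *pipeline* (learnability, metric
correctness, absence of evaluation leakage), never about clinical
performance.

## 2. The phantom generator

`generate_body_template()` draws a schematic body silhouette (head, torso,
arms, pelvis, legs, feet as half-plane/ellipse unions in fractions of the
image box) with baseline relative uptake 1 inside and 0 outside, then
multiplies in fixed anatomical elevations: a spine band (x1.5), pelvic
band (x1.3), skull (x1.25), and Gaussian patches at shoulders, knees,
wrists, ankles, kidneys and bladder (x1.2-1.6).  The anchor coordinate
table (`scint_anchors()`) is a versioned constant; all paired structures
satisfy `col_right = 1 - col_left` exactly, so bilateral symmetry is a
testable invariant.  Posterior views strengthen the renal signature, the
only anterior/posterior asymmetry modeled.

Class-specific uptake is multiplicative, isotropic-Gaussian per lesion
(`u <- u * (1 + (m - 1) * exp(-d^2 / 2sigma^2))`), the simplest compact
hot-spot model:

* **malignant** — `N ~ Poisson(lesion_rate = 5)` truncated to `N >= 1`
  (a malignant image must contain a lesion; the truncated mean
  `lambda / (1 - e^-lambda) = 5.034` is a closed-form test oracle), placed
  at jittered axial-skeleton anchors, multipliers `m ~ U(2.5, 6.0)`,
  radius `U(0.8, 2)%` of the image height (8-20 px at full geometry);
* **degenerative** — 1-4 joint pairs with the *same* multiplier
  `m ~ U(1.5, deg_max)` on both mirrored sides plus an optional spine
  segment (probability 0.5);
* **artifacts** — with probability 0.3 one injection-site (forearm,
  `m ~ U(4, 8)`) or bladder (`m ~ U(3, 5)`) blob, recorded with kind
  `artifact` and never changing the label, in any class.

`difficulty` controls the overlap of the two multiplier ranges: `easy`
caps the degenerative interval 0.5 below the metastatic minimum
(`[1.5, 2.0]` vs `[2.5, 6.0]`, disjoint by construction); `hard` extends
it 0.7 past the metastatic minimum so the classes genuinely overlap.

Counting noise is Poisson per pixel with mean `noise_scale x uptake`
(`noise_scale = 40` counts at baseline — a realistic planar-acquisition
count density, giving ~16% relative noise at baseline and the
mean-equals-variance property the tests check).  `noise_scale = 0` is the
documented zero-noise limit.  Images are written as 16-bit grayscale PNG
precisely so these count statistics survive the round trip; the package
carries its own fixed-settings PNG16 codec, making outputs byte-identical
under a fixed seed.

What the phantom does **not** emulate: attenuation, scatter, collimator
blur, patient habitus variation, osteoarthritic pattern diversity, or the
curation artifacts of a real archive.  A green test on the phantom
establishes that the pipeline can learn and measure; it does not establish
clinical accuracy, and the published clinical accuracies (e.g. 97.41%
overall) are out of reach by construction.

A deliberately trivial rule-based detector (`hotspot_rule_classifier`:
3x3-smoothed counts divided by the expected normal pattern, one high
threshold over the axial region, one bilateral joint score) achieves over
90% on easy-mode datasets at 512 x 128 px or larger.  Its role is to prove
the classes separable *before* any network is involved; at very coarse
geometries (e.g. 256 x 64) its fixed thresholds are defeated by
blob-size-dependent smoothing attenuation, which is expected and
documented rather than patched.

## 3. Preprocessing conventions

* Grayscale: ITU-R BT.601 weights (0.299, 0.587, 0.114).
* Resize: longer side to `target_size`, bilinear
  (align-corners-false), shorter side scaled by the same factor, centered
  zero padding with the odd pixel on the trailing side.  1024 x 256 at
  target 224 gives a 224 x 56 content region with 84-column pads — an
  exact arithmetic test.
* Normalization: division by the bit-depth maximum (65535), **not** the
  per-image maximum: absolute count levels carry diagnostic information
  (hot spots are defined relative to a shared scale), and the first batch
  normalization makes the network indifferent to the resulting small
  absolute magnitudes.
* Augmentation: rotation `U(-10, +10)` degrees and zoom `U(0.9, 1.1)` by
  default ("minimal" augmentation is unquantified in the protocol this
  follows; 10 degrees is a conventional choice), applied online per image
  per epoch inside each training split only — never before fold
  assignment, which would leak.

## 4. The LB-FCN light architecture and its frozen default

The architecture family is constrained to: exactly four multi-scale
blocks; exactly three look-behind residual connections (the first block
has none — the look-behind pattern links consecutive blocks, and 4 blocks
support exactly 3 such links); depthwise separable convolutions
throughout; no hidden dense layers (global average pooling into a 3-unit
softmax, the only non-convolutional trainable layer).

The published description stops there; per-block filter counts, kernels
and dilations are not public.  The default configuration is therefore this
package's own construction under two hard constraints: (a) the structural
constraints above, and (b) a total trainable parameter count in
[300,000, 322,886] — the window that floor-truncates to 0.3 x 10^6 while
staying at least 10x below MobileNet's 3,228,864.  The frozen choice is
three branches per block (3x3 dilation 1, 3x3 dilation 2, 5x5 dilation 1
— two receptive-field scales at equal cost plus a dilated variant) with
16/40/88/130 filters per branch, batch normalization after every
separable convolution (convolutions carry no biases; BN supplies the 2
per-channel affine terms, all counted), pointwise projection + BN on each
residual path, and 2x2 max pooling after each block.  Total: **304,014**
trainable parameters, independent of input spatial size (fully
convolutional — an invariant the tests assert at 224 vs 112 px).

Parameter accounting is dual-routed: the spec-level sum over the layer
table must equal the training engine's allocated weight-vector length
exactly; `instantiate_model()` refuses to run otherwise.

## 5. The numeric engine

No deep-learning framework is assumed.  The engine (Rcpp/Armadillo) lays
activations out as `(N*H*W) x C` matrices so pointwise convolutions and
residual projections are single GEMMs, depthwise kernels are direct
per-channel loops, and batch-norm reductions stream contiguous columns.
Training is single-precision; the identical templated code path compiles
in double precision for the finite-difference gradient tests (central
differences at h = 1e-5 agree with backprop to ~1e-9 relative error on a
tiny network).  Optimization is Adam (lr 0.001, beta1 0.9, beta2 0.999,
batch 32 — the reference protocol's settings), with per-epoch reshuffling
and per-image augmentation drawn from one seeded Mersenne Twister stream:
identical seed, data and config reproduce the loss trace bit for bit on
this platform.

One engine-specific choice deserves note: after optimization the batch
-norm running statistics are **re-estimated in a calibration pass over the
clean (un-augmented) training images**.  With eight stacked BN layers,
statistics tracked under the augmentation distribution are systematically
off for clean inputs, and the mismatch compounds enough to visibly distort
inference.  The calibration shuffles its batches deterministically
(training splits arrive grouped by class, and single-class batches would
under-estimate every channel's variance by the between-class component)
and aggregates exact total moments, `E[batch var] + Var[batch mean]`, over
two passes.

Numerical conventions: BN epsilon 1e-3, biased batch variance, momentum
0.9 during training; softmax via max-shifted exponentials; cross-entropy
clipped at 1e-12; argmax prediction ties break toward the lowest class
index (normal < malignant < degenerative).

## 6. Complexity accounting conventions

Three conventions were fixed by reconciling them against the published
comparison table, and all are documented in `?flops_estimate`,
`?baseline_param_count` and the decisions they encode:

* **FLOPs = 2 x trainable parameters** (one multiply + one add per
  parameter).  Unusual, but it is the only rule consistent with the
  published rows (47.0/23.5, 6.4/3.2, 268.5/134.2, 0.6/0.3); it is not a
  spatial multiply-accumulate count.  The *rendered* FLOPs column derives
  from the truncated parameter figure (23.5 -> 47.0); the exact integer
  estimate remains 2 x parameters.  One published cell (InceptionV3,
  43.5) is consistent with neither ordering and is noted as an
  inconsistency rather than matched.
* **Headless totals for pretrained baselines**: parameter counts are the
  standard architectures without classifier tops, *including* batch-norm
  moving statistics (the "total params" of the headless model).  This is
  the only convention that reproduces all four pretrained rows
  simultaneously under floor-truncation (InceptionV3's trainable-only
  count truncates to 21.7, not the published 21.8).
* **Floor-truncation to one decimal in millions**: rounding would break
  ResNet50 (23.59 -> 23.6) and Xception (20.86 -> 20.9).

Two baselines are best-effort: VGG16 ships with the two-4096 dense head
and a 3-class output (134,272,835 -> 134.2, matching the table even though
the accompanying text says "dense nodes 512 x 512"), and the custom
reference CNN rebuilt literally from its stated configuration gives
~2.66 M parameters, not the published 6.5 M — no configuration consistent
with that description reproduces 6.5 M, so this row is reported but
excluded from the minimum lightness ratio, which is taken over the five
reproducible baselines (binding: MobileNet, ratio 10.62).

## 7. Evaluation protocol

`stratified_kfold()` shuffles within class (seeded) and deals round-robin:
per-class fold counts differ by at most one, so the 328/271/179 mix yields
32-33 / 27-28 / 17-18 records per fold — an exact arithmetic test.
Metrics are one-vs-rest per class; recall and sensitivity are the same
formula and are reported as such; zero denominators return 0 with a
warning (small-fold edge cases) rather than NaN.  Cross-validation reports
both the mean over fold metrics (headline, matching the common reading of
per-fold evaluation) and pooled-confusion metrics, since the reference
protocol does not say which it used.

## 8. Desk-scale protocol and what its green tests mean

The reference training protocol (200 epochs, 778 images, 224 x 224) is far
beyond a 1-CPU test budget.  The desk-scale protocol (`desk_protocol()`)
keeps the full pipeline and shrinks sizes only:

* 300 images at the reference class proportions (127/104/69), easy mode,
  phantom geometry 256 x 64;
* network input 32 x 32 — legitimate because the network is fully
  convolutional and its parameter budget is provably input-size invariant;
* lesion radius fractions enlarged by exactly the resolution ratio
  (224/32 = 7).  A lesion's footprint at the network input is
  `radius_frac x input_size` px whatever the phantom geometry, so without
  this the full protocol's 1.8-4.5 px lesions would shrink to sub-pixel
  specks and the benchmark would measure resolution loss rather than the
  pipeline (empirically: training loss ~0.1 but test accuracy capped near
  0.84).  Keeping the per-lesion pixel footprint constant is the standard
  way to scale a simulation to a coarser grid;
* 20 epochs, 10 folds, Adam and batch size unchanged;
* geometric augmentation disabled.  The binding class contrast at desk
  scale is normal vs degenerative — an intensity-at-fixed-location cue at
  the joints, which sit in the outermost columns of an 8-column content
  region; any useful rotation or zoom displaces them by a blob diameter.
  Empirically augmentation cost 3-7 accuracy points at this resolution,
  so the desk protocol drops it while the full-scale protocol keeps its
  minimal rotation/rescale.

Two properties are asserted: mean CV accuracy >= 0.90 on the easy phantom
(learnability), and chance-level accuracy after label shuffling (leakage
guard).  With the imbalanced class mix, "chance" for any
label-independent predictor lies between the smallest and largest class
prior (0.23-0.42 around the nominal 1/3), so the shuffled run is asserted
to fall in [0.15, 0.55] — observed ~0.37 — and far below the 0.90 bar.

## 9. Known limitations

* The phantom's realism is schematic; see section 2.  Its easy mode is
  intentionally separable — hard mode exists for stress testing, with no
  accuracy promise attached.
* The frozen block configuration is this package's construction, not the
  original authors'; only the structural constraints and the parameter
  budget are theirs.
* The engine targets this architecture family, not general graphs; it is
  single-threaded by design (BLAS threading aside) and CPU-only.
* Bit-reproducibility is guaranteed per platform (same BLAS and libm),
  not across platforms.
* The rule-based detector's guarantees hold at >= 512-row geometry.
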