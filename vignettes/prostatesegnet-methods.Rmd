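---
title: "ProstateSegNet: model, phantoms and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProstateSegNet: model, phantoms and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modeling assumptions, the scope of the
synthetic data generator, and the numerical design decisions behind
ProstateSegNet. It is the "why" companion to the reference
documentation's "what".

## 1. Problem and model

The package segments axial T2-weighted prostate MRI (T2WI) slices into
three classes — surrounding tissue (0), central gland (1) and marginal
gland (2) — with a compact encoder–decoder convolutional network,
`PSSNET`, and then feeds the segmentations into a small clinical
pipeline: Dice/Hausdorff quality metrics, D'Amico-style risk
stratification, and concordance statistics between detection methods.

The network, built by `buildPSSNet()` from a `NetworkConfig`:

* **Encoder**: three blocks of 3×3 same-padding convolution with 16, 32
  and 64 channels, each followed by spatial batch normalization and
  ReLU; the first two blocks end in 2×2 average pooling, the deepest
  block does not. A 64×64 input therefore reaches the bottleneck at
  16×16×64.
* **Decoder**: two stride-2 transposed convolutions (32 then 16
  channels), each followed by batch normalization and ReLU, restoring
  64×64 resolution.
* **Head**: a 1×1 convolution to 3 per-pixel class scores, a pixel-wise
  softmax, and the mean cross-entropy over every pixel of every image
  in the batch.

Training uses Adam (learning rate 1e-3, β₁ = 0.9, β₂ = 0.999,
ε = 1e-8), batch size 8, 10 epochs, He-initialized kernels. These are
the package's fixed reference conditions, not tuning targets: the test
suite and the acceptance script always run them as-is.

All layers are written from first principles in R. No deep-learning
framework is available (or wanted) here — the hand-derived forward and
backward passes *are* the point, and each is checked in the test suite
against an independent nested-loop oracle, hand-computed examples, and
finite differences.

## 2. Numerical design decisions

**Convolution as GEMM.** `convForward()` lowers each input window into
a column matrix (im2col) and evaluates the layer as one matrix product
on BLAS; the backward pass uses the transposed product plus a
scatter-add (col2im). Convolution means cross-correlation (no kernel
flip), the convention of every modern CNN framework.

**ReLU derivative.** The subgradient is taken as 1 for x > 0 and 0
otherwise, i.e. the derivative of max(0, x); the kink at 0 is assigned
0.

**Batch normalization.** Channel statistics are population moments over
all pixels and all batch samples of a channel; normalization divides by
`sqrt(var + eps)` with ε = 1e-5. Running means/variances are tracked
with momentum 0.1 for inference. Training-mode normalization of a
single-sample batch is refused (its variance estimate is degenerate);
`trainPSSNet()` therefore merges a trailing singleton batch into its
predecessor instead of ever normalizing a batch of one.

**Softmax stability.** Pixel scores are shifted by their per-pixel
maximum before exponentiation, so the partition function (the sum of
exponentials that normalizes the per-pixel class probabilities) never
overflows even for scores of magnitude several hundred.

**Cross-entropy normalizer.** The loss divides by the total number of
pixels across the whole batch (height × width × batch size), making the
reported loss a per-pixel average that is comparable across image and
batch sizes. Probabilities are clipped at 1e-12 before the logarithm.

**Transposed convolution.** Decoder kernels are constrained to
kernel size = stride (2×2, stride 2). This is the only configuration
whose output is exactly stride × the input dimensions with
non-overlapping contributions, which keeps the upsampling free of
checkerboard artifacts and makes the operator the exact adjoint of the
stride-2 valid convolution — an identity the tests verify to machine
precision.

**Input scaling.** Intensities (0–255) are divided by 255 before the
first layer so that activations start in a well-conditioned range for
He-initialized kernels.

**Determinism.** All randomness flows through `withSeed()` (which
saves and restores the caller's RNG state) and `deriveSeed()` (a
polynomial hash that fans a master seed out to named stages and cases).
Identical seeds give bit-identical phantoms, training runs and demo
artifacts; the demo's `manifest.yaml` deliberately contains no
timestamps so whole output directories are byte-reproducible.

## 3. The phantom generator: scope and limits

Real T2WI data cannot ship with the package, so `generatePhantom()`
draws a stylized axial slice: two concentric ellipses — a 40 mm
transverse × 20 mm antero-posterior gland with a central zone at 55 %
of the gland's linear size — over surrounding tissue, with class-mean
intensities 90 (surrounding), 140 (central), 190 (marginal) and
additive Gaussian noise (sd 10) at 1 mm/pixel on a 64×64 grid by
default. `generateCohort()` pairs each slice with a sampled clinical
record (Gleason patterns, log-normal PSA, clinical T-stage) and stamps
a dark lesion (intensity 70) into most cancer cases *before* noise is
added, mimicking the low-signal appearance of carcinoma on T2WI.

The generator is a test harness, not an anatomy simulator. It captures
the properties the pipeline depends on — concentric zonal geometry,
distinct class intensities, noise, dark foci, class imbalance — and
nothing else: no bladder or rectum, no intensity inhomogeneity, no
shape variation between cases (every mask in a cohort shares one
geometry; variation enters through noise, lesions and records). DSC
values near 0.99 on phantoms therefore say "the implementation learns
and segments correctly", not "expect 0.99 on patients".

The 64×64 default keeps a 250-phantom generate–train–evaluate cycle in
the minutes range on one CPU core; 128×128 phantoms work and are
exercised in the tests, they are simply slower.

## 4. Metrics

`dice()` operates on pixel-coordinate sets (filled regions) and errors
on two empty sets rather than defining 0/0. `hausdorff()` is computed
between 4-neighbor boundary pixels (image border counts as background,
so a region touching the edge has a boundary there) with Euclidean
distances, reported in pixels by default or millimetres when a pixel
spacing is given. `evaluateSegmentation()` offers a foreground mode
(any gland label vs background — the headline figure) and a per-class
mode (macro average over classes present in either mask).

## 5. Risk rule and concordance

`defaultRiskRule()` encodes the D'Amico-style thresholds: high if
Gleason ≥ 8 or PSA > 20 ng/mL or stage ≥ T2c; otherwise medium if
Gleason = 7 or 10 ≤ PSA ≤ 20 or stage = T2b; otherwise low. Precedence
is high > medium > low, which makes the rule total and exclusive — an
exhaustive grid test checks totality and monotonicity in each input.
Only confirmed cancer cases are stratified; `assignRisk()` refuses
hyperplasia records instead of silently binning them.

`positiveRate()` uses half-up rounding of the percentage (so 34.5 %
reports as 35, not R's banker's rounding to 34), matching how such
rates are conventionally reported. `chiSquare()` wraps
`stats::chisq.test(correct = FALSE)` in an S4 result object; the tests
verify it against a hand-written observed/expected loop.

The bundled reference tables (`inst/extdata/table2.csv`,
`table3.csv`) are reproduced as published data. They contain one
bookkeeping inconsistency: the before-processing row of the strata
table sums to 39 true cancers although the corresponding detection
count is 30. The tables are shipped as-is — the package documents the
discrepancy rather than silently "correcting" either number.

## 6. Pipeline

`runDemo()` chains everything: simulate an 89-case cohort (39 cancer /
50 hyperplasia), train the network, segment every slice, score DSC/HD,
call cancer per case from dark-focus evidence inside the segmented
gland (intensity cutoff 105, the midpoint between lesion and central
gland means; an intensity-threshold gland at cutoff 115 serves as the
"before processing" comparator), stratify detected cancers, and write
`metrics.csv`, `detections.csv`, `strata.csv`, `report.csv` and
`manifest.yaml`. The same stages are exposed individually through
`runPipeline()` and the `inst/scripts/prostatesegnet` command-line
front end, with run parameters supplied as a YAML file
(`loadRunConfig()` rejects unknown sections rather than ignoring
typos).

## 7. Limitations

* Phantoms are geometric stand-ins; none of the reported phantom
  metrics transfer to clinical data.
* The network is intentionally small and CPU-bound R; it is a reference
  implementation for study and verification, not a production
  segmentation engine.
* Risk stratification uses only Gleason/PSA/stage; no imaging features
  enter the rule.
* 2D slices only; there is no volumetric context.
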