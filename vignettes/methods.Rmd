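---
title: "Methods: spherical geometry, image generation and evaluation in sphereInsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spherical geometry, image generation and evaluation in sphereInsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphereInsight)
options(sphereInsight.verbose = FALSE)
```

## The problem

16S rRNA count tables (OTU/ASV features) are *compositional* — only relative
abundances are meaningful, because sequencing depth caps the total — and
*zero-inflated*: in typical stool cohorts well over 90% of cells are exact
zeros, a mixture of structural zeros (the taxon is truly absent) and sampling
zeros (present but undetected at finite depth). The classical log-ratio
toolkit for compositions is undefined at zero and forces pseudocounts or
model-based zero replacement, both of which distort exactly the sparsest —
often most informative — part of the table. They are also high-dimensional:
thousands of taxa against tens of samples.

`sphereInsight` classifies such tables by a route that needs no zero
handling at all:

1. **Closure.** Each sample's counts are divided by their total:
   \(x_i \in S^{d-1}\), the simplex (boundary points admitted).
2. **Square-root transform.** \(y = \sqrt{x}\) elementwise. Since
   \(\sum_i x_i = 1\), \(\lVert y\rVert_2 = 1\): samples become points on
   the nonnegative orthant of the unit hypersphere \(\mathbb{C}^{d-1}\).
   Zeros map to zeros; the boundary is a first-class citizen.
3. **Tangent projection (PGA).** The Fréchet mean \(p\) — the minimiser of
   summed squared geodesic distances — is rotated to the pole
   \((0,\dots,0,1)\), and every sample is flattened by the pole Log map
   \(\mathrm{Log}_p(y) = \frac{\theta}{\sin\theta}(y_1,\dots,y_{d-1})\),
   \(\theta = \arccos(y_d)\). Principal geodesic analysis is PCA in this
   tangent space; `pga()` provides it, but by default the *full* tangent
   representation (no truncation) feeds the next stage.
4. **Image generation.** A DeepInsight-style layout: the data matrix is
   transposed, the *features* are embedded in 2-D (PCA, kernel PCA, or
   t-SNE), the convex hull and its minimum-area bounding rectangle are
   computed by rotating calipers, the rectangle is axis-aligned and mapped
   onto a pixel grid, feature values are normalized to \([0,1]\), and each
   sample becomes a grayscale image.
5. **Segmentation offset.** Every foreground pixel value \(v\) is replaced
   by \(\max(v, \varepsilon)\). Without this, a zero-valued feature renders
   at exactly the background intensity, so zero-inflated samples have
   erratically varying image shapes; with it, all images share one support
   and "true zeros" remain distinguishable from the featureless background.
6. **Evaluation.** Stratified k-fold cross-validation of a small CNN, scored
   by the pair-counting (Mann–Whitney) AUC.

## Geometry: numerical choices

* **Fréchet mean.** Fixed-point iteration
  \(p \leftarrow \mathrm{Exp}_p\big(\tfrac1n\sum_i \mathrm{Log}_p(y_i)\big)\),
  initialised at the normalised extrinsic mean, full step, tolerance
  `1e-10` on the step norm, at most 200 iterations. Square-root compositions
  live in one open hemisphere (the nonnegative orthant), where this
  iteration converges to the unique minimiser; non-convergence raises an
  error carrying the last iterate rather than returning silently.
* **Small angles.** \(\theta/\sin\theta\) and \(\sin r / r\) switch to their
  Taylor series below \(10^{-6}\) rad, so a sample equal to the mean maps to
  the exact zero tangent vector instead of 0/0.
* **Antipodal points** are errors, not special cases: they cannot occur for
  nonnegative-orthant data, so they always indicate a caller bug.
* **Rotation.** `rotationToPole()` returns the dense rotation in
  span\(\{\mu, \text{pole}\}\) (identity on the complement). The pipeline
  itself applies the same map in a factored rank-2 form costing
  \(O(nd)\), so large taxon counts never materialise a \(d \times d\)
  matrix.
* **Leakage hygiene.** In cross-validation the Fréchet mean, rotation,
  feature layout, bounding rectangle, pixel map and normalization statistics
  are all fit on the training fold only; held-out samples are projected and
  rendered with the training-fold frame. The laxer fit-once-on-everything
  protocol is available by rendering outside `crossValidate()`, but is not
  the default.

## Imaging: parameters that matter

* **Grid size** (`gridH`, `gridW`): 224×224 is the full-scale CNN
  convention; the package defaults to 32×32, which keeps a desk-scale run in
  seconds while preserving the method's structure. All shipped tests and the
  acceptance script use 32×32 or smaller.
* **Rounding convention:** pixel coordinates round half-away-from-zero,
  0-based, row 0 at the top. Any consistent convention works; this one is
  stated so results are reproducible bit-for-bit.
* **Collision aggregation:** features sharing a pixel contribute their
  arithmetic *mean* (a `max` option exists). Mean preserves boundedness and
  is the convention of the original tabular-to-image layout.
* **\(\varepsilon\) (segmentation offset), default 1/255:** the smallest
  increment visible to an 8-bit consumer, so foreground and background stay
  distinct even after quantization. The offset is applied *after*
  normalization, as a clamp on foreground pixels. Applying it as a clamp —
  rather than tracing original zero positions through the rotation — is a
  deliberate design choice: the rotation to the pole mixes coordinates, so
  "the pixels of originally-zero features" is not well defined downstream,
  while the clamp realises the actual goal (one shared image support)
  unambiguously.
* **Normalization:** `independent` (per-feature train min/max; constant
  features map to 0) or `topology_preserving` (one global train min/range,
  preserving cross-feature ordering); `select_by_validation` picks per fold
  by inner-validation error. Out-of-range test values clip to \([0,1]\).
* **Layout rearrangement by clustering** (an optional step in some
  tabular-to-image pipelines) is not implemented: no concrete procedure is
  specified for it anywhere, and the pipeline is complete without it.

## Classification

The CNN is deliberately small: two 3×3 convolution blocks (8 and 16
channels, ReLU, 2×2 max pooling) and a linear head, trained with AdamW on
binary cross-entropy. Two head variants exist:

* `flatten` (default): the pooled feature map is flattened before the linear
  layer. DeepInsight's value lies in *where* features land on the grid;
  a location-aware head preserves that signal.
* `gap`: global average pooling. Location-invariant, closer to standard
  image-classification heads, but it discards the spatial coding that the
  layout constructs — measurably weaker on layouts whose classes differ by
  pixel position, which is exactly this package's regime. It is kept as an
  option for ablation.

No pretrained deep architecture ships with the package; requesting
`resnet50` errors explicitly rather than silently substituting. Learning
rate must lie in \([10^{-6}, 10^{-2}]\) and weight decay in
\((10^{-6}, 10^{-2})\); `randomSearch()` samples both log-uniformly so draws
are evenly spread across magnitudes, marks failed trials and continues, and
can report the max-over-trials objective — which is an optimistically biased
estimate, reported but not endorsed as a performance figure.

Folds are *stratified*: with imbalanced cohorts (e.g. 24 cases vs 67
controls) unstratified folds can lack positives entirely. One master seed
fans out to folds, layouts, initialisation and batch order; identical
configuration and seed reproduce image stacks byte-identically.

## The synthetic generator

Real IBD-cohort data of the kind this method targets are not distributable
with the package, so every stage is exercised on synthetic data whose
ground truth is known. Per sample: relative abundances are drawn from a
Dirichlet whose concentrations are class-adjusted (signal taxa multiplied by
`effectMultiplier` in class 1 — multiplicative on the concentration scale so
the signal survives closure), each taxon is masked structurally with
probability `structuralZeroProb` (truly absent), and counts are drawn from a
multinomial at the sequencing depth (adding sampling zeros). The two zero
mechanisms of real data are thus reproduced by two distinct mechanisms.

Shipped presets:

* `deskStrongParams()` — n = 200, d = 500, 25 signal taxa at 6× concentration,
  masking 0.3, depth 2×10⁴, balanced classes. Zero fraction ≈ 0.45. A linear
  probe (class-mean direction) on the tangent coordinates reaches AUC ≈ 1,
  so an end-to-end failure is attributable to the pipeline, not the data.
* `paperRegimeParams()` — n = 91 with 24/91 class balance, d = 2000,
  concentration 0.02, masking 0.85, depth 5×10⁴, weak signal. Calibrated
  once by Monte-Carlo to an empirical zero fraction of ≈ 0.975 (stored as
  `attr(, "targetZeroFraction")`), emulating cohorts where ~98% of cells are
  exact zeros.

What the generator does **not** emulate: phylogenetic correlation between
taxa, depth variation across samples, batch effects, and compositional
overdispersion beyond the Dirichlet. Passing tests therefore demonstrate
correctness of the machinery and recoverability of a known multiplicative
signal — not clinical performance on real cohorts.

## Problem sizes used in shipped checks

The package's own test and acceptance runs use the desk-scale
configuration: 32×32 grids, the `small_cnn`, 5-fold cross-validation of the
`desk-strong` preset, reduced-size replicates (n = 60, d = 80, 16×16) for the
paired segmented-vs-unsegmented comparison, and 10 seeds of the sparse
preset for generator calibration. These sizes are the package's choice of a
configuration that any laptop reproduces in minutes; the method itself is
unchanged at 224×224 with larger models.

## Known limitations

* The segmentation offset guarantees a shared support; it does not claim an
  AUC improvement on any particular dataset. On strong synthetic signal both
  arms saturate, so the shipped comparison asserts *non-inferiority* of the
  segmented arm, plus the support-mask contrast that separates the arms
  structurally.
* Exact t-SNE is \(O(d^2)\) per iteration in the feature count — fine for
  thousands of features, not for hundreds of thousands.
* The CNN is a CPU-scale stand-in for the full-scale architecture family;
  its purpose is faithful evaluation of the *data representation*, not
  state-of-the-art image classification.
* `pga()` truncation is available but off by default: the image stage
  consumes the full tangent representation, and truncating first would
  change what the layout sees.

## A worked desk-scale run

```{r, eval = FALSE}
sim <- generateDataset(deskStrongParams())
empiricalZeroFraction(sim$counts)
report <- crossValidate(sim$counts, sim$labels, k = 5, seed = 7)
report
foldAucs(report)
```

On the shipped preset and seed this prints a mean held-out AUC of 1.000
across the five folds (the preset is calibrated to be easy); the
label-permuted control under the same configuration lands near 0.45, inside
the chance band for these fold sizes.
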