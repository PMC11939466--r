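---
title: "Methods: patch-based detection of architectural dysplastic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based detection of architectural dysplastic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oedcnn)
```

## The problem and the model

Oral epithelial dysplasia (OED) is a premalignant condition of the oral
mucosa. Two of its *architectural* features — irregular epithelial
stratification (uneven layering of the epithelium) and bulbous rete ridges
(epithelial projections with a broad base and a narrow top) — are visible
at low power in H&E sections, and detecting them patch-wise avoids
segmenting whole slides.

The package frames this as three-class classification of fixed-size image
patches ("signatures"): `others`, `irregular_stratification`,
`bulbous_rete_ridge`. A compact CNN maps a patch to class probabilities:

* per block: an *l*-dilated `w1 × w1` convolution (valid, with bias) →
  batch normalisation (affine) → ReLU → pointwise `w2 × w2` convolution →
  BN → ReLU → 2 × 2 max pool, stride 2;
* the dilated (à trous) convolution spaces the kernel taps `l` pixels
  apart: `(f ⋆_l w)(p) = Σ_{s + l·t = p} f(s) w(t)`, cross-correlation
  convention (kernels are not flipped). A 3 × 3 kernel at `l = 2` has a
  5 × 5 receptive field with 9 weights. Each valid convolution shrinks the
  side by `(w − 1)·l`; each pool halves it (floor);
* the last block's `M` feature maps are reduced to an `M`-vector by global
  pooling: the mean (GAP), the maximum (GMP) or the log-sum-exp (GLSEP,
  computed max-shifted). For any map,
  `GMP ≤ GLSEP ≤ GMP + log(F1·F2)`;
* a fully connected hidden layer (ReLU, optional dropout with survivor
  scaling `1/(1 − p)`; identity at inference) feeds three output nodes with
  a softmax.

The flagship five-block configuration — channels 16/32/64/128/256, all
dilations 1, `w1 = 3`, `w2 = 1`, BN, GAP, hidden width 2048, no dropout,
350 × 350 YCbCr input — has exactly 1,014,867 trainable parameters;
`count_parameters()` gives the closed form (per block
`w1²·C_in·C_out + C_out + 2·C_out + w2²·C_out² + C_out + 2·C_out`, then
`M·h1 + h1 + 3·h1 + 3`) and always matches the built model. The channel
widths of the intermediate blocks follow the doubling progression — the
unique choice consistent with that printed total. BN is placed between
convolution and activation, the ordering that the layer table and the
parameter count jointly pin down.

## Colour space

Patches are converted from RGB to YCbCr with the fixed affine BT.601 map
(`rgb_to_ycbcr()`); both chroma rows of the matrix sum to zero, so
achromatic pixels keep `Cb = Cr = 128`. The transform is applied to
unit-scale RGB by default (`rgb_scale = "unit"`), exactly as specified for
inputs in `[0, 1]³`. Note the consequence: with unit inputs the luma spans
only `[16, 16.86]` and the chroma stay within about ±0.45 of 128 — the
conversion is then essentially a fixed offset plus a small signal. The
`"8bit"` switch applies the same matrix to `255 × RGB`, the convention
under which it produces full-range digital YCbCr. Both are exposed on
`arch_config()` so a network records which convention it consumes.

## Training

The loss is the class-weighted cross-entropy
`l_n = −w_{y_n} log softmax(x_n)_{y_n}`, evaluated on unnormalised logits
through the log-sum-exp identity for stability. Weights are inversely
proportional to class counts, normalised to sum to the number of classes —
any positive rescaling only multiplies the loss, and the normalisation
keeps unit weights for balanced data. The optimiser is Adam (the de-facto
default for small CNNs; the name is recorded in the run config), with the
stepped schedule `lr(e) = 10⁻³ · 0.5^⌊e/50⌋`. Epoch count (default 200,
covering four halvings) and batch size (32) are configurable. One master
seed drives weight initialisation, shuffling, dropout masks and fold
assignment, making every run exactly reproducible.

Evaluation uses stratified k-fold cross-validation (default `k = 4`):
within each label the signatures are shuffled and dealt round-robin, so
every fold contains all classes whenever counts allow (the split errors
otherwise). Per-class precision/recall/F1 are combined by support-weighted
averaging — the convention under which averaged recall is identically the
trace-over-total accuracy, which is also the pattern the reported per-fold
tables exhibit.

### Batch-norm statistics at inference

Two numerical choices matter here. First, the EMA running statistics are
debiased by the accumulated momentum weight (as Adam debiases its
moments), since they start from zero. Second, and more importantly,
`train_network()` finishes with a frozen-weight calibration pass that
recomputes exact population means and variances at every BN layer
(standard BN re-estimation). With unit-scale YCbCr inputs the convolution
outputs carry means roughly three orders of magnitude larger than their
standard deviations (the 16/128/128 offsets propagate through the
filters), so even the small lag of an EMA behind the drifting weights
misnormalises the features at inference; the calibration pass removes that
lag exactly.

### Mixed precision

`precision = "mixed_16_32"` emulates framework automatic mixed precision:
activations and propagated gradients are rounded through IEEE binary16
(round-to-nearest-even, implemented bit-exactly in C++) at every layer
boundary, while master weights, BN statistics and the optimiser state stay
in full precision. For inputs with O(1) feature scales (e.g. the RGB
configuration) full- and mixed-precision training reach final losses
within a fraction of a percent of each other. For the *unit-scale YCbCr*
configuration the contract genuinely breaks: at magnitude 128 the binary16
resolution is 0.0625, the same order as the entire chroma signal, so half
precision erases most of the colour information. This is a real property
of the number format, not of the implementation; it suggests that any
successful mixed-precision training of this network consumed inputs on the
8-bit (or otherwise rescaled) convention, and it is why the precision
contract is exercised on the RGB configuration in the test suite.

## The signature library

`extract_signatures()` slides a patch-sized window on a regular grid and
labels each cell by mask coverage: the feature class covering at least
`positive_fraction` (default 0.5) of the patch wins, ties going to the
rarer bulbous class; otherwise `others`. The grid yields exactly
`⌊(H−p)/s+1⌋·⌊(W−p)/s+1⌋` cells. Because a cell covering, say, 40% of a
ridge is neither clean background nor a clean feature example, library
builders may pass `ambiguous_band = c(lo, hi)` to drop cells whose largest
coverage falls in that band; `generate_library()` uses `[0.2, 0.5)` by
default. This mirrors how curated patch libraries are built in practice
and removes label noise that otherwise caps the attainable accuracy; the
bare `extract_signatures()` default keeps every cell.

Augmentation applies only to the training portion and, by default, only to
the bulbous minority: each signature gains one copy per transform, so the
three flips/rotation quadruple the class. The test portion is never
augmented, and train/test are disjoint by source image.

## The synthetic-data generator

The real 400× dysplasia dataset is private, so `generate_slide()` emulates
the *statistical structure* the classifier must exploit, with no claim of
biological realism:

* an eosin-pink background stippled with hematoxylin-purple nucleus dots on
  a regular row lattice ("strata", spacing 10 px, ±5% jitter);
* one rectangular irregular-stratification region (about 1.05–1.3 patch
  heights tall, 55–80% of the slide wide, placed in the upper slide) whose
  dots are re-drawn with positional jitter scaled by
  `stratification_disorder` (default 0.8 of the lattice spacing) plus
  ~50% extra dots ("crowding") — uneven cell arrangement;
* 1–3 teardrop-shaped ridges (broad base, narrow top; half-width
  `∝ cos(πt/2)^0.7` from base to tip, about 1–1.4 patch sides in extent)
  filled in the nucleus hue with chromatin speckle, placed in horizontal
  slots below the stratification band — the deterministic layout both
  matches where rete ridges sit relative to the epithelium and guarantees
  feasibility for every seed (infeasible geometry errors instead);
* Gaussian pixel noise (sd 0.03), then clamping to `[0, 1]`.

Masks are binary, class-disjoint and exactly reproducible from
`(seed, slide index)`. Defaults (384-px slides, 20 slides, 96-px patches,
stride 48) give a library of several hundred signatures in the imbalance
pattern of the domain: background majority, stratification intermediate,
ridges the minority. What the generator does **not** emulate: stain
variability, nuclear pleomorphism, focus/compression artefacts, tissue
folds — so passing tests demonstrate that the pipeline learns and detects
*separable* structure end to end, not that it would reach any particular
accuracy on real slides.

The desk-scale study used by the tests trains the three-block
`reduced_architecture()` (8/16/32 channels, hidden width 64, GAP) on
96 × 96 patches for up to 8 epochs; the full 350-pixel five-block geometry
is exercised by construction, counting and shape tests. Problem sizes were
chosen so the whole suite trains several networks in a few minutes.

## Sliding-window detection and FROC curves

`scan_image()` scores every window of a blind image on a stride-10 grid
(windows fully inside the image; smaller images are refused, since partial
windows lose information). At a threshold, firing windows paint their full
extent onto a coverage mask and the 8-connected components become
countable detection regions — the painting rule (`extent` vs `center`) and
matching rule (any-pixel overlap vs IoU) are configurable, since false
positives per image are only defined once these semantics are pinned
down. A ground-truth region counts as detected when any detection region
of its class touches it; one detection touching two ground-truth regions
detects both; several detections on one region count once. Coverage masks
nest as the threshold rises, so the probability of detection is monotone
non-increasing along the sweep (101 evenly spaced thresholds by default).

## Design choices that were genuinely open

* **Grid extraction.** Whether the original signatures were grid-sampled or
  hand-cropped is not determinable from the published counts; a grid with
  configurable stride (default 50 at full scale) is the reproducible
  choice.
* **Patch labelling.** Coverage thresholding with a configurable
  `positive_fraction` is the standard, testable rule.
* **Scorer plug-in.** `scan_image()` accepts either a fitted model or a
  plain scoring function receiving the window list (with origins and the
  slide as attributes); reference scorers — e.g. a ground-truth oracle —
  plug into the same evaluation path as trained networks.
* **Region semantics.** Full-extent painting + 8-connectivity +
  any-overlap matching as defaults, with centre painting and IoU matching
  as alternates.
* **Metric averaging.** Support weighting, selected because it uniquely
  reproduces the recall ≡ accuracy identity.

## Known limitations

* No stain normalisation or H&E deconvolution; colour shifts between
  laboratories would reach the classifier unchecked.
* The CPU implementation is intended for desk-scale experiments; training
  the full 350-pixel five-block network to convergence is out of its
  intended range.
* Exponentially chained dilation schedules are deliberately not
  implemented; dilations are per-layer constants.
* Mixed-precision mode is an emulation for studying the numerical
  contract, not a speed optimisation (rounding through binary16 in
  software is slower than full precision).
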