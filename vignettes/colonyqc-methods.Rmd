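---
title: "colonyqc: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colonyqc: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why.
It covers the classification model, the synthetic data generator and the
limits of what it emulates, the numerical conventions the operators
commit to, and the design decisions that were genuinely open.

## The problem

Human pluripotent stem cells grow as multicellular colonies whose
morphology tracks their state: colonies maintaining pluripotency are
flat with tightly packed, square-shaped cells and a prominent smooth
edge, while spontaneously differentiating colonies show loosely packed,
elongated cells with phase-bright inter-cell gaps and irregular, spiky
outlines. `colonyqc` frames quality control as binary image
classification of phase-contrast colony images (good vs bad phenotype)
and adds the scaffolding needed to study such a classifier quantitatively:
a generator with known ground truth, preprocessing and augmentation
operators with testable contracts, an evaluation toolkit, and a
multi-scale cropping analysis.

## Classification model

Five VGG-family convolutional networks are registered. `VGG13` follows
the canonical configuration-B layout: five stages of 3×3
same-padding convolutions with ReLU — 2×64, 2×128, 2×256, 2×512, 2×512
channels — each stage closed by a max-pool. The classifier head is
deliberately compact (flatten → dense 256 → ReLU → dense 1 → sigmoid):
with a single sigmoid output the network predicts `P(good)` directly and
pairs with the binary cross-entropy loss

\[ L = -\frac{1}{N}\sum_{i=1}^{N} \left[ y_i \log \hat y_i + (1-y_i)
\log(1-\hat y_i) \right], \qquad y_i = 1 \text{ for good}, \]

rather than a two-way softmax. The remaining variants are the most
literal readings of their names, isolated in one registry
(`arch_registry()`) so they are trivial to edit if a different reading is
wanted:

* `VGG13-FirstPool4` / `VGG12-FirstPool4` — the first max-pool uses
  kernel and stride 4 instead of 2, shrinking feature maps earlier; the
  saving is absorbed by the head, so these variants have strictly fewer
  parameters.
* `VGG12` — `VGG13` minus the second convolution of the last stage.
* `Res+VGG13` — `VGG13` with a skip connection around every stage. The
  skip is always a 1×1 projection convolution (channels change at four of
  the five stages anyway); the projection is added to the stage's last
  pre-activation and the ReLU follows the addition. Zeroing all
  projections therefore reproduces `VGG13`'s forward map exactly, which
  the test suite asserts.

Constraints and conventions:

* the square input side must be divisible by the product of pooling
  strides (32 for the base variants, 64 for `FirstPool4` ones);
* weights are He-uniform initialized (`limit = sqrt(6 / fan_in)`) from a
  seed, drawn in a fixed layer order, so a model is reproducible from
  `(name, input_side, width_factor, seed)` alone;
* `width_factor` scales every channel width and the head width. The
  canonical networks (`width_factor = 1`) are large; the package's own
  experiments use reduced widths (1/8 to 1/32) on 32–64 px inputs, which
  keeps a full train/evaluate cycle in the tens of seconds while
  exercising identical code paths.

The convolution and pooling kernels are compiled (Armadillo im2col +
GEMM; max-pool with argmax bookkeeping) with analytic backpropagation;
the test suite checks the gradients against central finite differences.
Optimization uses Adam (defaults: learning rate 1e-4, β₁ 0.9, β₂ 0.999,
batch 16, up to 50 epochs, early stopping after 10 stale epochs); the
returned checkpoint is the epoch with the lowest validation loss.
Learning rate, epochs, batch size and optimizer were not constrained by
the problem statement; the defaults are conservative choices for small
datasets, and the small-model experiments in the tests use 1e-3, which
converges in a handful of epochs at those widths. Probabilities are
clamped to `[1e-7, 1 - 1e-7]` inside the loss to avoid `log(0)`. A
non-finite training loss aborts with a diagnostic rather than continuing
silently.

## Data splitting and evaluation

`split_dataset()` draws a validation set of `round(n · val/(train+val))`
items (4:1 by default, so 269 images yield 54). Stratification by label
is on by default — the problem statement is silent on it, but with
near-balanced classes it is benign and removes a nuisance source of
variance; per-class quotas are assigned by largest remainders so the
total is exact, and a missing class falls back to an unstratified split
with a warning.

`confusion()` counts under an explicit positive-class convention.
`evaluate_predictions()` reports all measures under **both** conventions:
the loss convention makes good the positive class, but published
precision/recall pairs for this kind of classifier are sometimes only
consistent with bad-positive counting, so the report keeps both visible
(headline = good-positive) instead of silently choosing. Zero-denominator
ratios are reported as 0 and flagged in `undefined_measures` rather than
returned as `NaN`. AUC is the rank-based Mann–Whitney statistic with
ties counted ½; the suite checks it against a threshold-sweep
trapezoidal oracle and against `pROC`.

## The synthetic generator

`generate_colony()` renders a pseudo-phase-contrast colony: a radial
polygon outline (72 vertices, low-frequency lobes shared by both classes
plus per-vertex uniform noise scaled by `edge_spikiness`), dark
anti-aliased elliptical cell bodies placed on a jittered square grid,
inter-cell space at `gap_brightness`, a Gaussian-blurred bright halo ring
along the colony rim, a mild illumination gradient, a final 0.6 px blur,
and additive Gaussian noise (`noise_sd`, default 0.02 on the unit scale).

The per-class presets encode the qualitative phenotype criteria:

| parameter | good | bad | rationale |
|---|---|---|---|
| eccentricity | 0.25 | 0.75 | square-ish vs elongated cells |
| packing_fraction | 0.90 | 0.55 | tight vs loose packing |
| size_cv | 0.15 | 0.40 | uniform vs greatly varying cell sizes |
| edge_spikiness | 0.05 | 0.40 | smooth vs spiky colony edge |
| gap_brightness | 0.60 | 0.88 | phase-bright gaps between cells |

No quantitative morphometrics are published for the two phenotypes, so
these presets are plausibility choices, fixed once: they are presets, not
fits. `separation` interpolates the effective bad preset component-wise
from the good preset (0 = identical classes) to the full bad preset (1),
giving a controlled effect size. Cell geometry is physical: mean cell
diameter 15 µm (cells are drawn area-true for their eccentricity), and
the default canvas is 256×256 px at 290/256 ≈ 1.13 µm/px so a whole
~290 µm field of view fits; the real-capture geometry (1280×960 px at
0.227 µm/px) is available through `image_size_px`/`um_per_px`.

Seeding: a master seed spawns one child seed per item as a pure function
of `(master, class, index)`, so the i-th good image is identical no
matter how many bad images are requested, and datasets are byte-for-byte
reproducible through PNG encoding.

What the generator does **not** emulate: phase-contrast optics (no point
spread function, shade-off or proper halo physics), nuclei and nucleoli,
confluent multi-colony fields, focus drift, debris, or the continuum of
partial differentiation — classes are drawn from exactly two parameter
vectors. Tests passing on synthetic data therefore demonstrate that the
pipeline machinery is correct and that the classifier can exploit cues of
this kind; they say nothing about accuracy on real micrographs.

## Preprocessing conventions

* **Resize**: the 4:3 source frame cannot be "proportionally" mapped onto
  a square, so the resize is a direct anisotropic map to the target
  square using exact area interpolation (each output pixel is the mean of
  the input area it covers — antialiasing on downsampling, global mean
  preserved exactly), with µm-per-pixel rescaled per axis so the physical
  field of view is invariant.
* **Grayscale**: `Y = 0.299R + 0.587G + 0.114B`; the coefficients sum to
  1, so gray inputs are fixed points. Values stay floating point until
  export.
* **Min–max**: `(x − min)/(max − min)`; a constant image maps to all
  zeros (declared convention for the degenerate range). Idempotent.
* **Binarize**: on the unit scale, `pixel ≥ threshold → 1` (inclusive
  boundary, one side had to be chosen and is documented); the default
  threshold is per-image Otsu — parameter-free and standard — with a
  numeric override. Idempotent.
* **Equalize**: global 256-bin CDF remap, `v → CDF(v)`, stretching the
  histogram over the unit interval; monotone, so pixel order is
  preserved. Not adaptive (no CLAHE) — the global dialect is the plain
  reading of "histogram equalization".
* **Order**: resize first, then the intensity operator. Whether the
  original pipeline equalized before or after resizing is unknowable from
  its description; resize-first is cheaper and is fixed here as the
  package's convention.

## Augmentation conventions

Random cropping keeps a square window of linear fraction
`crop_fraction` (default 0.875, the common 224/256-style convention; the
original description does not state a crop size) at an offset uniform
over all valid positions inclusive, then resizes back to the model input
side — feeding networks at a fixed input side requires one of crop-size
or resize-back, and resize-back is the interpretation fixed here. The
dihedral family is the full 8-element symmetry group of the square,
drawn uniformly; these transforms permute pixels exactly, so intensity
histograms are invariant. Composition order is crop → dihedral (the two
commute distributionally; fixing an order buys reproducibility).
Augmentation is applied online, per epoch, to training items only —
validation data is never augmented, which the suite verifies by showing
validation metrics are unchanged by augmentation settings when the
learning rate is driven to zero.

## The spatial-scale scan

`quarter()` cuts an image into four exact tiles (odd sizes are
edge-replicated first, with a message); `build_pyramid()` iterates it, so
level *k* holds `n·4^k` images of linear physical size `base/2^k` — for a
290 µm field: 290, 145, 72.5, … µm. Labels are inherited, so class
balance is exact at every level. `scale_scan()` makes the 4:1 split once
per seed **at level 0** and propagates it down, so all crops of one
parent stay on one side of the split — the description of the original
procedure does not say whether it did this, but not doing it leaks
near-duplicate content across the split, and scientific correctness wins
over literal ambiguity. Crops are resized to the network input side
before training; "image size" for a non-square frame is reported as the
crop **width** in µm (the only reading consistent with a ~145 µm optimum
after one quartering of a 290 µm-wide field). The best level per seed is
the accuracy argmax, with ties resolved toward the shallower level.

The test suite's constructed scale experiment generates classes that
differ **only** in cell eccentricity (0.05 vs 0.95) with packing, gap
brightness, outline and cell size matched — at equal packing with looser
cells (0.5) so cell bodies stay visually distinct. Elongation is
invisible once a 128 px frame is compressed to the 32 px network input
(cells span ~3 px) but survives in level-1 crops (~7 px/cell), so the
scan should — and in the suite does — place the accuracy argmax below
whole-image scale in the majority of seeds. Sizes used there (120 base
images, width-1/8 VGG12 at input 32, 15 epochs, 3 seeds) were chosen to
make the effect reproducible at desk scale.

## Problem sizes in the test suite

The suite runs entirely on generated data: separability and null
training runs use 200 images at 64 px with a width-1/8 VGG12 (about
120k parameters); property checks use 8–64 px images; the scale scan is
described above. The canonical full-width registry entries are exercised
for construction, parameter-count arithmetic and forward contracts, not
for training.

## Known limitations

* The generator's two-point class structure makes synthetic
  classification much easier than real phenotyping; accuracy numbers on
  synthetic data are machinery checks, not performance claims.
* The canonical architectures at 256 px input are computationally heavy
  in this pure-R/Armadillo engine (single-threaded CPU); realistic-scale
  training is possible but slow, and the package's experiments use the
  reduced widths instead.
* The registry encodes one interpretation of the five architecture
  names; the original appendix-level layer tables were not available, so
  channel widths and head sizes beyond `VGG13`'s canonical layout are
  declared interpretations, kept in one file by design.
* Only binary labels are supported; partially differentiated colonies
  must be binned into one of the two classes upstream.
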