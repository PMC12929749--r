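---
title: "Coarse-to-fine localization and segmentation of retropharyngeal edema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine localization and segmentation of retropharyngeal edema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Retropharyngeal edema (RPE) is a reactive fluid pattern in the
retropharyngeal space — the narrow compartment between the pharyngeal
constrictors and the prevertebral muscles — that appears on fat-suppressed
T2-weighted neck MRI as a thin, bright, midline band in patients with acute
deep neck infections. Its volume carries prognostic information, which makes
automated volumetry attractive. Segmenting it automatically is hard for one
dominant reason: the lesion is vanishingly sparse. In clinical material of
this kind the positive voxels make up between 0.0023% and 0.31% of the
volume, and neck MRI is strongly anisotropic (roughly 0.5 mm in plane
against ~4.8 mm between the 26–60 axial slices). A segmentation network
trained directly on full slices never converges on a target this small,
even under an overlap-based loss.

`rpeseg` implements a coarse-to-fine answer to that problem:

1. **Slice-wise classification.** Three independent convolutional
   classifiers score every axial, coronal and sagittal slice for lesion
   presence. Scores along each slice axis are smoothed with a centered
   moving average and binarized at the Youden-index threshold estimated
   from training-set predictions.
2. **Bounding-region construction.** A voxel is inside the positive region
   iff its axial, coronal *and* sagittal slices were all predicted
   positive — the literal set product of the three positive index sets.
3. **Tile segmentation.** 64×64 tiles are sampled on a stride-32 lattice
   around the region (a tile qualifies if it holds at least one third of
   the region's cross-section on that slice, or an absolute pixel count)
   and segmented by a compact U-Net trained with the soft Dice loss.
   Volumes with fewer than 64 axial slices are stretched along z for the
   coronal and sagittal views.
4. **Reassembly and 2.5D fusion.** Tile predictions are written back into a
   zero-initialized array of the volume's shape (overlaps averaged),
   binarized per view, and fused across the three views by per-voxel
   majority vote — the "2.5-dimensional" mask.

The package contains everything needed to train and evaluate this pipeline
without patient data: a synthetic phantom generator, the two network
architectures with a compiled training engine, cross-validation
orchestration, and the evaluation battery (confusion metrics, AUROC, Dice,
volume agreement).

## The two networks

Both networks are fixed reference architectures; their trainable parameter
totals are part of the package's contract and are asserted in the tests.

The **slice classifier** takes one 128×128×1 slice (any slice is bilinearly
resized to 128×128 and min–max normalized with the *whole-volume* extrema)
and returns a single probability. It is a U-Net-style encoder: four stages
of paired 3×3 convolutions with 16, 32, 64 and 128 filters, each stage
closed by max pooling (2, 2, 2, then 4), followed by dense layers of 128,
64 and 32 ReLU units and a sigmoid output — 565,873 trainable parameters.
It trains with binary cross-entropy, Adam at learning rate 0.001, for five
epochs.

The **tile U-Net** maps a 64×64×1 tile to a per-pixel probability mask:
encoder stages of paired 3×3 convolutions (16 then 32 filters) with 2×2
pooling, a 64-filter bottleneck, and a decoder of 2×2 transpose
convolutions with skip concatenations from the two encoder stages, closed
by a 1×1 sigmoid head — 116,753 parameters. It trains with the soft Dice
loss

$$L = 1 - \frac{2\sum_i p_i q_i + \varepsilon}{\sum_i p_i + \sum_i q_i + \varepsilon},$$

Adam at 0.001, for 30 epochs.

Dice-loss training on targets this sparse has a failure mode that shaped
four deliberate choices of this package (the loss formula, optimizer,
learning rate and epoch counts are untouched):

* **The smoothing constant is small** ($\varepsilon = 10^{-6}$), a pure
  guard against 0/0. The popular choice $\varepsilon = 1$ is quantitatively
  wrong at this tile size: at the all-empty prediction the uniform-direction
  derivative of the per-tile loss is
  $-2\Sigma q/S + 4096\,\varepsilon/S^2$ with $S = \Sigma q + \varepsilon$,
  which is *positive* — the empty state is a genuine local minimum —
  whenever the lesion covers fewer than about $\sqrt{4096} = 64$ pixels.
  Typical tiles here hold 15–50 lesion pixels, and with $\varepsilon = 1$
  training converged to the frozen all-empty predictor reproducibly across
  seeds. With a small $\varepsilon$ the escape force wins for any nonempty
  target.
* **Leaky convolution activations** (slope 0.01) in the U-Net: the early
  "suppress everything" transient can otherwise silence the entire ReLU
  stack permanently (a constant output with exactly zero gradients —
  observed in roughly half of initialization/shuffle pairs before the fix).
* **The head bias starts at the background-prior logit** (−4) rather than
  0, the standard sparse-segmentation initialization; it removes most of
  that destructive transient in the first place.
* **Head logits are clamped** to $|z| \le 15$ so single-precision sigmoid
  gradients never underflow to exactly zero.

```{r}
library(rpeseg)
n_parameters(build_classifier(seed = 1))  # 565873
n_parameters(build_unet(seed = 1))        # 116753
```

Where the architecture drawings admitted more than one reading (dense-layer
widths, the pooling schedule), the printed parameter totals were treated as
the binding constraint; the configuration above is the unique one with
doubling filter widths and power-of-two dense layers that reproduces both
totals exactly.

## The compiled engine and its numerics

No deep-learning framework is involved: the package ships its own compiled
single-threaded engine (RcppArmadillo, single precision, im2col + GEMM)
implementing the forward and backward passes of exactly these two
architectures, with Adam, binary cross-entropy and soft-Dice losses. Two
properties matter for users:

* **Verifiability.** The test suite contains a plain-R double-precision
  reference implementation of both forward passes; the compiled engine must
  agree with it to float tolerance, and its analytic gradients must match
  central finite differences of the reference loss.
* **Reproducibility.** Initialization (Glorot uniform), per-epoch shuffling
  and every sampling step draw from R's RNG under explicit seeds, and the
  engine runs strictly sequentially, so a run is a pure function of
  (configuration, seed) for a fixed BLAS thread count. Subnormal floats are
  flushed to zero inside the engine; this affects only values below about
  1e-38 and keeps step times flat as trained weights shrink.

Half precision appears as a *storage contract*: preprocessed slices and
tiles are rounded to the nearest IEEE half-precision value (the package
computes in full precision thereafter). Normalization uses whole-volume
extrema rather than per-slice extrema — per-slice scaling would erase the
between-slice intensity differences that distinguish edematous slices, and
the choice is deliberately conservative for the classifier task.

## Thresholds, ties and degenerate inputs

* The Youden scan evaluates midpoints between adjacent sorted unique scores
  plus both extremes, classifies with `score >= threshold`, and breaks ties
  toward the **lower** threshold (higher sensitivity at equal J).
* The moving average is centered with truncated (shrinking) windows at the
  series ends; the default width is 3 and must be odd.
* A constant volume (max = min) normalizes to all zeros.
* Dice against an empty ground-truth mask raises an error rather than
  silently defining 0 or 1; only lesion-positive patients are evaluated.
* The tile lattice starts at index 1 with stride 32; when an axis is not
  stride-aligned a final edge-clamped offset is appended so the image edge
  remains coverable.
* Fused tile probabilities binarize at 0.5 by default (configurable), and
  overlap fusion defaults to the mean (`"max"` available).
* The per-view masks are binarized first and majority-voted afterwards.
* Non-contiguous positive index sets are kept as-is in the region (the set
  product is *not* bridged into one contiguous box); the smoothing step
  already discourages isolated gaps.
* All indices in the R interface are 1-based; axial/coronal/sagittal slices
  fix the first/second/third array index of the `[z, y, x]` grid.
* Accuracy is computed as `(TP+TN)/(TP+FN+FP+TN)`; a variant omitting FP
  from the denominator exists behind `formula = "as_printed"` purely for
  auditability against older reports.
* Metrics with zero denominators are reported `NA` and excluded from
  cohort means rather than imputed.

## The phantom generator

`generate_phantom()` emulates the geometry and sparsity of the clinical
material, not its radiological appearance. Per case it samples 26–60 axial
slices, slice spacing from Normal(4.80, 0.228) mm clipped to [3.98, 5.96],
in-plane spacing from Normal(0.528, 0.149) mm clipped to [0.375, 0.694],
and a lesion volume drawn log-uniformly from 234–31,490 mm³ scaled by
`(in_plane/512)^2` — the desk-scale default of 128×128 pixels preserves the
positive-voxel *fraction* that makes the problem hard while keeping
training fast; the clinical 288–640 px range is selectable. The sampled
volume is truncated (with a 5% guard for discretization) to the range that
keeps the positive fraction inside [0.0023%, 0.31%] for the sampled grid,
so the sparsity regime holds by construction for essentially every seed.

The lesion is shaped like RPE: a thin anterior midline band, tall along z,
wide along x, thin along y, built as the superlevel set of a sum of three
overlapping anisotropic Gaussian blobs. The threshold is found by binary
search on the size of the largest 26-connected component (superlevel sets
are nested, so that size is monotone in the threshold), giving exactly one
connected lesion within a few percent of the target volume. The background
contains simple anatomic surrogates — a dark airway column with axial
wobble, a vertebral column, bright fat planes, a slow intensity ramp — plus
additive Gaussian noise. Lesion contrast (mean lesion over mean background
intensity, default 3) and noise SD (default 0.05) are free parameters; no
claim is made about real fat-suppressed T2 intensity statistics, which the
source material does not report.

What passing tests on phantoms do show: the pipeline's machinery —
classification, thresholding, region construction, tile bookkeeping,
reassembly, voting, evaluation — is correct and learns when lesions are
learnable. What they do not show: performance on real MRI, with its bias
fields, motion, fat-suppression failures, anatomical variability and
ambiguous lesion boundaries. The phantom's high-contrast lesions make the
classification task much easier than the clinical one; phantom metrics are
upper bounds by design.

## The desk-scale reference experiment

`run_experiment(experiment_config(), seed)` runs the whole method at desk
scale: 25 lesion-positive phantoms (contrast 3, 128² in-plane), five-fold
cross-validation over patients, per-fold training of three classifiers and
three U-Nets, Youden thresholds from smoothed training predictions,
end-to-end prediction of each fold's held-out patients, and the full
evaluation battery. Patients never appear in the training set of their own
test fold, for either network family; the split audit is part of the test
suite.

Three knobs make the default run fit in minutes on one CPU without changing
the method, and all three can be turned off:

* `max_train_slices = 120`: classifiers train on a balanced per-view
  subsample (all-slices training is `Inf`). Balance also counters the heavy
  negative-slice majority in the coronal and sagittal stacks.
* `youden_volumes = 6`: thresholds are estimated from the full smoothed
  score series of six training volumes per fold, and the U-Net's training
  tiles are sampled from those volumes' *predicted* regions — the same rule
  used at test time (`tile_source = "truth_region"` switches to
  ground-truth regions).
* `max_train_tiles = 64`: per-view cap on training tiles, balanced so that
  lesion-bearing tiles fill at least half of it. Balance matters here:
  wherever the predicted region overshoots the true lesion extent it yields
  tiles whose ground truth is entirely empty, and a Dice-loss U-Net trained
  on a mostly-empty tile set collapses to the all-empty prediction.
* Mini-batch 8 for both networks: with capped training sets, batch 32
  would leave only a few dozen optimizer steps inside the fixed 5/30-epoch
  budgets; batch 8 restores enough steps to converge reliably at identical
  wall time. Batch size is an implementation choice here, not part of the
  reference recipe.

The absolute tile-selection criterion (1,000 region pixels at full 288–640
px scale) is scaled by `(in_plane/512)^2` automatically — 62.5 pixels at
the 128² desk scale — since it was calibrated to full-size slices.

One further desk-scale reading: cross-validation is run once per fold
(five trainings in total); the stricter repeat-per-fold reading of the
protocol is available by simply re-running with different seeds.

## Known limitations

* The engine implements exactly the two reference architectures; it is not
  a general network library.
* Tile sampling assumes in-plane sizes of at least 64 pixels, and the
  axial stretch targets exactly the tile side.
* Phantom realism is geometric, not radiometric (no bias field, coil
  profile, or Dixon fat–water effects).
* Bit-exact reproducibility assumes a fixed BLAS thread count; on a single
  CPU (the intended desk-scale setting) this holds automatically.
* Patient-level presence/absence classification is out of scope; all
  evaluated patients carry a lesion, and Dice against an empty truth is
  deliberately an error.
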