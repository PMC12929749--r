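# rpeseg

Coarse-to-fine localization and segmentation of retropharyngeal edema (RPE)
in anisotropic 3D neck MRI — as a fully trainable, desk-scale R package.

## The problem

RPE is a reactive fluid band in the retropharyngeal space that shows up
bright on fat-suppressed T2-weighted MRI in acute deep neck infections, and
its volume is a candidate severity marker. Automated volumetry is hard
because the lesion is extremely sparse — 0.0023%–0.31% of the voxels of a
strongly anisotropic volume (~0.5 mm in plane, ~4.8 mm between the 26–60
axial slices). A segmentation CNN pointed at whole slices simply never
converges on a target that small.

`rpeseg` implements the coarse-to-fine strategy that works around this:

1. **Slice-wise classification** — three encoder-style CNNs (one per
   anatomical view) score every axial, coronal and sagittal slice for
   lesion presence; score series are smoothed with a centered moving
   average and binarized at the Youden threshold estimated from training
   predictions.
2. **3D bounding region** — a voxel is positive iff its axial, coronal and
   sagittal slices are all predicted positive (the set product of the three
   positive index sets).
3. **Tile segmentation** — 64×64 tiles sampled on a stride-32 lattice
   around the region (kept if they hold ≥ ⅓ of the region's slice
   cross-section or an absolute pixel count) are segmented by a compact
   U-Net trained with the soft Dice loss
   `1 − (2Σpq + ε)/(Σp + Σq + ε)`; short volumes are stretched along z for
   the coronal/sagittal views.
4. **2.5D fusion** — tile predictions are reassembled into per-view 3D
   masks (overlaps averaged, uncovered voxels 0) and fused by per-voxel
   majority vote.

The two networks are fixed reference architectures: the slice classifier
(128×128×1 → scalar; conv pairs 16/32/64/128 with max-pools, dense
128/64/32/1) has exactly **565,873** trainable parameters, and the tile
U-Net (64×64×1 → 64×64; 16/32 encoder, 64 bottleneck, two skip
concatenations) exactly **116,753**. Training (Adam 0.001; BCE for 5
epochs, Dice loss for 30) runs on the package's own compiled
single-threaded engine (RcppArmadillo); no deep-learning framework is
required. Since no clinical accession exists for this kind of data, the
package ships a synthetic phantom generator that reproduces the geometry
and sparsity statistics above, so the entire method is trainable and
testable at desk scale.

## Worked example

Build the networks and verify the architecture contract:

```r
library(rpeseg)
n_parameters(build_classifier(seed = 1))
#> [1] 565873
n_parameters(build_unet(seed = 1))
#> [1] 116753
```

Generate a phantom and look at it:

```r
case <- generate_phantom(phantom_spec(seed = 7))
case
#> <phantom_case 'phantom'>  44 x 128 x 128, lesion 68.5 mm^3 (0.0146% of voxels)
autoplot(case)  # axial slice through the lesion with the truth contour
```

Run the desk-scale reference experiment — 25 lesion-positive phantoms,
five-fold cross-validation, full pipeline per fold (trains 15 classifiers
and 15 U-Nets; about 12 minutes on one CPU):

```r
ex <- run_experiment(experiment_config(), seed = 1)
ex
#> <rpe_experiment>  25 patients, 5 folds, 12.2 min
#>   patient-wise AUROC:  axial 1.000, coronal 1.000, sagittal 1.000
#>   mean Dice:           2.5d 0.905, axial 0.858, coronal 0.904, sagittal 0.873
#>   volume agreement:   r 0.963, MAE 84 mm^3, MRE 19.3%
```

Reading the numbers: per-view patient-wise AUROC is the slice
classifiers' discrimination on held-out patients; mean Dice is the overlap
between each predicted 3D mask (per view, plus the 2.5D majority vote) and
the ground truth; the volume agreement line compares lesion volumes
computed from the axial-view masks with the true volumes (Pearson r, mean
absolute error, mean relative error). On easy high-contrast phantoms the
classifiers are near-perfect and segmentation overlap is high; larger
lesions still segment better than smaller ones (`ex$dice_volume_r` is
positive), mirroring the volume–Dice relationship seen clinically. Real
fat-suppressed T2 material is far harder than these phantoms — there the
same pipeline design lands in the Dice ~0.5 range typical of
sparse-lesion MRI segmentation.

All result tables are tibbles (`ex$slice_metrics`, `ex$dice`,
`ex$volumes`, `ex$regions`, …) with `tidy()`/`glance()` methods and
`autoplot()` displays (`type = "dice"`, `"auroc"`, `"volume"`).

A command-line front end is installed with the package
(`system.file("cli", "rpeseg.R", package = "rpeseg")`) with `phantom` and
`experiment` subcommands writing NIfTI cohorts and CSV result tables.

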