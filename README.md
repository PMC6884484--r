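# gplfuse

Multi-atlas label fusion for 3D brain MR segmentation, combining sparse
representation and patch-similarity voting through trained greyscale
probabilities.

## The problem

Multi-atlas segmentation (MAS) labels a target image by registering several
expert-labelled atlases to it and fusing their propagated labels at each
voxel. The two standard patch-based fusion rules fail in complementary ways
on deep grey-matter structures (thalamus, hippocampus, caudate, putamen,
pallidum, amygdala):

* **PSWV** (patch-similarity weighted voting) fuses *all* candidate patches
  with NCC weights, `Fv(x_j) = Σ w_i l_i / Σ w_i` — robust in the interior
  but blurred at tissue boundaries, where registration error makes label
  frequency unreliable.
* **SRLF** (sparse-representation label fusion) votes with the sparse
  coefficients `α` of `min ‖α‖₀ s.t. ‖PT − D_I α‖₂ ≤ ε`, where `D_I` is the
  dictionary of atlas patches — sharp at boundaries but prone to "empty
  points" inside the structure, because most patches are discarded.

`gplfuse` implements a piecewise fusion of both, gated by a per-intensity-bin
probability `P(x_j)` that the voxel's grey level belongs to the target
tissue:

```
L(x_j) = 1                      if Fv_SRLF > 0.9  or  Fv_PSWV > 0.9
       = 1{β₁·Fv_SRLF·Fv_PSWV·P(x_j) > 0.5}   if both in (0.4, 0.9)
       = 1{β₂·Fv_SRLF·P(x_j) > 0.5}           if Fv_SRLF ≤ 0.4
       = 1{β₃·Fv_PSWV·P(x_j) > 0.5}           if Fv_PSWV ≤ 0.4
```

`P` is defined on 20 intensity bins of the normalized [0, 1] range,
restricted to a tissue greyscale range detected from the target's histogram
peaks, and trained by maximizing `‖Dsc‖₁` — the summed leave-one-out Dice
over the spatially selected training atlases. Per-tissue constants
(β₁ = 3.13; β₂, β₃, intensity span and peak offset per structure) ship with
the package.

Because registration itself is out of scope, the package includes a synthetic
generator: piecewise-constant noisy phantoms plus smooth random deformation
fields standing in for residual registration error, so the entire pipeline is
testable offline.

## Worked example

```r
library(gplfuse)

# a 48x48x12 phantom world with six warped atlases
truth   <- make_phantom(phantom_spec(), seed = 1)
atlases <- make_warped_atlases(truth, warp_spec(seed = 102))

# fit: detect the tissue greyscale range on the target, train P by
# leave-one-out coordinate ascent over the atlases
fit <- gplf_train(truth$intensity, atlases, "thalamus", seed = 1)
print(fit)
#> Greyscale-probability label fusion model
#>   tissue: thalamus (beta = 3.13 / 1.25 / 0.67)
#>   tissue greyscale range: [0.400, 1.000] (20 bins, ISNmax 17)
#>   training: 6 atlases, leave-one-out mean Dsc 0.8826

# segment with the full model and both baselines
for (m in c("gplf", "pswv", "srlf"))
  print(evaluate_segmentation(truth$label, predict(fit, method = m)))
#> Dsc 0.9555 | Recall 0.9148 | Precision 1.0000 | HD 1.000 mm   (gplf)
#> Dsc 0.8500 | Recall 0.7473 | Precision 0.9855 | HD 1.500 mm   (pswv)
#> Dsc 0.9377 | Recall 0.9505 | Precision 0.9251 | HD 1.500 mm   (srlf)
```

The fused model recovers the voxels PSWV misses at the boundary (recall
0.91 vs 0.75) without SRLF's interior false positives (precision 1.00 vs
0.93). `coef(fit)` returns the trained per-bin probabilities and `plot(fit)`
draws them over the detected tissue range.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/gplf.R simulate --out data --seed 7
Rscript inst/cli/gplf.R train-p  --data data/subject01 --tissue thalamus --out coeffs.json
Rscript inst/cli/gplf.R fuse     --data data/subject01 --tissue thalamus \
                                 --coeffs coeffs.json --out seg.nii
Rscript inst/cli/gplf.R evaluate --seg seg.nii --truth data/subject01/target_label.nii
```

Real data enters through `read_volume()` (NIfTI-1, `.nii`/`.nii.gz`), with
`binarize_label()` to pull one structure code out of a multi-label image;
volumes are assumed already co-registered.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the seeded phantom world, fits the model from scratch (range
detection, probability training), segments with all three methods, prints
their Dice / recall / precision / Hausdorff metrics, and writes the results
JSON.

## Documentation

The methods vignette (`vignettes/gplf-methods.Rmd`) describes the model, its
parameters and defaults, the synthetic-data generator's scope, and the
numerical design choices.
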