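---
title: "Greyscale-probability label fusion: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greyscale-probability label fusion: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gplfuse)
```

## The segmentation model

`gplfuse` labels each voxel of a target volume by fusing the labels of
co-registered atlases (each an intensity image plus an expert binary label
image). Two fusion values are computed per voxel from a library of atlas
patches centred at the same in-plane position:

* `Fv_PSWV`: the similarity-weighted vote `Σ w_i l_i / Σ w_i`, with `w_i` the
  NCC between the target patch and atlas patch `i` (clamped at zero — a
  negatively correlated patch carries no vote mass) and `l_i` the atlas
  centre-voxel label.
* `Fv_SRLF`: the same vote with `w_i = max(α_i, 0)`, where `α` sparsely codes
  the target patch over the dictionary of atlas patches.

The decision combines both with a greyscale probability `P(x_j)`, evaluated
branch by branch in fixed order (first match wins):

1. `Fv_SRLF > 0.9` or `Fv_PSWV > 0.9` — tissue, regardless of `P`. Nearly all
   such voxels are correct, and the rule doubles as a speed shortcut.
2. both values in `(0.4, 0.9)` — tissue iff `β₁·Fv_SRLF·Fv_PSWV·P > 0.5`.
3. `Fv_SRLF ≤ 0.4` — tissue iff `β₂·Fv_SRLF·P > 0.5`.
4. `Fv_PSWV ≤ 0.4` — tissue iff `β₃·Fv_PSWV·P > 0.5`.

The four conditions neither partition the unit square nor exclude each other
(e.g. `Fv_PSWV = 0.9` exactly with mid-range `Fv_SRLF` matches none; two low
values match both 3 and 4). The package resolves this deterministically:
branches are evaluated in the printed order, and any residual combination
falls through to branch 2's joint-product rule. This makes the decision a
total function on `[0,1]²`, verified exhaustively against an independent
transcription in the acceptance suite.

`P` is monotone in each branch, so raising a bin probability can only add
tissue voxels — a useful sanity property that the tests assert.

## Tissue greyscale range and probability training

All intensities are min–max normalized to `[0, 1]` (over a brain mask when
given, otherwise over the nonzero foreground; a volume already spanning
exactly `[0, 1]` passes through unchanged, which makes the maskless path
idempotent). The histogram of the masked target is built on `N = 20`
equal-width bins (half-open, last bin closed). Peaks are strict local maxima
carrying at least 1% of the mask (plateaus and edge bins never qualify; the
mass filter suppresses noise maxima). If 2 or 3 peaks are found the range is
accepted; a single peak (or none) doubles the bin count, more than three
halves it, with at most 4 rounds and a closest-to-2-peaks fallback. The
"value" of the highest peak bin is its upper edge — the serial-number-to-value
mapping is a package choice; the upper edge keeps the resulting ranges
plausible for bright deep-grey structures. The tissue range is then
`[upper − span, upper]` with `upper = value(ISNmax) + offset`, clipped to
`[0, 1]`, using per-tissue spans (thalamus 0.6, others 0.5) and offsets
(+0.15, 0, 0, +0.1, +0.15, −0.05 for thalamus, hippocampus, caudate,
putamen, pallidum, amygdala). The offset is treated as an intensity (not a
bin-count) quantity, consistent with spans being intensity spans.

`P` lives on the histogram bins; bins outside the tissue range are pinned to
zero — by construction the tissue cannot live there, and branch 1 still
recovers out-of-range voxels with overwhelming atlas support. A bin is "in
range" when its interval overlaps the tissue range with positive length.

Training maximizes `‖Dsc‖₁`, the summed Dice of a leave-one-out protocol:
each training atlas in turn becomes a pseudo-target, is segmented by the full
model from the remaining atlases, and scored against its own label image.
Because every branch thresholds a product, the objective is piecewise
constant in `P` — gradients are useless — so the optimizer is a deterministic
coordinate ascent over a finite probability grid (default `{0, 0.1, …, 1}`),
initialized at 0.5, sweeping bins in fixed order until a sweep changes
nothing (at most 5 sweeps), ties resolved toward the smaller value (a flat
bin therefore falls to 0, claiming nothing). The fusion values do not depend
on `P`, so they are computed once per pseudo-target and cached; every
objective evaluation is then a cheap rethresholding. On problems small enough
to enumerate, the ascent attains the exhaustive-search maximum (asserted in
the acceptance suite).

The greyscale model used in training is normally built from the *target*
image's histogram (the range is a property of the image to be segmented);
`train_p()` falls back to the pooled training intensities when no model is
supplied.

## Patch selection and sparse coding

Atlas slices participate in a voxel's fusion when their axial position lies
within `SR = 3` mm of the voxel's slice (closed interval), mirroring how
slice-position-based atlas selection trades accuracy against registration
cost. One candidate patch is taken per selected atlas slice at the same
in-plane coordinate — the registration being emulated is assumed good enough
that no non-local search is needed. Patches default to `7×7×3` voxels
(in-plane larger than through-plane, matching 1.5 mm anisotropic slices;
the extent is configurable because no canonical value exists), are vectorized
in fixed raster order, replicate edges at volume borders, and the `K = 60`
highest-NCC candidates are retained for both fusion routes.

The sparse coder approximates `min ‖α‖₀ s.t. ‖PT − D α‖₂ ≤ ε` greedily. Two
numerical choices matter:

* **Atom selection by residual gain.** Instead of picking the atom most
  correlated with the residual, each step picks the atom whose least-squares
  refit shrinks the residual the most; projecting the candidate columns off
  the current support gives this in closed form at the same asymptotic cost.
  Correlation picking is measurably weaker at small dictionary sizes.
* **First-atom branching.** The first pick dominates greedy quality, so the
  `branch = 8` most promising first atoms are each completed and the best
  solution wins (ties prefer the higher-ranked atom). For supports of at most
  two atoms and dictionaries of at most `branch` columns this is exhaustive
  over atom pairs, which is what the oracle tests exercise.

`ε` defaults to the relative rule `0.01·‖PT‖₂` (the tolerance is not a
physical quantity; a relative rule adapts it to patch contrast), the support
is capped at 5 atoms, and negative coefficients carry no vote mass. An
optional nonnegative mode restricts the pursuit to positively correlated
atoms with clip-and-refit. A zero target patch returns the zero solution.

## Whole-volume segmentation and the speed path

For every voxel the engine gathers the candidate centre labels first. When
all of them are background, both fusion values are exactly zero — the vote
numerator vanishes for any weights — and every branch of the decision yields
0, so these voxels are skipped without patch extraction or sparse coding.
Unlike a shortcut keyed on the voxel's intensity alone, this skip cannot
disturb branch 1 and is therefore *provably* bit-identical to exhaustive
per-voxel evaluation (asserted on the full fixture in the acceptance suite).
On background-dominated volumes it removes over 90% of the work.

## The synthetic world

`make_phantom()` builds a piecewise-constant head: by default a 48×48×12
voxel block at 1×1×1.5 mm (an IBSR-like axial slab at desk scale) holding a
brain ellipsoid (intensity 0.35), a deep white-matter-like ellipsoid (0.55)
and a bright target nucleus (0.8, ~360 voxels), with Gaussian noise
(σ = 0.03) inside the head and min–max normalization over it. The three
levels are separated by well over `2σ`, so the histogram machinery sees 2–3
peaks at the default binning — the regime the range-setting rules expect.

`make_warped_atlases()` emulates residual registration error: per atlas, a
white-noise displacement field is Gaussian-smoothed (scale 3 voxels) and
rescaled to a per-axis standard deviation of 1 voxel — a realistic residual
for a competent non-linear registration — then intensity (trilinear) and
label (nearest-neighbour) are warped with the *same* field, followed by a
linear intensity jitter (scale ±10%, shift ±0.05) standing in for
non-standardized MR intensities. Six atlases form the default fixture. All
generation is deterministic per seed with a private RNG stream.

What the generator does *not* emulate: anatomy (no template shapes), MR
physics (no bias field, partial-volume model or Rician noise), and true
registration failure modes (topology changes, large misregistration). A green
end-to-end test therefore establishes that the fusion machinery orders the
methods correctly under controlled distortion — not that the package
reproduces any particular accuracy on clinical data, which additionally
requires real registration output.

## Degenerate inputs and conventions

* Constant in-mask intensities: normalization refuses (degenerate range).
* Empty candidate slice set (search radius smaller than the slice spacing):
  slice-selection errors and asks for a wider radius.
* All vote weights zero: the fusion value is 0 — no atlas evidence means
  background.
* Empty sets in metrics: Dice of two empty sets is 1; recall, precision and
  Hausdorff with an empty reference/segmentation are reported as missing
  (`NA`), never silently 0, so averages stay unbiased. Hausdorff distances
  are physical (mm) via the voxel spacing, with a voxel-unit mode.
* Label images with other structure codes: `binarize_label()` selects one
  code; the mapping lives in configuration, not code.

## Known limitations

* One β per tissue: per-target adaptive β (matching fusion-value statistics
  of the individual image) is out of scope.
* Single-structure (binary) fusion only; no simultaneous multi-label model.
* The per-bin probability is a step function; no smoothing across bins.
* Registration is consumed, never performed.
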