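---
title: "Detecting ischemic scar from LV anatomy: models and methods"
author: "lvscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ischemic scar from LV anatomy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ischemic scar — fibrotic myocardium left behind by infarction — is imaged
reliably only by late-gadolinium-enhancement (LGE) MRI. Computed tomography
angiography (CTA) resolves cardiac *anatomy* well but offers little direct
scar contrast. Scar, however, remodels anatomy: infarcted walls thin
locally. `lvscar` implements a pipeline that detects scar per short-axis
slice from anatomy alone, so that the same classifier can read either
modality once both are reduced to a common, intensity-free representation:
a binary myocardium mask.

The pipeline is: 3D epicardial/endocardial surface meshes → PCA long axis →
25 short-axis slice planes → 256×256 binary myocardium masks at 1 mm/pixel
→ polar re-encoding about the blood-pool centroid → VGG-style CNN trained
with focal loss under patient-wise balanced cross-validation. Ground truth
for a second modality is established by rigid ICP registration of paired
meshes and transfer of the scar sub-mesh.

## Geometry

**Axes.** The long axis is the first principal component of the epicardial
vertex cloud. PCA leaves the sign free; the base end is chosen as the side
nearer the valve annulus markers when present, otherwise as the side with
the wider endocardial cross-section (mean radial distance of endocardial
vertices within the outer 20% of the axis — a monotone proxy for cavity
area that avoids a full contour computation). Exactly symmetric vertex
clouds (numerically degenerate PCA) fall back to a deterministic
eigenvector ordering with a warning; rank-deficient clouds are an error.

**Slicing.** 25 planes normal to the long axis, evenly spaced from 20% of
the apex-to-base length up to the base, both endpoints included (a
`linspace` convention; the endpoint choice is ours). Plane/mesh
intersection computes one point per crossing mesh edge and chains segments
by exact edge identity, so contour closure does not depend on
floating-point point matching. A plane is "valve-contaminated" when it
passes within 2 mm (configurable) of a valve marker along the axis, or
when the epicardial intersection is not a single simple closed curve.

**Rasterization.** A pixel center is myocardium iff it is inside the
epicardial contour(s) and outside every endocardial contour under the
even-odd rule, sampled at pixel centers with the epicardial area centroid
mapped to the grid center. A center exactly on a contour counts as
myocardium (the epicardial test is boundary-inclusive, the endocardial
cavity test is strict-interior); pixel centers lying on exactly horizontal
contour segments are the one case outside this guarantee, and are resolved
by the crossing rule. The fill is a scanline even-odd sweep, which makes
it deterministic and fast.

**Exclusion rules.** A slice is dropped when its contours self-intersect
(segment-pair crossing test), when it hits a valve, or when it has fewer
than 50 foreground pixels (strict `< 50`). "Under 50 pixels in total
volume" is read as the myocardium-foreground pixel count of the slice
mask; counting myocardium + cavity would only change behaviour for slices
that are already degenerate. The three checks are order-independent; the
reported reason follows a fixed priority (self-intersection, valve, size).

**Labels.** A slice is scar-positive iff its plane geometrically
intersects the closed scar sub-mesh — for a closed surface, exactly when
the signed vertex distances to the plane span zero.

## Polar encoding

Masks are resampled to polar coordinates about the blood-pool centroid:
rows are radius (1 mm per row, radius 0 at row 1), columns are angle
(360/256° per column), nearest-neighbor sampling to keep the mask binary
(bilinear would introduce gray levels the network input does not have).
The blood pool is the background region fully enclosed by the myocardium
(hole-filling); apical cap discs without a cavity fall back to the
foreground centroid with a warning. Rows beyond the sampled radial extent
are zero-padded at the large-radius end — we read "padded at the base" as
the outer-radius end of the radial axis, which is the reading consistent
with the stated rationale (compensating for centroids near the image
edge). The angular origin is along +x of the mask frame, counter-clockwise;
no anatomical landmark anchors the angle, which is why rotation
augmentation (below) is principled.

Two geometric facts about this encoding matter for testing: (i) an
in-plane rotation of the mask is exactly a circular column shift of the
polar image; (ii) the unwrapping preserves area only near the radius where
the circumference equals the column count (256/2π ≈ 41 mm) — foreground
counts are inflated inside that radius and deflated outside it.

## The classifier

**Focal loss.** `FL(p_t) = -α (1 − p_t)^γ log(p_t)`, with `p_t` the
probability assigned to the true class, γ ≥ 0 the focusing parameter and α
a loss weight. The formula is implemented exactly as printed, with α a
flat multiplier on every sample (not the per-class `α / 1−α` convention
some focal-loss variants use). Probabilities are clamped at 1e-7 before
the logarithm. Defaults are the swarm-tuned values γ = 1.560, α = 0.6,
learning rate 0.009, momentum 0.73, batch size 10; 100 epochs per
cross-validation fold and 500 epochs for the final full-data retrain.

**Architecture.** The engine is a from-scratch float32 CNN (im2col + BLAS
convolutions, 2×2 max pooling, SGD with momentum) living in the package's
C++ code. Two topologies are provided. `vgg16` is the full 13-convolution
VGG16 stack adapted to 1-channel 256×256 input with a 4096–4096–1 head; at
CPU scale it exists for completeness and parameter-count comparisons.
`vgg_small`, the default, preserves the VGG idiom (3×3 convolutions,
width doubling, pool halving) at a desk-trainable size: a 2×4
(radial×angular) average-pool stem reduces 256×256 to 128×64 — keeping
full-resolution radial information, because wall thickness lives on the
radial axis at the millimetre scale — followed by eight convolutions with
widths (4, 4, 8, 8, 16, 16, 32, 32), pooling after each pair, and a
1024→32→1 sigmoid head (51,277 parameters, against ~166M for the full
`vgg16`).

**Rotation augmentation.** Each training sample receives a random circular
shift of the angular axis per epoch (default on). Scar azimuth is
patient-specific, so without it the network can memorize angular
idiosyncrasies of training patients; in polar coordinates the augmentation
is free (a column rotation) and exact.

**Cross-validation.** Folds are patient-wise: every slice of a patient
stays in one fold. Patients are assigned greedily in decreasing order of
scar-slice count (seeded tie-breaking) to the currently scar-poorest fold,
under a patient-count capacity of ⌈n/k⌉; a warning is raised when any
fold's scar fraction deviates more than 10% (relative) from the global
fraction. Pooled out-of-fold predictions are scored as a single test set;
each slice is predicted exactly once. Calls use a 0.5 threshold with ties
called positive.

**Hyperparameter search.** Global-best particle swarm over learning rate,
momentum, batch size (rounded), γ and α, with standard constants (inertia
0.729, cognitive = social = 1.49445, 20 particles) — a reconstruction, as
the original search's exact constants are not public — and a reduced-epoch
(10) cross-validated accuracy objective to keep each evaluation tractable.

**Baseline.** The minimum-wall-thickness classifier measures, per polar
mask, the minimum over angular columns of the foreground row count, and
thresholds it (threshold chosen to maximize training accuracy). It is the
natural anatomical-measurement comparator for the CNN and is expected to
be strong on synthetic data, where thinning *is* the generative signal.

## Registration and label transfer

Paired meshes of the same patient from two modalities are aligned by a
full rigid transform: initialization rotates the source long axis onto the
target's, resolves the roll about the axis from the first valve marker,
and translates apex onto apex; point-to-point ICP on the epicardial
vertices then alternates closest-point correspondence (on a deterministic
600-vertex subsample) with Kabsch/SVD estimation until the mean
closest-point distance changes by less than 1e-4 mm or 200 iterations.
Although the original description speaks of a "registration translation",
the axis/valve initialization implies rotational alignment, so the full
rigid transform is estimated (a translation-only mode would be a strict
subset). The scar sub-mesh is mapped through the result, and target slices
are labeled against the transferred scar exactly as native slices are.

## The synthetic cohort

Real paired MRI/CTA meshes are restricted data, so the package ships a
seeded generator that emulates segmentation-tool output:

* **Base shape**: a truncated prolate spheroid (truncation at a 105° polar
  angle), apex-to-base length drawn from 75–95 mm, equatorial-to-axial
  ratio 0.50–0.60, remote wall thickness 8–12 mm — typical adult LV
  dimensions. Smooth low-order angular harmonics (relative amplitude 0.02)
  perturb the surface; wall thickness carries its own ±few-percent smooth
  field.
* **Scar**: a contiguous patch (default 80° × 0.35 of the length, centered
  at 45% apex→base at a random azimuth) where thickness is multiplied by
  the thinning factor (default 0.5), with a raised-cosine taper over the
  outer 30% of each half-extent; a closed "pillow" scar sub-mesh fills the
  patch mid-wall (30–70% depth). Slices in the taper carry scar labels with
  little thinning — deliberate hard cases mimicking minimally remodeled
  scar; thinning factors near 1 make the task arbitrarily hard.
* **Pairing**: the "CTA-like" mesh reuses the patient's anatomy with an
  independent perturbation draw, a global volume rescale whose signed
  relative change δ is drawn so that E|δ| matches the configured 0.19
  (δ ~ N(0, 0.19·√(π/2)), clamped at ±0.45), and a random rigid
  displacement (5–20° rotation, ±10 mm translation) for registration to
  undo. Blood-volume bookkeeping is exact because rigid motion preserves
  mesh volume.

What the generator does **not** emulate: real segmentation noise and
topology defects, papillary muscles and trabeculation, non-ischemic
remodeling (e.g. hypertrophic phenotypes), scar without thinning, and
inter-modality differences concentrated at the aortic root. Passing
end-to-end tests on this cohort therefore demonstrates that the pipeline's
machinery recovers a thinning-mediated scar signal at realistic geometry
and label noise — not clinical-grade performance on real scans.

## Numerical choices and degenerate inputs

* Vertices exactly on a slice plane are perturbed by 1e-9 mm before
  intersection, so every crossing triangle has exactly two crossing edges.
* Contour chaining is by integer edge identity (cycles in the
  edge-adjacency graph), immune to coordinate rounding.
* Maxpool ties take the first maximum in scan order; fill-rule and
  threshold ties are documented above ("on the contour" = inside;
  probability exactly at threshold = positive call).
* Training runs entirely in float32 with a dedicated deterministic RNG for
  shuffling and augmentation; two runs from one seed are bit-identical on
  the same BLAS. Batch composition can perturb predictions in the last
  float bits, so equality across permuted prediction batches is asserted
  only to 1e-6.
* Empty masks, cavity-free discs, planes that miss the mesh, single-class
  training sets, rank-deficient PCA and unanimous rating matrices all have
  defined behaviour (fallback, exclusion or explicit error) exercised by
  tests.

## Problem sizes in the shipped tests

The end-to-end experiment used by the test-suite and the acceptance script
is a 60-patient cohort (50% prevalence, ~1370 retained slices), 5-fold
cross-validation at 30 epochs per fold with the tuned hyperparameters —
sizes chosen so the whole suite completes in well under half an hour on a
single CPU core while still giving ~270 slices per held-out fold. The
100/500-epoch protocol remains the package default for real use
(`train_config()` and `default_config()$classifier`). On the synthetic
cohort the 30-epoch budget is already past the loss plateau.

## Known limitations

* The anatomical signal is wall thinning; scar with minimal remodeling is
  invisible by construction (thinning factors near 1 drive AUC toward
  chance), matching the method's stated failure mode on real data.
* Scar burden/transmurality estimation and AHA-segment localization are
  out of scope.
* ICP here is rigid; true MRI/CTA anatomical differences beyond a rigid
  motion end up as ground-truth label noise, which is also how the
  original pairing behaves.
* `vgg16` at 256×256 is provided but not desk-trainable; all quantitative
  claims in the tests use `vgg_small`.
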