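# lvscar

Anatomy-based detection of ischemic myocardial scar in left-ventricular
(LV) short-axis slices.

Ischemic scar is reliably visible only in late-gadolinium-enhancement
(LGE) MRI; CT angiography shows anatomy but almost no scar contrast. Scar,
however, thins the wall it replaces. `lvscar` re-implements an
anatomy-only detection pipeline: 3D LV surface meshes (from any modality's
segmentation) are reduced to binary myocardium masks per short-axis slice,
re-encoded in polar coordinates, and classified per slice by a VGG-style
convolutional network trained with focal loss — so a network trained on
MRI-derived masks can read CTA-derived masks unchanged.

The pipeline, per patient:

1. **Axes** — long axis via PCA of the epicardial vertices, oriented
   apex→base by the valve markers (`compute_axes`).
2. **Slicing** — 25 planes from 20% of the apex–base length to the base;
   plane/mesh intersection to closed contours (`slice_mesh`).
3. **Masks** — 256×256 binary myocardium rasters at 1 mm/pixel, even-odd
   fill (`rasterize_slice`); slices excluded if self-intersecting, valve-
   contaminated, or under 50 foreground pixels (`filter_slice`).
4. **Polar encoding** — resampling about the blood-pool centroid, 1 mm
   radial × 360/256° angular (`to_polar`, `pad_polar`).
5. **Classification** — CNN trained with the focal loss
   `FL(p_t) = -α (1-p_t)^γ log(p_t)` (tuned γ = 1.560, α = 0.6, SGD with
   learning rate 0.009, momentum 0.73, batch 10) under 10-fold
   patient-wise, scar-balanced cross-validation (`scar_cnn`,
   `cross_validate`, `make_folds`).
6. **Cross-modality ground truth** — rigid ICP registration of paired
   meshes and scar-mesh transfer (`icp_register`, `transfer_scar`),
   orchestrated with a train/test leakage guard (`run_test_flow`).

Because the clinical MRI/CTA meshes behind the original study are
restricted, the package ships a seeded synthetic cohort generator
(`generate_cohort`): truncated prolate-spheroid LV shells with realistic
dimensions, scar modeled as a tapered wall-thinning patch with a closed
mid-wall scar sub-mesh, paired "second-modality" meshes with a ±19% mean
blood-volume perturbation and a random rigid displacement. Everything
downstream is exercised end-to-end on these cohorts. Supporting tools: a
minimum-wall-thickness baseline classifier (`thickness_baseline`),
particle-swarm hyperparameter tuning (`tune_hyperparameters`), and an
evaluation suite — accuracy, ROC/AUC with bootstrap confidence intervals,
sensitivity/specificity, Fleiss' kappa, apex/mid/base rollup.

## Worked example

Sixty synthetic patients, half with scar (thinning factor 0.5), 5-fold
patient-wise cross-validation at 30 epochs per fold (a reduced budget that
is already past the loss plateau on synthetic data; the clinical protocol
defaults are 100 epochs per fold and a 500-epoch final retrain):

```r
library(lvscar)

cohort  <- generate_cohort(cohort_spec(n_patients = 60, seed = 101))
dataset <- cohort_to_dataset(cohort, "mri", "native")
print(dataset)
#> slice dataset: 1500 slices from 60 patients (1377 valid, 363 scar among valid)

cv <- cross_validate(dataset, train_config(epochs = 30), k = 5, seed = 1)
print(cv)
#> 5-fold patient-wise cross-validation (vgg_small):
#> evaluation on 1377 slices (363 scar):
#>   accuracy    0.895
#>   AUC         0.922  [0.907, 0.938] (bootstrap 95%)
#>   sensitivity 0.702
#>   specificity 0.964
```

2806-style bookkeeping: of 1500 candidate slices, 1377 survive the
exclusion rules (the rest hit valves, fall below 50 pixels, or
self-intersect), and 26% of retained slices carry scar. The model then
reads the paired, volume-perturbed "CTA-like" meshes it never saw, with
ground truth transferred by ICP registration:

```r
model <- scar_cnn(dataset, train_config(epochs = 30), seed = 1)
test  <- run_test_flow(model, cohort,
                       train_fingerprints = unlist(lvscar:::cohort_fingerprints(cohort, "mri")))
print(test)
#> independent test flow (transferred-label agreement 95.7%):
#> evaluation on 1366 slices (363 scar):
#>   accuracy    0.890
#>   AUC         0.915  [0.897, 0.930] (bootstrap 95%)
#>   sensitivity 0.700
#>   specificity 0.959
```

Accuracy drops by half a point across modalities — the polar anatomical
encoding is doing its job. The minimum-wall-thickness baseline on the same
slices reaches AUC 0.906, below the CNN's 0.922: the network uses more of
the mask than its thinnest column. (Runtime: about ten minutes on one CPU
core for the full example.)

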