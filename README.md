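# muscleshape

Shape-aware post-processing of multi-label 3D muscle segmentations.

Automatic segmenters of lower-limb muscles in MRI reach good overlap with
manual references (Dice ≈ 0.8) but leave two characteristic local errors:
*blank regions* (voxels inside a muscle left unlabelled) and
*mis-segmentation* (voxels assigned to the wrong muscle, or spurious islands
off the muscle). Both inflate the worst-case and average surface distances
far more than they dent the Dice coefficient, and both defeat generic
post-processors that only look at the label map.

`muscleshape` post-processes a predicted label volume with an anatomical
prior: for each muscle it learns a statistical shape model (SSM) from
reference segmentations and **replaces the prediction by the model's mean
shape**, rigidly aligned by iterative closest point and then deformably
registered onto the prediction by a nodal-grid free-form deformation. The
output is a deformed copy of the mean shape, so interior holes and detached
islands are impossible by construction.

The SSM is built from entropy-optimized correspondence particles: particle
sets `x_k ∈ R^{3m}` constrained to each training surface minimize

    Q = H(Z) − Σ_k H(x_k)

(`H(Z)`: Gaussian-model entropy of the ensemble in shape space, compacted;
`H(x_k)`: Parzen entropy of each particle set on its surface, maximized for
uniform coverage), followed by PCA with at most N−1 modes. The deformable
step minimizes the sum of squared differences between Gaussian-smoothed
masks plus `λ · Σ ‖Δu‖²` on a hexahedral node grid with nodal spacing
NS = 5 voxels and trilinear densification; `λ = "auto"` picks the smallest
fold-free candidate (strictly positive Jacobian everywhere).

Also included, for controlled comparisons:

* the classical slice-wise **2D morphological pipeline** (erode r=3 disk →
  keep largest 8-connected component → dilate → fill holes → 5×5 uniform
  smoothing at threshold 0.5),
* a fully connected **CRF** with Gaussian appearance/smoothness kernels
  (W1 = θα = θβ = 10, W2 = θγ = 1) and exact O(n²) mean-field inference,
* the four standard metrics — **DSC**, signed relative volume error
  (**RVE**), Hausdorff distance (**HD**), average symmetric surface
  distance (**ASSD**) — per label and pooled, plus an exact paired
  **Wilcoxon signed-rank** test,
* a seeded generator of elongated, muscle-like 3D **phantom families** and
  corrupted "predictions" reproducing the error taxonomy above, so the
  whole pipeline is testable without any clinical data.

## Worked example

```r
library(muscleshape)

# a 10-subject training family of tube-like shapes, and its shape model
fam  <- generate_shape_family(phantom_spec(n_subjects = 10, seed = 0))
bank <- build_model_bank(list(fam), particles = 256, seed = 0,
                         iterations = 30)

# an unseen subject, corrupted the way segmenters fail
spt  <- phantom_spec(n_subjects = 1, seed = 2001)
gt   <- label_volume(array(as.integer(generate_shape_family(spt)[[1]]$grid),
                           spt$shape))
pred <- corrupt_prediction(gt, corruption_spec(seed = 1))

gtm <- extract_label_mask(gt, 1)
pm  <- extract_label_mask(pred, 1)
out <- ms_postprocess_label(pm, bank$entries[["1"]]$mean_mask,
                            ns = 5, lambda = "auto")

round(c(dsc_pred = dsc(gtm, pm),   dsc_ms = dsc(gtm, out),
        hd_pred  = hausdorff(gtm, pm), hd_ms = hausdorff(gtm, out),
        assd_pred = assd(gtm, pm), assd_ms = assd(gtm, out)), 3)
#> dsc_pred    dsc_ms   hd_pred     hd_ms assd_pred   assd_ms
#>    0.788     0.915     7.071     3.000     1.189     0.589
```

The corrupted prediction overlaps the truth at Dice 0.79 with a worst-case
surface error of 7.1 mm; the registered mean shape raises Dice to 0.92 and
more than halves both surface distances — holes are gone because the warped
mean cannot have any. `ms_postprocess_volume()` does the same per label and
recomposes a multi-label volume; `run_experiment()` reproduces the full
paired comparison (raw vs 2D vs CRF vs mean shape, Wilcoxon-tested) from a
single seeded config.

A thin command-line front end (`inst/cli/muscleshape`) exposes `simulate`,
`build-ssm`, `register`, `postprocess {ms|2d|crf}`, `evaluate` and
`run-experiment --config cfg.yaml`; all volumes are NIfTI (`.nii/.nii.gz`)
or MetaImage (`.mhd/.mha`).

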