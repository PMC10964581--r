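# hfsnet

Detection and segmentation of hepatocellular carcinoma (HCC) in three-phase
dynamic CT with **HFS-Net**, a three-stage hierarchical fusion of
segmentation networks — plus a synthetic phantom generator and the full
evaluation protocol, so the method can be trained and tested at desk scale
without clinical data.

The package is for researchers in medical image analysis who want a
self-contained, CPU-reproducible implementation of the method: the pipeline,
its five sub-models, the losses, the instance-level detection metrics, and a
controlled synthetic cohort to exercise all of it.

## The method

HCC shows phase-dependent contrast: it hyperenhances in the arterial phase
and washes out (appears hypodense) against the bright liver in the
portal-venous phase. No single network is best for both small and large
lesions, so HFS-Net splits the work:

* **Stage I** — liver segmentation (`f_liver`: portal-venous, 2D DenseU-Net,
  cross entropy + dice loss) and a tumor probability map used solely for
  per-slice size estimation (`f_size`: dynamic 3-channel stack, 2D
  DenseU-Net, focal + dice loss).
* **Stage II** — divide and conquer: each per-slice tumor instance is routed
  by its longest in-plane axis *a* against the demarcation *m* = 30 px
  (≈ 4.2 cm at 1 px = 1.4 mm): *a* ≤ *m* → `f_small` (dynamic, 2D
  DenseU-Net, focal + dice), *a* > *m* → `f_large` (portal-venous, 2D U-Net,
  cross entropy).
* **Stage III** — fusion: the portal-venous image and the four sub-model
  outputs form a 5-channel volume segmented by a 3D U-Net (`f_3d`, focal +
  dice) into the final mask. Skipping this stage and taking the union of the
  branches is the "2d" mode.

Evaluation follows the instance-detection protocol: a predicted component
detects a labeled tumor in a slice when their Dice exceeds θ = 0.2;
sensitivity / precision / F1 = 2SP/(S+P) are aggregated per tumor volume,
per tumor cut, per slice and per patient; segmentation is scored as dice
per case and dice global; tumor size error as the maximum-tumor-diameter
(MTD) mean absolute error in cm; everything stratified by size bin
(< 2, 2–3, 3–5, > 5 cm) and tumor count (1, > 1).

The networks run on a compact deterministic CPU engine built into the
package (compiled im2col + GEMM convolutions, hand-derived backprop, Adam);
see the methods vignette (`vignettes/hfsnet-methods.Rmd`) for every design
decision and the phantom model.

## Worked example

```r
library(hfsnet)

# one synthetic case: a 2 cm and a 4.5 cm lesion in a tiny-profile liver
case <- generate_case(phantom_spec(tumor_diameters_cm = c(2.0, 4.5),
                                   profile = "tiny", seed = 42))
self_check_case(case)
#>   id expected_axis_px measured_axis_px measured_3d_mm axis_ok voxels_outside_liver inside_liver_ok
#> 1  1         14.28571         13.54781       22.67972    TRUE                    0            TRUE
#> 2  2         32.14286         31.89044       44.71655    TRUE                    0            TRUE
```

The 4.5 cm lesion measures 31.9 px — above the 30 px demarcation, so Stage
II routes it to the large-tumor branch; the 2 cm lesion (13.5 px) goes to
the small-tumor branch. Train the full pipeline on a small cohort and
evaluate held-out cases:

```r
coh    <- generate_cohort(16, seed = 411)
split  <- split_cases(16, seed = 7)                    # 9 / 3 / 4 cases
models <- train_hfsnet(coh$cases, split, epochs_2d = 5, epochs_3d = 5,
                       seed = 99, verbose = TRUE)
#> f_liver: val dice 0.994
#> f_size: val dice 0.975
#> f_large: val dice 0.938
#> f_small: val dice 0.766
#> f_3d: val dice 0.965

preds <- lapply(coh$cases[split$test],
                function(cs) run_hfsnet(cs, models, mode = "3d")$final_mask)
refs  <- lapply(coh$cases[split$test], `[[`, "tumor_labels")
evaluate_cases(preds, refs, spacing_mm = 1.4, theta = 0.2)
#> HFS-Net metrics report (theta = 0.2 )
#>   n=4  dice per case 96.8%  dice global 97.5%  MTD MAE 0.02 cm
#>   per_tumor_volume  S 95.5%  P 100.0%  F1 97.7%
#>   per_tumor_cut     S 92.5%  P 100.0%  F1 96.1%
#>   per_slice         S 95.5%  P 100.0%  F1 97.7%
#>   per_patient       S 100.0%  P 100.0%  F1 100.0%
```

On this easy piecewise-constant phantom the fused 3D mode reaches dice
global 0.975 on held-out cases versus 0.963 for the 2D (hierarchical-only)
mode — the fusion stage reconciles the branches and suppresses false
positives (a tumor-free phantom comes back with an empty mask). A command-line front end for the same operations
(`generate-phantoms`, `train`, `predict`, `evaluate`) is in
`inst/cli/hfsnet.R`.

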