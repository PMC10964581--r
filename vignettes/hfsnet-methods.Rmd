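---
title: "HFS-Net: a hierarchical fusion strategy for liver tumor segmentation in dynamic CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HFS-Net: a hierarchical fusion strategy for liver tumor segmentation in dynamic CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Hepatocellular carcinoma (HCC) is read on dynamic (three-phase) CT:
a non-contrast scan, an arterial phase in which HCC typically
hyperenhances, and a portal-venous phase in which it washes out against the
maximally enhanced liver parenchyma. A single segmentation network trades
off small-lesion sensitivity against large-lesion boundary accuracy:
dynamic-phase models with dense feature reuse do better on small tumors,
while a plain U-Net on the portal-venous phase — where large HCC has its
clearest edges — does better on large ones.

HFS-Net resolves that trade-off in three stages:

1. **Stage I — segmentation and size estimation.** A 2D DenseU-Net on the
   portal-venous phase segments the liver (`f_liver`); a 2D DenseU-Net on
   the three-channel dynamic stack produces a per-slice tumor probability
   map (`f_size`) whose only role is to estimate, per slice, each tumor
   instance's longest in-plane axis.
2. **Stage II — divide and conquer.** Each per-slice connected component of
   the Stage-I tumor map is routed by its longest axis: components with
   axis ≤ *m* pixels go to the small-tumor branch (`f_small`, dynamic
   input, DenseU-Net, focal + dice loss), components with axis > *m* to the
   large-tumor branch (`f_large`, portal-venous input, U-Net, cross
   entropy). The demarcation is *m* = 30 px, about 4.2 cm at the working
   scale of 1 pixel = 1.4 mm. The tie (axis exactly 30 px) goes to the
   small branch. A slice containing both kinds of instance is fed to both
   branches; the fusion stage reconciles them.
3. **Stage III — 3D fusion.** The portal-venous image and the four
   sub-model probability maps are stacked into a 5-channel volume (fixed
   order: image, liver, size, large, small — recorded on the array so a
   silent permutation is detectable) and a 3D U-Net produces the final
   volumetric tumor probability. Running only stages I–II and taking the
   union of the branch outputs is the "2D" mode; the full pipeline is the
   "3D" mode.

The final mask is binarized at 0.5, gated to the predicted liver (lesions
are intrahepatic by construction), and components smaller than 3 voxels
(26-connectivity) are discarded as speckle.

## Evaluation protocol

Segmentation is scored by the Dice coefficient, reported two ways: *dice
per case* (unweighted mean of case-level Dice) and *dice global* (voxel
sets pooled over cases, so large cases dominate). Detection works at the
instance level: in every slice, predicted components (8-connectivity) are
matched one-to-one to reference tumor cross-sections, greedily by
descending pairwise Dice; a tumor is detected in a slice when its match
exceeds θ = 0.2 — a significant but not exact overlap. Unmatched
predictions are false positives; undetected tumors false negatives.
Sensitivity/precision/F1 are aggregated at four granularities: *per tumor
volume* (all per-slice instances pooled), *per tumor cut* (per-case rates
averaged), *per slice* (a tumor-bearing slice counts when ≥ 1 of its
tumors is found), and *per patient* (same rule per case). The maximum
tumor diameter (MTD) of a case is the largest per-slice longest axis over
all its instances, in cm; MTD MAE is the mean absolute prediction error.
Reports are stratified by reference MTD (< 2, 2–3, 3–5, > 5 cm; bins
left-closed, so an MTD of exactly 2.0 cm falls in 2–3) and by tumor count
(1 vs > 1). Per-slice precision counts false-positive components on
tumor-free slices as well (config-switchable). Empty-vs-empty Dice is
defined as 1; this only affects tumor-free comparisons.

All of these are cross-checked in the test suite against brute-force
oracles (exhaustive voxel counting, exhaustive matching, all-pairs
distances) on dozens of random labelings, to 1e-9.

## The phantom generator

The study conditions this package emulates are: aligned three-phase stacks
at 1.4 mm/pixel in-plane, a liver region, 1–10 lesions per case, a
four-bin case-size mixture with probabilities 93/595, 133/595, 178/595,
191/595 (≈ 15.6 / 22.4 / 29.9 / 32.1 %), 84 % single-tumor cases, and the
classic enhancement pattern (arterial lesion > liver, portal-venous
lesion < liver). The bins are read as *per-case* sizes — the four bin
counts sum to the cohort size — so each case's primary tumor draws its bin
from the mixture and a diameter uniform within the bin; additional lesions
in multi-tumor cases are satellites from the < 2 cm bin, which matches how
multifocal HCC typically presents and keeps placement geometrically
feasible in the bounded liver.

Lesions are spheroids: the major axis lies in-plane and equals the
requested maximum diameter (the in-plane minor axis is 0.85–1× that, the
z semi-axis 0.6–0.9×, mildly oblate given 2.5 mm slices), with an optional
low-amplitude radial perturbation (off by default so the diameter stays
exactly controllable; the generated mask reproduces the requested axis to
within one in-plane voxel, and `self_check_case()` re-measures every
instance). Intensities are piecewise-constant compartment means per phase
(HU-like; background 20/30/40, liver 55/70/110, lesion 45/110/80 for
non-contrast/arterial/portal-venous), Gaussian-smoothed in-plane
(σ = 0.7 px) to mimic partial volume, plus additive Gaussian noise
(SD 10). The source cohort publishes no intensity statistics, so these
defaults are chosen for plausibility — contrast in the direction and
rough magnitude a radiologist would expect — not fidelity.

Two geometry profiles exist: `default` (64 × 256 × 256 at
(2.5, 1.4, 1.4) mm, bins up to 8 cm) and `tiny` (32 × 64 × 64, top bin
capped at 5.5 cm so the lesion fits the smaller liver), the CPU test
profile. Phase misalignment is off by default — the emulated pipeline
aligns phases before modelling — but `align_phases()` implements
nearest-Z matching with a half-slice-gap tolerance for data that needs it.
What phantoms deliberately do not model: breathing artifacts, vessels,
lesion heterogeneity and infiltrative margins, other lesion etiologies.
Passing the recovery tests therefore shows the pipeline's plumbing,
routing and fusion logic work end to end — not clinical-grade accuracy.

## Networks, losses, training

No deep-learning framework is part of this package's dependency stack;
the networks run on a compact, fully deterministic CPU engine written for
this package (im2col + GEMM convolutions with compiled kernels,
hand-derived backward passes, Adam). Three architectures are provided in
their canonical forms: a 4-level-style 2D U-Net (configurable depth), a 2D
DenseU-Net whose blocks are dense blocks with concatenative
tightly-connected paths (growth rate 8, two layers per block by default;
growth 0 degenerates to a plain encoder-decoder, which the tests verify
still learns), and a 3D U-Net applied to fixed-depth Z patches (default 8
slices, stride 4, overlap averaged) to bound memory. The layer-level
details of the original nets are not published; the canonical published
forms are used. Weight initialization is He-scaled and seeded;
single-threaded training makes runs bit-reproducible.

Losses: cross entropy, soft-dice (smoothing 1 in numerator and
denominator), focal loss (γ = 2, the original formulation's default), and
median-frequency-balance weights `median(f)/f_c` applicable to either
focal or plain cross entropy — the published description is ambiguous on
which, so the weights are a parameter of both. Compound losses such as
`"ce+dice"` use unit term weights, as the published "A + B" notation
gives no coefficients. Probabilities are clamped to `[1e-7, 1 − 1e-7]`.

`f_size` and `f_small` share a strategy but are trained as two
independent models (a shared-weights option would be a config change),
because the pipeline lists them as separate functions. Training samples
are per-slice: `f_size`/`f_small` use 32-px crops centered near
foreground — without this, per-sample updates on 64-px slices collapse to
all-background under the ~1 % foreground fraction — while `f_liver` and
`f_large` train on full slices, where their targets occupy a large,
roughly balanced fraction. Gradients are clipped at global norm 5.
Validation always uses full slices; the best-validation epoch is kept and
training stops early after 3 stalled epochs. Splits are a seeded
case-level shuffle at 5:2:3 (train:validation:test), rounding in favor of
training.

## Problem sizes and numerical choices

The shipped experiments use the tiny profile: cohorts of 16 cases
(9/3/4 split), five epochs per sub-model, and 8 × 32 × 32-px fusion
patches — sizes chosen so the whole pipeline trains in a few minutes on
one CPU while still containing small (< 30 px) and large (> 30 px)
instances, multi-tumor cases and tumor-free slices. On held-out phantom
cases this configuration reaches dice global above 0.9 and per-patient
sensitivity 1.0, and the 3D mode matches or beats the 2D mode; the
acceptance script recomputes those numbers at run time.

Degenerate inputs are defined, not special-cased: empty pixel sets are an
error for `longest_axis_px` (a single pixel has axis 0); a slice with no
routed component leaves both branch outputs zero; a cohort with no
multi-tumor cases reports an empty `>1` stratum rather than erroring; a
reference case without tumors is an error for MTD MAE. Binarization is at
0.5 everywhere; ties in greedy matching resolve to the first maximum in
scan order. Stage-III fusion consumes probabilities rather than binary
masks (config-switchable by thresholding the inputs) — probabilities
preserve the sub-models' confidence for the fusion net to weigh.

## Known limitations

The phantom's piecewise-constant intensity model makes the segmentation
task easier than clinical CT; recovery scores here do not transfer to
patient data. DICOM series input is out of scope (convert to NIfTI);
there is no inter-phase registration beyond Z-coordinate matching, no
handling of post-treatment change, extrahepatic disease or vascular
invasion, and no surface-distance metrics. The ablation grid covers the
two architectures and phases the final model uses, not the wider families
evaluated only during the original model selection.
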