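---
title: "Methods: thin-slice CT synthesis from two orthogonal thick-slice series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thin-slice CT synthesis from two orthogonal thick-slice series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsr)
```

## The problem

Most archived chest CT studies keep only thick (5 mm) reconstructions: an
axial series and a coronal series. Thin (1–1.25 mm) axial reconstructions,
which clinicians need for multi-planar reformatting, nodule characterisation
and longitudinal research, are usually discarded. `ctsr` implements a
two-stage recovery: the two orthogonal thick series are fused into one
registered low-resolution (LR) 3D volume on the thin-axial grid, and a
plane-selective convolutional super-resolution (SR) network synthesises the
thin-slice detail. Because the axial series is sharp in-plane (x, y) and the
coronal series is sharp in (x, z), the fused volume is blurred *least* along
sagittal sections — which is why SR applied to the sagittal plane is the
configuration of interest.

## Volume fusion

Every series is handled as a `ct_volume`: a Hounsfield-unit array plus a
`volume_geometry` (origin, spacing, direction cosines) mapping 0-based voxel
indices to patient-space millimetres (LPS), `world = origin + D (s ∘ ijk)`,
with voxel *centres* as reference points — the DICOM tag convention.

`fuse_series()` maps each thin-grid voxel centre to patient space, evaluates
both thick series there by trilinear interpolation, and averages:

* both series cover the point → mean of the two values (equal weights);
* one covers → that value alone, flagged in the coverage mask;
* neither → −1000 HU (ambient air).

Trilinear interpolation was chosen because it is the standard resampler for
this job and admits an exact independent oracle (it reproduces affine
intensity fields exactly; the test suite checks both this and a brute-force
per-voxel loop to 10⁻⁶ HU). Coverage is defined by the voxel-centre hull of
the source (no extrapolation). Intensities are averaged in HU; no intensity
harmonisation is applied between the two series. Pairs whose slice normals
are not orthogonal, or whose in-plane axes are not aligned with the patient
axes, within 10⁻³ on absolute cosine residuals, are rejected — the same
discard rule applied at data admission.

## Series admission and DICOM handling

`validate_triplet()` enforces the collection rules: thin axial 1–1.25 mm
thickness with a 0.7–1.25 mm interval never exceeding the thickness; both
thick series exactly 5 mm / 5 mm; right-orthogonality of each axial series to
the coronal one. Inter-slice intervals are *computed from slice positions*
(projections onto the slice normal), not read from the thickness tag, and a
series is rejected when consecutive gaps differ by more than 10⁻² mm, when
orientations differ across slices, or when rescale slope/intercept vary
within a series.

The package carries its own minimal DICOM reader/writer (single-frame CT,
explicit VR little endian, uncompressed): slices are sorted by position
projection, rescale slope/intercept produce HU, and writing inverts the
transform into signed 16-bit stored values, refusing out-of-range
intensities. Round-trips are bit-exact in stored values and reproduce
geometry to better than 10⁻⁶ mm; a cross-check against an independent Python
DICOM implementation is part of the test suite. `deidentify()` empties
patient name/ID tags, moves every date to January 1 of its year, and draws
fresh UIDs on every call.

## The four networks

All four architectures are the 1:1 variants: input and output grids are
identical, so the interpolation / upsampling stages of the published designs
are removed and every network maps a 1-channel H×W slice to a 1-channel H×W
slice, fully convolutionally.

| network | structure | loss | initial lr |
|---|---|---|---|
| SRCNN | 3 conv stages, kernels 9–5–5, widths f, f/2, 1 | MSE | 1e-4 |
| VDSR | 20 conv layers of 3×3, global input skip, gradient clipping | MSE | 1e-5 |
| SRResNet | 16 residual blocks (conv–BN–PReLU–conv–BN), long feature skip | MSE | 1e-4 |
| EDSR | 32 residual blocks (conv–ReLU–conv, no BN), residual scaling 0.1 | L1 | 1e-4 |

Design choices where the published descriptions leave freedom:

* **Global input skip.** VDSR is residual by construction. For the 1:1
  SRResNet and EDSR variants the output stage is also given a global input
  skip, so all three predict a correction to the input; zeroing the final
  convolution makes them the exact identity. With the final layer
  zero-initialised, training starts from the LR volume itself, which is the
  natural starting point when input and output resolution agree.
* **SRCNN initialisation.** SRCNN has no skip, so it is initialised with a
  centred delta-kernel pass-through path plus small (sd 10⁻³) random weights:
  it too starts near the identity. Without this, the first thousands of
  updates are spent re-learning the identity map.
* **Feature width** is configurable (`n_feats`, default 64 — the conventional
  width of these networks). Block counts, normalization presence and the 0.1
  residual scaling are structural constants and do not scale down.
* **VDSR gradient clipping**: global-norm clip at 1.0.
* **Optimizer**: Adam at the per-architecture initial learning rates, no
  schedule.
* **Intensity normalization**: one global window, [−1024, 3071] HU → [0, 1]
  (width 4095), recorded in the trained model and used for de-normalization
  and clipping at inference.

The engine behind these networks is a small purpose-built convolution stack
(im2col + BLAS matrix multiply, manual backpropagation, Adam) in double
precision; training is bit-reproducible given the seed under a fixed BLAS
configuration.

## Training and inference protocol

Training draws, per batch, `batch_size` random 96×96 patch pairs (the
full-scale patch size; smaller desk-scale profiles use smaller patches) from
slices of the configured plane of randomly chosen training cases, cropping HR
and LR at the same location; slices smaller than the patch are
reflect-padded. No patch rejection is applied — air-only patches are kept.
The full-scale profiles are:

```{r}
table_training_settings()
```

`batch_size × batches_per_epoch × total_epochs` gives the total patches
trained (2.4M for EDSR, 3.2M SRCNN, 3.84M VDSR, 2.88M SRResNet); the package
keeps a patch counter and the test suite verifies the bookkeeping. After each
epoch the evaluation cases are scored (PSNR of inferred SR vs HR, evenly
subsampled slices) and the checkpoint with the best evaluation PSNR is
returned. Inference runs every slice of the requested plane through the
network at full slice size, restacks, de-normalizes and clips to the window;
inferring on a plane other than the training plane warns but proceeds, since
cross-plane inference is a legitimate experiment.

## Quality metrics and ROIs

`psnr()` is `10·log10(range²/MSE)` with a 100 dB sentinel for identical
inputs; `ssim()` is mean local SSIM with an 11×11 Gaussian window (σ = 1.5),
K₁ = 0.01, K₂ = 0.03, windows fully inside the image. `data_range` is fixed
to the 4095 HU normalization-window width rather than per-image ranges, so
scores are comparable across cases.

Three nested ROIs are scored per case (`evaluate_case()`): the whole volume;
the body-area bounding box (largest connected component of HU > −500, holes
filled); and the lung-fields bounding box (components of HU < −320 inside the
body, border-touching components excluded, two largest kept). ROIs are
derived from the ground-truth volume only, as one 3D box per case (the
per-slice-2D-box alternative exists but was not taken; boxes, not tight
masks, match how the regions are drawn in practice). Metrics are computed per
axial slice and averaged over slices. Ambient air is error-free by
construction wherever both HR and reconstruction agree on −1000 HU, which is
why the whole-image ROI scores highest and the lung box lowest — blank areas
inflate similarity scores, the motivation for ROI-aware evaluation.

## Paired statistics

`wilcoxon_one_sided(x, y)` tests "x exceeds y" on paired per-case metrics.
Zero differences are dropped; tied absolute differences get midranks. For
n ≤ 25 the p-value is exact: the distribution of the signed-rank sum over all
2ⁿ sign assignments is built by a generating-function dynamic program over
doubled midranks (so ties remain exact — the base-R implementation falls back
to a normal approximation there, and serves as an independent oracle only in
the untied case). Larger n uses the normal approximation with continuity and
tie corrections. With 22 test cases and all differences in one direction the
smallest attainable one-sided p is 1/2²² ≈ 2.38×10⁻⁷.

`comparison_matrix()` reproduces the two comparison families: *plane* mode
compares all C(13,2) = 78 unordered pairs of {LR, 4 models × 3 planes};
*roi* mode crosses {LR, 4 models} with the three ROIs and evaluates only
pairs sharing the method or the ROI — 5·C(3,2) + 3·C(5,2) = 45 pairs, since
cross-method-cross-ROI comparisons have no practical meaning and are recorded
as absent, not zero. Bonferroni thresholds are α/78 = 6.41×10⁻⁴ and
α/45 = 1.11×10⁻³ at α = 0.05 (α itself is implied by those two printed
thresholds). Cells are one-sided row-over-column, upper triangle only.

## The phantom generator

Because the clinical DICOM data are private, the package ships a seeded
synthetic chest phantom (`phantom_spec()` / `make_triplet()`) from which the
whole pipeline is testable. It emulates, per case:

* ambient air at −1000 HU and a soft-tissue trunk at 40 HU shaped as an
  elliptical cylinder crossing the entire scanned z-range — as a torso does;
  an earlier ellipsoidal body put end-caps inside the volume, a geometry no
  chest scan has, and distorted per-slice ROI statistics;
* two ellipsoidal lungs at −800 HU containing tubular vessels (0 HU),
  ground-glass-like nodules (−400 HU), and a fine parenchymal texture
  (sd 200 HU at the 1 mm grid) standing in for the unresolved
  vasculature/interstitium that makes lung fields the most detail-dense
  region of a real chest CT — resolved on the thin grid, destroyed by
  thick-slice averaging, exactly the detail SR is asked to restore;
* Gaussian reconstruction noise (sd 15 HU) confined to the body, so blank
  air areas behave as in clinical images;
* thick series derived from the same volume by pure boxcar block averaging
  of 5 consecutive 1 mm slices (slice profile = slice interval, consistent
  with thickness = interval = 5 mm), the coronal series re-gridded so its
  slice normal is the anterior–posterior axis.

Defaults are 96×96×60 voxels at 1 mm; tests use 48×48×30 and 24×24×15
variants with proportionally scaled anatomy. What the phantom does *not*
emulate: scanner physics (beam hardening, dose-dependent noise correlation),
reconstruction kernels, breathing/cardiac motion, anatomy beyond the
lung/trunk layout. Passing tests therefore demonstrate the correctness of the
pipeline's geometry, fusion, optimisation and bookkeeping, and the *direction*
of the SR-over-LR and ROI-ordering effects — not clinical effect sizes.

## Problem sizes and numerical choices

The shipped desk-scale profile (`run_config()` defaults: 48³-scale phantoms,
width-8 networks, 24×24 patches, batch 4, 8 batches/epoch, 3 epochs,
learning rate 10⁻³) trains any of the four architectures in seconds to tens
of seconds on one CPU while preserving every structural constant; it is the
package's own choice of test-scale experiment. The full-scale profiles of
the table above are shipped unchanged and are GPU-scale.

Numerical details fixed by design: orthogonality tolerance 10⁻³ (absolute
cosine residuals); inter-slice uniformity tolerance 10⁻² mm; out-of-coverage
fill −1000 HU with a recorded coverage mask; exact-test cutoff n ≤ 25;
PSNR sentinel 100 dB; SSIM windows valid-mode only (images below 11 px per
side are an error). Degenerate inputs: all-zero difference vectors give
p = 1; an all-air scan is an "empty scan" error; non-uniform rescale slopes
within a series reject the series rather than silently mixing scales.

## Known limitations

* Body-vs-lung SSIM ordering on phantoms has a small margin: the bounding-box
  body ROI includes the blurred trunk/air boundary, which depresses its SSIM
  toward the lung value; on occasional seeds the two cross. PSNR ordering is
  robust. Clinical images, with far richer lung detail, separate the two
  further.
* The DICOM layer reads explicit-VR little-endian single-frame CT only — the
  format it writes; compressed transfer syntaxes and multi-frame objects are
  out of scope.
* Fusion assumes right-orthogonal series; arbitrary-angle pairs are rejected,
  not registered.
* Training at the full Table settings (millions of patches at width 64) is
  not reproduced at desk scale; the package verifies its bookkeeping and its
  learning direction instead.
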