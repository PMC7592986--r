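---
title: "Two-step hybrid Demons registration for super-resolution TR-4DMRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step hybrid Demons registration for super-resolution TR-4DMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Time-resolved 4D-MRI (TR-4DMRI) aims to image multi-breath respiratory
motion volumetrically. Neither acquisition alone suffices: a breath-hold
(BH) scan gives high spatial resolution (2 mm isotropic) but no motion,
while a free-breathing (FB) 3D-cine series at 2 Hz captures motion at only
5 mm isotropic. Super-resolution reconstruction bridges the two by
deformably registering the BH volume onto every cine frame; the deformed
high-resolution image inherits the frame's breathing phase.

Intensity-driven deformable registration (DIR) works well where contrast is
high — the lung/diaphragm interface — and poorly in low-contrast tissue:
lung parenchyma, vessels, and low-contrast tumors contribute little
intensity difference, little gradient force, and little misalignment
penalty. The package implements a two-step hybrid remedy:

1. **Step 1 — conventional DIR.** A multi-resolution Demons registration on
   the union of the two body masks aligns high-contrast structure. Its
   stopping criterion is deliberately relaxed (relative VID change
   `1e-3` rather than `1e-4`), since the second step will finish the job in
   low-contrast regions.
2. **Step 2 — hybrid refinement.** The lungs are segmented automatically on
   the step-1 deformed image and the same contour is reused on the frame,
   splitting the body into two low-dynamic-range (LDR) sub-regions: the
   dark lungs and the bright "bodyshell" (body minus lungs). Air bubbles in
   the bowel, which do not correspond across breathing phases, are filled
   with the mean bodyshell intensity. Each sub-region's LDR is then
   stretched to the full dynamic range (FDR), which turns faint parenchymal
   structure into strong registration evidence, and each sub-region is
   refined by an independent Demons registration. The two refinement fields
   are stitched (their supports are disjoint) with a smoothing pass across
   the interface band, and a short final tuning registration runs in that
   band only.

## The registration engine

The engine is classic additive Demons with a multi-resolution pyramid
(factors 6, 2, 1 of the native voxel size). Per iteration at each level:
warp the moving image with the current field `U`, evaluate the voxel
intensity difference (VID, the mean absolute difference over the ROI),
compute the per-voxel force, accumulate, and Gaussian-smooth.

**Force.** The default force is a symmetric variant of the Demons force,

`u = (I_s - I_m)·ḡ / (|ḡ|² + (I_s - I_m)² + ε)`,   `ḡ = (∇I_s + ∇I_m)/2`,

with gradients by central differences. Averaging the static and
warped-moving gradients keeps a force alive where one of the two images is
locally flat — the typical situation when a sharp 2 mm image meets a
5 mm-derived frame whose edges are spread over several voxels. The classic
passive (static-gradient-only) force is available via
`demons_params(force = "passive")`.

**Pseudo-force spreading.** At the coarsest level (factor ≥ `pseudo_level`,
default 6) each voxel's force is distributed over its 5×5×5 neighbourhood
with normalized Gaussian weights (σ = 1 voxel). The spread force reaches
`2 mm × (5/2) × 6 = 30 mm` from its source voxel on a 2 mm image
(`pseudo_force_reach()`), which is what lets the engine bridge diaphragm
excursions up to 6 cm whose intensity profiles do not initially overlap.
The convolution kernel is normalized, so the total force vector is
conserved for interior-supported fields.

**Stopping.** A level stops once the relative VID change between
consecutive iterations falls below `stop_dvid` (`1e-4` conventional,
`1e-3` for the hybrid first stage). Non-native levels apply a 10× stricter
version of the same criterion: coarse iterations cost almost nothing and
their convergence is what buys deformation range, whereas stopping them
early leaves large-displacement recovery unfinished. An iteration that
*increases* the VID by more than 5% is rejected (the previous field is
kept) and ends the level. Iteration caps default to 300/100/50.

**Point-spread matching.** When the static image derives from a 5 mm
acquisition, the warped moving image is Gaussian-blurred (σ = 0.9 native
voxels ≈ 1.8 mm, the measured width of a 5 mm box average plus trilinear
interpolation) before each force evaluation. Without this, the blur
mismatch between the two edge profiles biases the force; the warp that
produces the output image always uses the sharp data. Generic registration
of same-resolution images leaves `psf_sigma = 0`.

**Noise floor.** Intensity residuals below `diff_threshold` (default 0.05,
about twice the 2% Rayleigh noise level on normalized images) generate no
force, so noise cannot random-walk the field; the floor scales down with
the pyramid factor (prefiltering attenuates noise) but never below 0.015
(blur mismatch does not vanish). A stagnation guard additionally ends any
non-coarsest level that shows no net VID progress over five iterations —
the coarsest level is exempt because its slow grind is what recovers large
displacements.

## Intensity handling

Demons assumes intensities correspond; three calibrations enforce that:

* **Trimmed-window normalization** (`normalize_intensity()`): the means of
  the top and bottom 1% of body-ROI intensities define a window mapped to
  [0, 1], guarding against single-voxel spikes.
* **Background offset removal**: magnitude-MR noise has a positive mean
  (a Rayleigh background). It is estimated from voxels at least 4 voxels
  outside the body — the partial-volume ring around the body surface would
  otherwise inflate it — and subtracted.
* **Affine recalibration after step 1** (`run_two_step()` internal): a
  linear fit of the deformed BH on the frame over the body ROI absorbs
  residual global scale/offset differences (e.g. the noise-induced widening
  of the frame's normalization window). After stage 1 most voxels
  correspond, and the two intensity clusters (dark lungs, bright shell)
  pin the fit.

The sub-ROI FDR stretch (`renormalize_subroi()`) uses the 1%-trimmed window
of the *deformed BH* sub-region for **both** images, so the two images of
one sub-region share a single intensity scale; the window is applied
*after* warping and point-spread matching, mirroring the order in which the
acquisition itself blurred and quantized the tissue.

## Sub-ROI refinement dynamics

The refinements warm-start from the stage-1 field and evolve the *total*
field under forces restricted to their sub-ROI. The two sub-regions get
different regularization, reflecting what they contain:

* **Lungs — fluid-dominant** (×2 then native schedule, increment σ = 1.5,
  field σ = 0.5, floor 0.05): elastic (field) smoothing continuously
  diffuses the surrounding field into small rigid structures — a tumor
  embedded in axially compressing parenchyma is slowly squeezed by its
  neighbourhood — whereas fluid smoothing lets a converged boundary
  correction persist. This is what restores the tumor after the
  direction-dependent distortion of stage 1.
* **Bodyshell — conventional elastic** (native only, increment and field
  σ = 1, floor 0.08): abdominal organs are large and high-contrast, so
  elastic Demons suffices, and the fluid setting would slowly wander on
  residual blur mismatch at organ edges. Forces are also kept off the
  partial-volume ring at the outer body surface, whose intensity is
  resolution- rather than anatomy-driven.

The two refinement fields (expressed as increments over stage 1) are
stitched by `combine_dvfs()`; their supports are disjoint by construction,
and one Gaussian pass replaces the field within ±2 voxels of the
lung/bodyshell interface to avoid a seam. The final tuning DIR runs only in
a ±3 voxel interface band: in development it was the full-body finetune
that re-introduced the ambient compression into the tumor and most of the
folding (negative Jacobians), while the band-limited version fixes the seam
without either side effect.

## The digital thorax phantom

The generator supplies ground truth that licensed anthropomorphic phantoms
would otherwise provide: what the method needs is *known correspondence*,
not anatomical realism. Anatomy is parametric and scales with the grid
extent (default 96×96×120 voxels at 2 mm):

* an elliptical **body** with smooth cosine-field texture and nine
  organ-scale Gaussian blobs in the abdomen (T1w abdomen is rich in
  organ-level contrast, and that structure is what anchors deep
  registration), all rendered in a bright band (≈0.46–0.95);
* two **lung** ellipsoids, clipped from below by a diaphragm dome and
  laterally against a 10%-shrunken body surface so the bodyshell keeps a
  non-trivial thickness everywhere (otherwise 5 mm partial-volume
  averaging opens the dark cavity to the dark background, and body
  segmentation by thresholding plus hole-filling fails);
* a rigid spherical **tumor** (default Φ 30 mm) in the right lung,
  rendered at low contrast (≈0.30 vs lung ≈0.14);
* a procedural **vessel tree** per lung (greedy minimum-spanning tree over
  the landmark set, Gaussian-profile tubes) whose nodes serve as
  bifurcation-like landmarks: bright and localized at 2 mm, marginal after
  5 mm degradation;
* **air bubbles** (near-zero intensity) in the abdomen, placed with
  extent-scaled interior margins and mutual separation.

Motion is a superior-inferior displacement field: full amplitude at and
below the diaphragm, decaying linearly to zero at the lung apex, applied by
analytic inverse mapping so every frame is rendered exactly (no resampling
error in the ground truth). The tumor translates rigidly at
`tumor_motion_ratio` (default 2/3) of the diaphragm displacement; its
centre sits exactly at the height where the decaying field equals that
ratio, so tumor and surroundings move consistently. Landmarks follow the
same analytic map, which makes them a self-consistent oracle. Frames are
degraded per the acquisition model: overlap-weighted block-mean
down-sampling to 5 mm followed by additive Rayleigh noise with scale 2% of
the normalized range ("2%" is interpreted relative to the normalized [0, 1]
range; the scale is a parameter).

What the phantom does **not** emulate: hysteresis between inhale and exhale
pathways, cardiac motion, sliding at the chest wall, anterior-posterior
motion components (the motion is SI-only by default), intensity
non-uniformity (bias fields), and the anatomical irregularity of real
parenchyma. Passing tests on this phantom therefore demonstrate the
mechanics of the method — range recovery, contrast-driven refinement,
field quality — not clinical performance.

The breathing waveform generator (`irregular_waveform()`) produces
quasi-periodic traces whose end-exhale level is constant while each cycle's
inhalation depth and period vary (coefficient of variation
`inhale_variability`), matching the clinical observation that exhalation is
the stable phase.

## Numerical choices and degenerate inputs

* Voxel centres at `origin + index · spacing` (0-based); warps are backward
  maps with trilinear interpolation and nearest-edge clamping.
* Block-mean resampling uses exact 1-D overlap weights per axis (the
  2 mm → 5 mm factor of 2.5 makes fractional overlaps mandatory); it
  conserves intensity × volume for interior content.
* Gaussian smoothing is separable with 3σ truncation; kernels renormalize
  over in-bounds taps at edges, except pseudo-force spreading which uses
  zero padding so force is conserved.
* `det(I + ∇U)` and `∇×U` use central differences (one-sided at borders)
  of the mm-valued components over the mm grid, so both are dimensionless
  as conventionally reported; summary statistics are restricted to the
  body ROI, where deformation is defined.
* Constant sub-regions, empty ROIs, non-finite fields, and collapsed
  resampling grids raise errors rather than propagate silently; a level
  whose VID would rise by more than 5% rolls back.
* Seeded operations (`add_noise()`, the phantom content, waveforms) use a
  private RNG stream and restore the caller's RNG state.

## Problem sizes used in the shipped experiments

The packaged tests exercise the full-size phantom (96×96×120 at 2 mm) for
the motion-ladder experiments and the noise-replicated one-step versus
two-step comparisons, and smaller grids (64×64×80 and 48×48×64 — the same
anatomy at proportionally smaller extents) for segmentation, series and
engine property tests, chosen as the smallest sizes at which the
lung/tumor/bodyshell topology and the scaled motion range are faithfully
represented. Note that because the 5 mm acquisition blur does not scale
with the phantom, the small grids are *relatively* harder than the study
conditions, and the registration quality bounds asserted there are
correspondingly looser.

## Known limitations

* **Tumor volume under degraded evidence.** With targets down-sampled to
  5 mm and carrying 2% Rayleigh noise, the intensity-optimal tumor boundary
  sits 0.5–0.8 mm inside the true one, and the reconstructed tumor volume
  ratio settles near 0.85 rather than unity. The deficit is in the degraded
  evidence, not the engine: the identical pipeline registered to a
  noise-free high-resolution target recovers volume ratio 0.994 and Dice
  0.988. Tumor *position* (centre-of-mass error ≈ 0.2–1.1 mm across the
  2–6 cm ladder) and *overlap* (Dice ≈ 0.87–0.93) are unaffected.
* **Zero-motion residual.** Registering a frame to a degraded copy of
  itself leaves a mean field magnitude of roughly half a voxel, because
  block averaging and noise genuinely shift apparent sub-voxel edge
  positions; the field is not exactly zero even at the optimum.
* Large motions (5–6 cm) still degrade landmark accuracy relative to small
  ones; the two-step refinement reduces but does not eliminate this.
* The additive first-order Demons field is not guaranteed diffeomorphic;
  the Jacobian/curl QA quantifies, rather than prevents, folding.
* The cross-consistency check (CCC) flags outliers against a batch mean ±
  one standard deviation; with small batches this threshold is noisy.
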