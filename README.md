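# tr4dmri

Super-resolution reconstruction of time-resolved 4D-MRI (TR-4DMRI) by
two-step hybrid deformable image registration, in R.

## The problem

Volumetric imaging of multi-breath respiratory motion needs both spatial
and temporal resolution, which no single MR acquisition provides: a
breath-hold (BH) T1w scan gives 2×2×2 mm³ but a frozen breathing phase,
while a free-breathing (FB) 3D-cine series at 2 Hz manages only
5×5×5 mm³. TR-4DMRI reconstructs a high-resolution volume *per cine frame*
by deformable image registration (DIR): the BH volume is deformed onto
each frame, inheriting its breathing phase while keeping its resolution.
The audience is medical-physics / radiotherapy researchers studying
respiratory tumor motion.

Intensity-driven DIR is accurate at high-contrast interfaces (diaphragm)
and poor in low-contrast tissue (lung parenchyma, vessels, low-contrast
tumors), which distorts exactly the structures one cares about. The
package implements a two-step remedy:

1. **Conventional multi-resolution Demons DIR** on the union of the body
   masks. The Demons update at each voxel is

   `u = (I_s − I_m)·ḡ / (‖ḡ‖² + (I_s − I_m)² + ε)`,

   accumulated additively and Gaussian-regularized, over a ×6/×2/×1
   pyramid. At the coarsest level each force is spread over its 5×5×5
   neighbourhood with Gaussian weights (σ = 1 voxel) — a *pseudo-force*
   whose physical reach (2 mm × 5/2 × 6 = 30 mm) buys the deformation
   range needed for diaphragm excursions up to 6 cm. A level stops when
   the relative change of the voxel intensity difference
   (VID = mean |I_m − I_s|) falls below ΔVID (10⁻⁴ conventional, 10⁻³ as
   the relaxed first stage of the hybrid pipeline).
2. **Hybrid sub-ROI refinement.** The lungs are auto-segmented on the
   deformed BH image and the contour reused on the frame, splitting the
   body into lungs and "bodyshell" (body − lungs). Air bubbles in the
   bowel are filled with the mean bodyshell intensity; each sub-region's
   low dynamic range is renormalized to the full range (contrast
   enhancement); each sub-region gets an independent warm-started Demons
   refinement; the two fields are stitched with seam smoothing and a final
   tuning DIR runs in the interface band.

Quality assurance: voxel intensity correlation (VIC) and difference (VID),
3-D SSIM, tumor Dice / centre-of-mass shift / volume ratio, landmark
target registration error, the Jacobian determinant `det(I + ∇U)` (minimum
and % negative = folding), the curl `∇×U`, and a cross-consistency check
(CCC) comparing reconstructions of the same frame from two opposite
breath-holds:

`CCC = 2·VIC(recᴮᴴᴵ, recᴮᴴᴱ) / (VIC(recᴮᴴᴵ, FB) + VIC(recᴮᴴᴱ, FB))` — ideally 1.

A parametric digital thorax phantom (elliptical body, two lungs truncated
by a diaphragm dome, rigid spherical tumor moving at 2/3 of the diaphragm
amplitude, vessel-tree landmarks, abdominal air bubbles, quasi-periodic
breathing waveforms) provides ground truth; its frames are degraded to
cine realism by overlap-weighted 5 mm block averaging plus 2% Rayleigh
noise.

## Worked example

```r
library(tr4dmri)

spec <- phantom_spec(seed = 1)              # 96 x 96 x 120 voxels at 2 mm
bh   <- generate_frame(spec, 0)             # full inhalation (BHI)
tgt  <- generate_frame(spec, 30)            # 3 cm diaphragm displacement
low  <- add_noise(resample(tgt$image, c(5, 5, 5), "block_mean"),
                  level = 0.02, seed = 41)  # simulated cine frame

res <- run_two_step(bh$image, low)          # ~1-2 min on one core

tumor <- image3d(array(as.numeric(bh$tumor_mask), dim(bh$tumor_mask)),
                 spec$spacing)
warped <- warp_image(tumor, res$dvf)$data >= 0.5
dice_coefficient(warped, tgt$tumor_mask)
#> [1] 0.9151
com_delta(warped, tgt$tumor_mask, spec$spacing)   # mm
#> [1] 0.32
jacobian_map(res$dvf, res$roi)$pct_negative       # % folded voxels
#> [1] 0
```

The Dice index says 92% of the reconstructed tumor volume overlaps the
ground truth; the centre-of-mass error is a third of a millimetre — a
sixth of a voxel — and the final displacement field is free of folding.
Exact values vary slightly with the seeds used for phantom texture and
noise.

The shipped command-line front end mirrors the workflow
(`phantom`, `simulate`, `register`, `reconstruct`, `qa`, `ccc`):

```sh
Rscript inst/cli/tr4dmri.R phantom --config cfg.yaml --out phantom_out/
```

## Layout

- `R/`, `src/` — implementation (image container, Demons engine, phantom,
  hybrid pipeline, QA metrics, I/O, CLI; hot loops in C++).
- `vignettes/methods.Rmd` — the model, its parameters, and the design
  decisions, including what the phantom does and does not emulate.
- `tests/testthat/` — unit, property and acceptance suites.
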