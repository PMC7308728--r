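---
title: "Surface-based multiparametric qMRI enhancement of focal cortical dysplasia: models and methods"
author: "fcdenhance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FCD enhancement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Focal cortical dysplasia (FCD) is a malformation of cortical development
and a frequent cause of drug-refractory epilepsy.  Its MRI hallmarks —
blurring of the junction between cortical gray matter (GM) and white
matter (WM), thickening of the cortical ribbon, and subcortical T2/FLAIR
hyperintensity — are often subtle, and lesions are easily missed on
conventional weighted images, whose intensities also carry scanner
hardware bias (transmit field B1, receive-coil profile, B0).

Quantitative MRI (qMRI) instead maps physical tissue parameters — the
longitudinal and transverse relaxation times T1 and T2 (ms) and the
proton density PD (percent units, pu) — free of hardware effects.  This
package implements a surface-based pipeline that converts the
multiparametric qMRI signature of a blurred junction and a thickened
cortex into a voxel-wise enhancement factor that multiplies a clinical
FLAIR anatomy, boosting signal exactly where FCD features are present.
The package also provides a digital cortical phantom, so the entire
pipeline runs, and is validated, without patient data.

## Quantitative mapping

All fits are closed-form voxel-wise inversions of the ideal forward
models, which the phantom simulator shares; this keeps forward/inverse
consistency exactly testable (noiseless simulation followed by fitting
reproduces ground truth to machine precision).

* **B1** — a magnetization-prepared/reference gradient-echo pair: the
  preparation pulse rotates longitudinal magnetization by a nominal 45
  degrees, so `B1 = acos(prepared/reference) / 45deg`.  Because the
  transmit field is spatially smooth (and is acquired at 4 mm resolution
  in the source protocol), the fitted map is quotient-smoothed (FWHM
  8 mm by default) before it corrects the other fits; without this the
  voxel noise of B1 dominates the T1 error budget.
* **T1** — variable flip angle (VFA): two spoiled gradient-echo volumes
  at 4 and 24 degrees (TE 6.7 ms, TR 16.4 ms).  The SPGR equation
  linearizes as `S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)` with
  `E1 = exp(-TR/T1)`; the slope of the two-point line gives T1, with the
  local true angles `a = B1 * a_nominal`.  Slopes outside (0, 1) are
  invalid (CSF pulsation, background).  Ideal spoiling is assumed: the
  B0/spoiling corrections of the source protocol live in its cited
  references and are deliberately out of scope, and the phantom uses the
  same ideal model.
* **T2** — four spin echoes (TE 13/67/93/106 ms, TR 10 s): unweighted
  log-linear least squares of `ln S = ln S0 - TE/T2`.  Stimulated-echo
  corrections are likewise out of scope.
* **T2\*** — two gradient echoes (TE 4.3/11 ms), closed form
  `T2* = dTE / ln(S1/S2)`; unphysical voxels (S1 <= S2) are invalid.
* **PD** — the low-angle SPGR volume corrected for T1 saturation, T2\*
  decay, B1 and the receive-coil profile (RCP), then scaled so that a
  reference region (phantom default: CSF) averages 100 pu.  The RCP is
  estimated as a 3rd-order 3-D polynomial fit to the ratio of the
  measured signal to a model signal predicted from the fitted T1/T2\*/B1
  and the Fatouros pseudo-PD, normalized to mean 1 over the brain mask.
  The exact estimation procedure of the source protocol's reference is
  not public; the polynomial surrogate recovers smooth multiplicative
  fields exactly and noisy ones to ~2% RMS.
* **Fatouros pseudo-PD** — `1/PD = A + B/T1` with configurable constants
  (defaults A = 0.916, B = 436 ms, literature-plausible values giving WM
  ~0.71, GM ~0.81, CSF ~0.98 water fraction).  They are configuration,
  not results.
* **Synthetic MP-RAGE** — recursive Bloch simulation of the
  inversion/echo-train cycle at the virtual parameters TR 1900 ms, TI
  900 ms, 9 degrees, echo spacing 8.1 ms.  Train length (176) and
  k-space-centre index (88) are unspecified in the source description
  and exposed as configuration.  The steady state is independent of the
  initial magnetization (verified to 1e-9).

## Edge-preserving compartmental smoothing

The detection chain is run twice, once on the original maps (giving
R<sub>u</sub>) and once on smoothed maps (R<sub>s</sub>).  Smoothing is
compartmental and edge-preserving: each map is split into WM and non-WM
using the WM segmentation; non-WM T1 and PD voxels with T1 > 2000 ms and
non-WM T2 voxels with T2 > 300 ms are excluded (strict comparisons,
reducing CSF partial volume — GM T1 lies in 1200–1600 ms, so healthy GM
is never touched); each compartment is smoothed as the quotient
`G(map*mask) / G(mask)` with a 1.5 mm FWHM Gaussian, which prevents
zeros outside the mask from dragging edge values; finally the
compartments are recombined.  Excluded voxels stay invalid after
recombination (the alternative — re-including them — is not taken, since
the exclusion exists precisely to remove CSF-contaminated values).

## Depth sampling and the Q statistic

Each hemisphere is modelled by white and pial triangle meshes with 1:1
vertex correspondence and a per-vertex cortical thickness T (mm).  Depth
is parameterized per vertex along the white-to-pial vector: fraction 0
at the WM/cortex junction, 1 at the pial surface; negative fractions
extend the same vector into WM, implementing the "mirror at the
junction" convention.  (An alternative — mirroring along the
white-surface normal — would coincide with this choice on the phantom
geometries; the vector convention is used because it needs no normal
estimation and is symmetric by construction.)

Every qMRI map is averaged over four depth bands, sampled in 1%-of-
thickness layers (inclusive endpoints, 21 layers per band):

1. 20–40% of the thickness (deep cortex),
2. 60–80% (superficial cortex),
3. −40…−20% (WM, mirror of band 1),
4. −80…−60% (WM, mirror of band 2).

The per-vertex **population** standard deviation (divisor 4) of the four
band means is computed for T1, T2 and PD.  At a sharp junction two
values sit at the WM level and two at the GM level, so SD = |a−b|/2; a
blurred junction pulls the four values together and the SD falls.  The
sample-vs-population choice is not fixed by the source description;
population is used throughout and all thresholds were set under that
convention.  The SDs combine with the thickness into the vertex-wise
statistic

  Q = SD(T1) x SD(T2) x SD(PD) / T,

low where the junction is blurred and/or the cortex thickened.  A
minimal offset of 0.0001 avoids exact zeros before the later division.

Interpolation is trilinear.  A band sample's validity follows a
renormalized rule: weights of invalid corner voxels are dropped and the
rest rescaled, and the sample is invalid only when the valid weight
falls below one half or the point leaves the grid.  This matters because
the CSF exclusion deliberately invalidates voxels just above the pial
surface; under a strict any-invalid-corner rule the superficial band of
a realistic 2.5 mm cortex would be invalidated wholesale in the smoothed
branch.  Grid-resampling between volumes (a different operation) keeps
the strict rule.  A vertex is invalid — and excluded from Q and from
projection — if it is off-cortex (medial wall) or any of its band
samples is invalid.

## Projection, filtering and the R map

The Q overlay is projected into the volume by a nearest-vertex ribbon
fill (re-implementing the role of an external surface-to-volume tool,
which supports several dialects — one is fixed here): a voxel receives
the value of the valid vertex whose white-to-pial segment is nearest
(point-to-segment distance), provided the depth coordinate on that
segment lies in [0, 1] and the lateral distance is at most the mean mesh
edge length; ties take the lower vertex index.  All other voxels are 0.

Ribbon voxels are filtered as `Q0 / Q` with the empirical threshold
Q0 = 500 — high values flag suspicious (low-Q) cortex.  Quotients above
1000 (offset-only or otherwise unreadable vertices, e.g. the medial
wall) are excluded, i.e. set to zero *before* smoothing, following the
stated order of operations; whether "excluded" meant set-to-zero or
masked-out-of-smoothing is not specified, and set-to-zero is chosen.
The filtered volume is smoothed with a volumetric Gaussian (sigma 3 mm;
the surface-based alternative is explicitly not used in the source
method, which projects first and smooths in 3-D) and offset by +1.0,
giving the enhancement factor R >= 1, approximately 1 in normal tissue.
The whole chain runs once per input branch, giving R<sub>u</sub> and
R<sub>s</sub>, and the enhanced anatomy is

  enhanced FLAIR = 0.5 (R_s + R_u) x FLAIR.

## ROI analysis

Signal is read as the mean over 2 x 2 x 1 mm boxes; membership is by
voxel centre with half-open bounds, so on a 1 mm grid the box covers
exactly four voxels (deterministic, no partial-volume weighting).
Contralateral control ROIs are pure x-reflections about the midsagittal
plane (the phantom is symmetric about x = 0).  Paired comparisons use an
exact two-sided Wilcoxon signed-rank test: zero differences are dropped,
absolute differences are mid-ranked, and the null distribution of the
positive-rank sum is evaluated exactly by integer convolution over the
doubled ranks — identical to enumerating all 2^n sign assignments, and
valid under ties.  Exactness matters at n = 10, where ten all-positive
differences give p = 2/1024 ≈ 0.00195 while the continuity-corrected
normal approximation gives ≈ 0.0059; published small-sample values are
often the latter, so both are reported side by side.

## The digital phantom

Two analytic geometries ship with the package:

* a **slab** — flat WM half-space, a GM ribbon of constant thickness
  (default 2.5 mm), CSF above; planar meshes with configurable spacing
  (default 2 mm) and a border ring flagged as medial wall;
* a **shell** — concentric white/pial spheres (icosphere meshes, exact
  radial correspondence), exercising curved mirror geometry and
  x-reflection symmetry.

Default tissue values (WM/GM/CSF T1 900/1400/4000 ms, T2 70/90/2000 ms,
T2* 50/60/200 ms, PD 69/83/100 pu) are literature-plausible 3 T inputs,
exposed as configuration.  A lesion is a tapered circular footprint
(raised-cosine taper) in which (a) the sharp WM-to-GM parameter
transition across the junction becomes a logistic sigmoid whose scale
(mm) is the "blur width", (b) the pial surface is displaced outward by
the thickening delta with the thickness overlay updated consistently,
and (c) subcortical WM T2 is raised by a delta that decays into depth
(3 mm scale).  The white surface itself does not move — the premise of
the method is that segmentation still finds the junction while the
parameter transition across it is blurred.

Raw acquisitions are simulated from the ground truth with the same
forward models the fits invert, modulated by a smooth transmit-field
dome (±5%) and a tilted receive profile, with Rician noise (magnitude of
complex Gaussian); the per-volume noise sigma is the mean WM signal
divided by the SNR (default 50), so "SNR 50" is the WM signal-to-noise
ratio of each volume.  The FLAIR anatomy uses the standard
inversion-recovery form `PD (1 - 2e^{-TI/T1} + e^{-TR/T1}) e^{-TE/T2}`
(TR 5000 ms, TI 1800 ms, TE 353 ms): CSF is suppressed and a subcortical
T2 increase is hyperintense, which is all the pipeline needs from it —
clinical FLAIR contrast fidelity beyond that is not a goal.  Phantom
generation is bit-deterministic given the specification and seed.

What the phantom does **not** emulate: gyrification and curvature-driven
partial volume, B0 distortion, segmentation error (surfaces are exact),
motion, multi-coil artifacts.  Passing tests therefore demonstrate the
internal consistency and sensitivity/specificity of the *method*, not
clinical performance on real data.

## Study conditions and validation cohorts

The validation suite runs, per subject, on a 44 x 44 x 40 grid at 1 mm
with 2 mm mesh spacing (SNR-50 relaxometry checks use 64 x 64 x 48) —
sizes chosen so a full 10-subject cohort completes in well under a
minute while every band, ROI and smoothing kernel is resolved.  The
cohort conditions are: 10 subjects, seeds 1–10, one lesion each (blur
width 2 mm, thickening 1.5 mm, subcortical T2 +30 ms), SNR 50, ROI at
the lesion centre on the junction.  Under these conditions the enhanced
FLAIR exceeds the conventional one at the lesion ROI in 10/10 subjects
(relative increase ~25%, inside the 22.5–146.9% range reported for the
clinical cohort the method was developed on), exceeds the contralateral
enhanced signal in 10/10, and both exact Wilcoxon tests give p = 2/1024.
The lesion-ROI increase grows monotonically with the blur width over
0–3 mm.

Two regression bounds were computed once from the lesion-free fixed-seed
cohort and frozen: the lesion-free relative increase stays below 2.0%,
and the 99th percentile of R over the ribbon stays below 1.05.

One structural property deserves note: because R >= 1 everywhere by
construction and the enhanced image is R times the conventional one, the
enhanced-vs-conventional paired difference is positive for *every*
subject, lesion or not — a signed-rank test on it is significant at any
effect size.  Specificity is therefore carried by the magnitude bounds
above and by the contralateral comparison (which is non-significant on
lesion-free cohorts), not by the enhanced-vs-conventional p-value.

## Numerical choices and degenerate inputs

* Invalid data are NaN on disk; validity masks propagate through every
  operation, and invalid voxels/vertices never enter statistics.
* World frame: scanner RAS in mm; voxel centres at integer 0-based
  indices; positions outside the outermost voxel centres are invalid,
  never clamped.
* Gaussian kernels are sampled, truncated at 4 sigma, normalized to unit
  sum, and applied separably per axis with the sigma converted to voxels
  per axis (anisotropic grids smooth isotropically in mm); a sigma below
  0.2 voxels collapses to the identity.
* Degenerate fits (non-positive signals, slopes outside (0,1), S1 <= S2)
  mark voxels invalid rather than producing values.
* The report builder survives degenerate comparisons (e.g. neutral
  enhancement makes all enhanced-vs-conventional differences zero) by
  reporting NA p-values instead of aborting.

## Known limitations

* Only the linear-fraction laminar model is implemented (no
  equidistant/equivolume layering).
* No registration: all inputs are assumed coregistered to the reference
  grid; only grid resampling is provided.
* The enhanced image is a visualization aid: the method enhances, it
  does not diagnose, and because smoothing is involved the spatial
  extent of a lesion must not be estimated from the enhanced image.
* PD accuracy is limited by the receive-profile surrogate (~5% tissue-
  dependent bias under noise); this scales the Q statistic smoothly and
  does not affect the lesion contrast mechanism.
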