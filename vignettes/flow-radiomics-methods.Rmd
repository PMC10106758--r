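---
title: "Methods: radiomics characterization of cross-sectional aortic flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics characterization of cross-sectional aortic flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowradiomics)
```

## Overview and assumptions

`flowradiomics` quantifies the spatial organization of blood flow in aortic
cross-sections measured by 4D phase-contrast MRI. The core assumption is
that clinically meaningful flow-profile differences — a centered parabolic
profile versus an eccentric stenotic jet, laminar versus helical or
vortical flow — express themselves as *texture* in scalar parameter maps
derived from the velocity field, and that standardized radiomics features
of those maps are a reproducible, low-dimensional description of them.

The pipeline assumes: (i) a time-resolved 3-component velocity field on a
regular voxel grid in physical millimeter coordinates; (ii) a vessel
centerline with the four standardized aortic landmarks (A1.1, B1, B4.1,
D1.1) already available — centerline extraction and lumen segmentation are
upstream of this package; (iii) cross-sectional ROIs that are star-shaped
(true for vessel lumina), which the observer-perturbation model and the
contour descriptors rely on.

## Parameter maps

Throughflow, wall parallelity degree and flow angle relate velocity to the
local vessel geometry through the plane normal; local normalized helicity
and vorticity describe the rotational organization of the local
neighborhood irrespective of anatomy. Two numerical decisions matter here:

* **Vorticity is differentiated on the 3D source grid** (spacing-aware
  central differences, one-sided at grid borders) and then resampled to the
  plane with the same trilinear interpolation as the velocity. In-plane 2D
  differences could not recover all three curl components. Central
  differences are exact for the parabolic and rigid-rotation test fields,
  which is what makes the analytic phantom checks sharp.
* **Zero-velocity pixels** would make WPD, angle and LNH 0/0. They are
  defined away explicitly: WPD → 0, angle → 90°, LNH → 0, each with a
  low-signal flag, using a speed floor of 1e−6 m/s. No map ever contains
  NaN, including zero-flow diastolic frames.

The helicity map is signed by default — the sign carries helix handedness,
and the signed normalization range would be pointless otherwise — with an
`absolute = TRUE` option where only helicity magnitude is of interest.

A vorticity map in 1/s has no natural fixed range, and a fixed signed range
of [−1, 1] only makes sense for a normalized quantity. The package
therefore ships the **plane-normal vorticity component self-normalized by
the per-plane, per-timeframe ROI maximum** as the default fifth map, with a
fixed physical reference (in 1/s) as a configurable alternative for
cross-plane comparability. Self-normalization makes the map scale-free
(texture, not magnitude, is retained), which is consistent with how the
other normalized maps behave under scanner velocity bias.

## Normalization and discretization

Each map is affinely rescaled from its native range to a fixed integer
output range — unsigned maps to [0, 4096], signed maps to [−2048, 2047];
throughflow uses ±6 m/s, angle [0°, 180°], WPD [0, 1], LNH and normalized
vorticity [−1, 1] — with out-of-range values clipped to the ends.
Normalized values stay floating point; integer quantization happens only in
the discretization step (fixed bin width 25, bins anchored at the ROI
minimum, `level = floor((v − min)/25) + 1`), so bin boundaries are
controlled in exactly one place. A full-span map yields at most 164 gray
levels.

## The feature catalogue: why 79 per map

The six standard families total 93 features under their full definitions
(18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM). The
package targets 79 per map, so the shipped default catalogue excludes 14
near-duplicates: total energy and range (deterministic functions of other
first-order features), the GLCM features that are linear transforms or
near-copies of retained ones (sum average, sum of squares, joint average,
Idmn) and the informational-correlation trio (MCC, IMC1, IMC2), and the
normalized non-uniformity variants of GLRLM, GLSZM and GLDM. The exclusion
list was chosen so that every feature family member known to be robust in
inter-scanner comparisons (inverse variance, inverse difference (normalized),
zone percentage, size-zone/dependence/gray-level non-uniformity, run
entropy, coarseness, dependence entropy) is retained. The catalogue is a
plain R object (`default_catalogue()`) and can be replaced; the counts
79/16/411 are enforced as invariants of the default.

2D texture conventions: distance-1 neighborhoods; co-occurrences over the
four unique 2D directions, symmetrized, **features averaged over
directions**; run-length matrices **summed over directions** before feature
computation; zones are 8-connected; GLDM dependence counts 8-neighbors
within gray-level tolerance α = 0 and indexes the matrix at dependence + 1,
with feature size-weights using that 1-based index. Degenerate inputs
follow fixed conventions rather than producing NaN: constant-map NGTDM
coarseness is 1e6, GLCM correlation of a one-level map is 1, first-order
skewness/kurtosis of a constant ROI are 0.

The 16 shape descriptors extend the classical 2D set (areas, perimeter,
diameter, axis lengths, elongation, eccentricity, circularity, compactness,
extent, solidity, equivalent diameter) with two motion descriptors relative
to the reference timeframe — centroid drift (mm) and fractional area
change — because contour mobility over the cycle is itself informative.
Perimeter and mesh area come from the marching-squares iso-contour of the
binary mask, smoothed with a window-5 circular moving average to suppress
the staircase bias of pixelation; both come from the same polygon, so the
isoperimetric bound (circularity ≤ 1) holds. On a digitized disk of radius
10 mm at 1 mm pixels this estimates the perimeter within about 0.5%. The
maximum diameter uses boundary-pixel corner vertices (so a 10 × 10 mm
square yields exactly √200 mm).

## Plane placement and resampling

Planes sit on the centerline with the local tangent as normal. In-plane
axes are the normalized projection of a fixed global reference direction
(falling back to the next canonical axis when parallel) and its cross
product with the normal — reproducible plane coordinates across runs. The
default configuration places 5 additional equidistant planes between A1.1
and B1 (ascending aorta) and 3 between B4.1 and D1.1 (descending), for 12
planes total; only the total is standardized, so the per-segment split is
configurable. Resampling is trilinear at 1 mm; pixels outside the source
grid are flagged invalid and excluded from every mask, never extrapolated.

ROI transfer across timeframes uses centroid tracking: the mask translates
(integer pixels, area preserved exactly) to follow the centroid of
through-plane speed inside a search window. This replaces deformable
motion tracking, which is an external registration problem; for
cross-sections of a large vessel the dominant frame-to-frame ROI motion is
translational, and the phantom's is exactly so.

## Reproducibility statistics

Feature curves are compared on the normalized cycle fraction — heart rates
differ between acquisitions, so milliseconds are not comparable — and
curves with fewer frames are linearly upsampled to the finest grid with
endpoints preserved.

The ICC model is the two-way random-effects, absolute-agreement,
single-rating form: scanners and observers are exchangeable "raters" whose
systematic offsets *should* count against reproducibility (a scanner with a
consistent velocity bias is genuinely less interchangeable). The
consistency variant is selectable. Rating units pool subjects × planes ×
timeframes per feature; per-plane tables are available by filtering the
input. A ratings matrix with zero total variance is perfect agreement by
definition (ICC 1 with a degenerate flag). Category boundaries: 0.5 and
0.75 belong to the higher category, 0.9 itself is good (excellent requires
strictly more than 0.9). Selection takes the intersection of features at
least moderate in both the inter-scanner and inter-observer tables.

## Classification

The classifier is a ridge-penalized logistic regression (glmnet, α = 0,
default λ = 0.01) on z-scored features; the weak penalty keeps the fit
defined on linearly separable cohorts, where an unpenalized logistic model
diverges. Because no evaluation protocol is canonical for this design, the
report always carries both stratified 5-fold cross-validation (the headline
numbers) and resubstitution, each labeled; fold assignment is seeded.
Feature importance is the absolute standardized coefficient, ties broken
alphabetically. The positive class for F1 is aortic stenosis. When a
cohort is too small for every training fold to hold at least two subjects
per class, the report falls back to resubstitution with a warning.

## The synthetic phantom: what it does and does not emulate

The phantom provides closed-form velocity fields on a straight or arched
tube: Poiseuille, plug, helical (solid-body azimuthal rotation over a
parabolic axial profile), Gaussian jets (central, displaced, tilted,
triple) and a vortex (rotation-dominated with a weak axial plug). A
raised-cosine systolic pulse over the first 40% of the cycle with a 5%
diastolic tail modulates the field; no published waveform is canonical
here, and the analyses only require a realistic single-peaked systole.
All profiles are divergence-free in the continuum and — because their
in-plane dependence is at most linear or Gaussian-in-plane with constant
axial structure — their noiseless gridded samples are divergence-free to
machine precision on interior voxels, which the tests exploit.

Scanner differences are modeled as (i) a multiplicative velocity bias,
(ii) additive zero-mean Gaussian velocity noise with standard deviation
`noise_sigma_fraction × VENC` (default 2% of VENC, the scale of
phase-noise in routine acquisitions), and (iii) temporal resolution
(20–38 frames per cycle). Observer differences are smooth low-order
Fourier jitter of the contour radius (default 0.5 mm) plus a systematic
dilation/erosion bias. The default cohorts draw lumen radius 14 ± 1.5 mm,
control peak velocity 1.0 ± 0.15 m/s over parabolic/plug/helical profiles,
and stenosis peak velocity 2.8 ± 0.35 m/s over jet/vortex profiles —
values in the range reported for normal aortas and at least moderate
aortic stenosis.

The phantom deliberately does **not** emulate: velocity aliasing and phase
wrapping (preprocessing concerns), background phase offsets, k-space/MR
signal formation, wall motion or compliance, or Navier–Stokes-consistent
secondary flow. Consequently, passing tests demonstrate the correctness of
the measurement chain and its behavior under the modeled perturbations —
not that the features are robust against artifacts the phantom does not
contain.

## Problem sizes and numerical tolerances

The shipped analyses are sized for interactive use: demo cohorts of 8
subjects × 2–3 scanners at 20–38 frames, and the classification benchmark
with 30 + 30 subjects at 20 frames on a 2 mm grid, which together with the
default 1 mm MPR give ROI sizes of roughly 300–700 pixels per plane.
Texture features agree with independent brute-force enumeration oracles to
1e−8; trilinear resampling reproduces linear fields to 1e−10; the
WPD–angle duality holds to 1e−9; the ICC matches hand-computed ANOVA mean
squares to 1e−10. The discrete curl of the rigid-rotation field is exact
to 2% on interior voxels at 2 mm spacing (boundary stencils excluded).

## Known limitations

* Centerline extraction, lumen segmentation and MRI preprocessing are out
  of scope; inputs are assumed clean and unwrapped.
* The contour model (and `perturb_roi`) assumes star-shaped ROIs.
* ICC confidence intervals are not computed (point estimates and
  categories only), and scan–rescan / intra-observer designs are not
  modeled.
* The self-normalized vorticity map is scale-free by construction; studies
  needing absolute vorticity magnitudes should use the fixed-reference
  option and their own reference value.
* 3D (volumetric) texture families and filtered (wavelet/Laplacian)
  feature classes are intentionally absent.
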