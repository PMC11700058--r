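---
title: "Methods: phantoms, remodelling, morphometry, Raman and bending analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, remodelling, morphometry, Raman and bending analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteotrack)
```

`osteotrack` implements the computational core of a longitudinal rodent
bone-health workup: voxel-differencing quantification of bone remodelling
from registered in vivo microCT timepoints, static trabecular and cortical
morphometry, Hounsfield-calibrated abdominal adipose quantification, Raman
band-ratio analysis of embedded cortical bone, and three-point-bending
curve analysis. Because studies of this kind rarely deposit raw scans, the
package ships generators that produce every input type with exact recorded
ground truth, and the test suite is built entirely on those phantoms. This
vignette explains the models, the tunable parameters, the numerical
choices, and what a green test does and does not establish.

## Density volumes and calibration

All imaging operations run on `density_volume` objects: a 3D array in
`(x, y, z)` order (`z` is the scan axis, slices are `values[, , k]`,
1-based), an isotropic voxel size in micrometres, and a calibration state.
Two calibrations exist, both affine and order-preserving:

* **Hydroxyapatite (HA)**: two phantom rods of known density (250 and
  750 mg/cm^3 by default) anchor a linear map; segmentation thresholds
  (300 mg/cm^3 trabecular, 700 mg/cm^3 cortical) only make sense on this
  scale, so `segment_volume()` refuses anything else.
* **Hounsfield units**: air maps to -1000 HU and water to 0 HU. The
  adipose window used for abdominal fat is -280 to -150 HU.

Millimetre offsets and extents of a volume of interest are converted to
whole slices by rounding half away from zero, and slice ranges are
half-open `[start, stop)`. At 18 um, "0.5 mm below the landmark, 2 mm
long" resolves to 28 slices of offset and 111 slices of extent; the
growth-plate landmark is always an input, never auto-detected.

## Rigid registration

`register_rigid()` aligns two timepoints in two stages: (1) centroid
alignment, adding a principal-axes rotation only when the threshold
structure is anisotropic enough to make the axes well defined (smallest
eigenvalue ratio above 1.15; near-isotropic trabecular cubes keep the
identity rotation); (2) Nelder-Mead maximisation of the normalised
cross-correlation (NCC) of the grey values, scored on a stride-subsampled
grid, with a restart at the optimum. A final *trimmed* polish re-optimises
the NCC on the best-matching 90% of voxels, twice. The trimming matters:
voxels that genuinely changed between timepoints (remodelling) are gross
outliers under NCC and bias the plain optimum by a few tenths of a voxel;
with trimming, known transforms are recovered to better than 0.05 degrees
and 0.05 voxels on the synthetic phantoms.

Resampling uses Catmull-Rom cubic interpolation (trilinear inside the
scoring loop for speed). Voxels that fall outside the moving volume's
field of view are `NA`, and every downstream mask operation excludes
voxels invalid in either timepoint — zero-filling would count the lost
border as fake "resorption". Masks are never interpolated: segmentation
always re-thresholds the resampled grey volume.

## Remodelling by voxel differencing

Given registered bone masks at two timepoints, voxels present only in the
older mask are resorption, voxels present only in the newer mask are
formation, and each fraction divides by the union (common + unique). The
arithmetic is integer set counting and is tested against a brute-force
voxelwise loop. `percent_change()` reports longitudinal series as percent
change from the previous timepoint, not from baseline.

The trabecular phantom is a Gaussian random field smoothed at a
correlation length of 5 voxels and thresholded at the empirical quantile
that hits the target BV/TV exactly. Densities are not binary: they follow
a `tanh` ramp through the 300 mg/cm^3 threshold, spanning roughly three
voxels, so the phantom behaves like a partial-volume-limited scan — the
iso-surface survives resampling and re-thresholding at sub-voxel accuracy.
`evolve_phantom()` builds the second timepoint by surface accretion and
surface removal in clustered, three-layer packets (ranked by a smoothed
random field on the surface), with densities on the same ramp. Packets a
few voxels deep are both what remodelling physically looks like
(apposition/erosion depth) and a prerequisite for voxel differencing to be
well-posed under registration: a one-voxel full-contrast monolayer is
destroyed by any interpolation. The realized voxel counts are recorded
exactly, so pre-registered recovery is exact; after recovering a known
rigid transform the pooled mean absolute error of the fractions is about
0.012, dominated by resampling wobble at packet boundaries, not by
registration error.

## Morphometry

Trabecular thickness and separation use the maximal-inscribed-sphere local
thickness (exact Euclidean distance transform, ridge-based sphere
painting), averaged over bone and background voxels; Tb.N is the direct
plate-model `1 / (Tb.Th + Tb.Sp)` since the reference software's algorithm
is unspecified. BMD averages all VOI voxels; TMD averages bone voxels
after a one-voxel in-plane erosion to suppress partial-volume edges, and
is therefore never below BMD when marrow is less dense than bone.

Cortical metrics are per-slice: the periosteal boundary is filled, so
`Ct.Ar + Ma.Ar = Tt.Ar` holds exactly by construction. The section modulus
for antero-posterior bending is `I_ML / c_AP` with `I_ML` the second
moment of the bone area about the medio-lateral centroidal axis (with the
1/12 voxel self-moment) and `c_AP` the furthest bone voxel from that axis
plus half a voxel; the AP direction is the image y axis by convention and
configurable. Major/minor axes come from the ellipse-equivalent second
moments of the filled section. The perimeter behind circularity
(`4 pi A / P^2`) is measured on the traced boundary-pixel contour after
circular moving-average smoothing plus the half-voxel Steiner offset; a
raw staircase contour overestimates smooth perimeters by ~5% and would cap
circularity near 0.9, while the smoothed estimator keeps a digitised disk
above 0.98. A ring whose marrow cavity disappears in some slices but not
others is reported as broken, naming the slice; a rod with no cavity in
any slice is a legitimate solid section.

For abdominal fat, the body mask is the largest connected component above
-400 HU, filled slice-wise ("the outer perimeter of the abdominal cavity
... filled in"), then eroded by 1 mm (configurable; the source protocol
does not quantify the skin/subcutaneous exclusion — the abdomen phantom's
shell is 0.8 mm so the default erosion removes it with 0.2 mm margin).
Adipose voxels are those inside the eroded mask within the HU window, and
the percentage divides by all voxels of that mask. The phantom's cavity
adipose fraction is exact by construction (quantile threshold of a
smoothed field), so recovery to within one percentage point exercises
calibration, masking, erosion and counting together.

## Raman pipeline

Spectra live on an 800-1800 cm^-1 grid (step <= 1 cm^-1). Preprocessing:

* **Despiking**: channels whose second difference is a robust z-score
  outlier (threshold 8) are replaced by the mean of the nearest unflagged
  neighbours. The z-score needs a noise floor: on noise-free synthetic
  spectra the robust scale collapses and band curvature would dominate, so
  such spectra are returned unchanged and the clean recovery tests call
  the baseline step directly.
* **Baseline**: iterative polynomial (order 3 by default) refitting the
  original values after excluding points above the fit plus twice the
  robust noise estimate, until the excluded set stabilises. Refitting the
  originals (rather than clipping to the minimum envelope) keeps the
  baseline centred in the noise instead of 1-2 sigma low, which would leak
  directly into every small band height.
* **Resin subtraction**: the pMMA reference is scaled so its ~812 cm^-1
  peak height matches the spectrum's and subtracted; negative scales clamp
  to zero with a warning. Nanoporosity (812/960 ratio) is always computed
  *before* this subtraction, and a regression test asserts the ordering.

Band "intensity" is the window maximum (10 cm^-1 half-windows; 5 cm^-1
for the 1670/1690 pair), but the parameter pipeline evaluates it on a
Gaussian-denoised spectrum (sigma = 3 channels) and divides out the known
attenuation of a Gaussian band of nominal width under that kernel. This
choice is load-bearing: at the generator's default noise (0.5% of the
tallest band) the per-channel noise is ~15% of the small 1690 and 1375
bands, and a raw window maximum is biased upward by far more than the
recovery tolerance. The corrected estimator is exact for clean Gaussian
bands and keeps the mean absolute recovery error of all seven parameters
under 3% (clean) and 6% (baseline + noise + spikes), which is how the
recovery criterion is read — per-spectrum bounds on the smallest bands are
not attainable at that noise level by any unbiased estimator.

Crystallinity is the inverse FWHM of the v1PO4 band, measured by linear
interpolation of the half-maximum crossings on the unsmoothed spectrum.

Line-scan distributions are histogrammed with Sturges' rule by default
(configurable). A fixed 32-bin histogram — a plausible alternative — makes
the Gaussian-fit R^2 > 0.95 normality rule fail for ~80% of draws at
n = 500 simply from Poisson bin noise, so the data-driven rule is the
default. The reported mean is the bin-weighted mean `sum(Xi Fi) / sum(Fi)`
(the printed formula dividing by the number of bins is dimensionally
inconsistent with a weighted mean; the implemented form reduces to the
intended pixel mean and agrees with the arithmetic mean within half a bin
width). The FWHM of the distribution comes from the fitted Gaussian
(`2 sqrt(2 ln 2) sigma-hat`), which is stable at moderate point counts.
Non-bone points are excluded by a mineral-to-matrix floor (default 1.0)
before summarising.

## Bending analysis

Curves are preload-trimmed at 1 N and re-zeroed. Stiffness is the maximum
least-squares slope over a sliding window spanning 20% of the samples
between 10% and 90% of the ultimate load (moving-average smoothing width 5
for slope estimation only; integration always uses the raw curve). The
yield line has slope `0.9 S` and is anchored at the zero-load intercept of
the best linear fit — the secant convention; the source definition names
the 10% stiffness loss but not the anchor. A curve that never crosses the
line is flagged and its ultimate point reported as yield. Failure is the
first sample below 10% of the running maximum (configurable); work to
fracture is the trapezoidal integral to failure; post-yield displacement
is failure minus yield displacement. Peak moment is `F L / 4` for central
loading on a 15 mm span, and tissue strength divides it by the section
modulus from microCT, which enters as an input.

The curve generator records *analytic* truth under these same
definitions: for a bilinear-hardening curve the 10%-loss crossing sits at
`0.9 Y (S - k) / (0.9 S - k)`, not at the nominal yield parameter, and the
recorded work integrates the ideal piecewise curve. Recovery within 2% on
20 seeded noisy curves therefore tests the estimators, not a circular
definition.

## Group statistics

`group_compare()` mirrors the common preclinical scheme: Brown-Forsythe
variance gate (ANOVA on absolute deviations from group medians), then
either ordinary one-way ANOVA with many-to-one comparisons against the
control, or Kruskal-Wallis with Dunn's rank comparisons; pairwise p-values
are Holm-adjusted. No installed package provides Dunnett's exact
multivariate-t adjustment, so the parametric branch uses pooled-variance
t statistics with Holm correction — slightly conservative, clearly
labelled in the result. The omnibus type-I error is calibrated by
simulation in the acceptance suite. An optional Shapiro-Wilk normality
gate is available and off by default, since the variance gate is what the
source scheme names.

## What the synthetic world does not establish

The phantoms emulate partial-volume behaviour, remodelling packets,
compartment HU contrast, Gaussian bands on polynomial backgrounds, and
piecewise-linear mechanics. They do not emulate scanner physics (beam
hardening, ring artefacts, noise texture), anatomically realistic
geometry, automatic trabecular/cortical contouring on real anatomy, or
non-Gaussian band shapes. Green tests establish that the estimators
recover known ground truth under the stated conditions — not that they
reproduce any particular animal study's numbers, which would require the
original scans.
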