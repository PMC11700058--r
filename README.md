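# osteotrack

Longitudinal microCT bone remodelling, static morphometry, Raman
band-ratio analysis and three-point-bending mechanics for small-animal
bone studies — with synthetic phantoms carrying exact ground truth, so the
whole pipeline is testable without scanner data.

## What it is for

Preclinical bone studies (for example, tracking skeletal effects of diet,
surgery, pregnancy or drugs in rats) combine four measurement streams:

1. **Longitudinal in vivo microCT**: two registered timepoints are
   compared voxel by voxel. Voxels present only in the older scan are
   *resorption*, voxels present only in the newer scan are *formation*,
   and each fraction is the unique-voxel count over the union:
   `BF = |new \ old| / |old ∪ new|`, `BR = |old \ new| / |old ∪ new|`.
   Series are reported as percent change from the previous timepoint.
2. **Static morphometry**: BV/TV, Tb.Th/Tb.Sp/Tb.N by maximal-sphere
   local thickness, BMD/TMD, cortical areas (`Ct.Ar + Ma.Ar = Tt.Ar`),
   Ct.Th, ellipse-equivalent axes, circularity `4πA/P²`, and the section
   modulus `Z = I_ML / c_AP` for antero-posterior bending. Abdominal
   adipose tissue is segmented in the calibrated HU window (−280, −150)
   after excluding the subcutaneous shell.
3. **Raman spectroscopy** of embedded cortical bone: despiking, iterative
   polynomial baseline removal, pMMA resin subtraction at ~812 cm⁻¹, and
   seven compositional parameters (v1PO4/Amide I, v3CO3/v1PO4,
   nanoporosity — computed *before* resin subtraction —, 1/FWHM(v1PO4),
   872/854, 1375/1245, 1670/1690), plus line-scan distribution statistics
   (weighted mean, Gaussian-fit FWHM and R²).
4. **Three-point bending**: stiffness, yield by the 10%-stiffness-loss
   rule, ultimate load, work to fracture, post-yield displacement, peak
   moment `F·L/4` and tissue strength `M/Z` in MPa.

Every input type has a generator (`make_trabecular_phantom()`,
`evolve_phantom()`, `make_cortical_phantom()`, `make_abdomen_phantom()`,
`make_raman_spectrum()`, `make_load_curve()`) that records the exact
realized truth, and the test suite checks that the analysis recovers it.

## Worked example

```r
library(osteotrack)

# a trabecular phantom and an evolved second timepoint with known truth
ph <- make_trabecular_phantom(shape = 48, target_bvtv = 0.25, seed = 7)
ev <- evolve_phantom(ph, formation_fraction = 0.10,
                     resorption_fraction = 0.05, seed = 3)
rem <- remodel_pipeline(ev$old_volume, ev$volume, register = FALSE)
rem
#> <remodel_result> union 30721 voxels: formation 0.1000, resorption 0.0500

# cortical annulus: closed forms are pi-formulas
cp <- make_cortical_phantom(outer_radius_mm = 2, inner_radius_mm = 1,
                            voxel_size_um = 20, n_slices = 3)
cm <- cortical_metrics(cp$volume)
round(c(tt_ar = cm$tt_ar_mm2, ct_ar = cm$ct_ar_mm2,
        z = cm$section_modulus_mm3, circ = cm$circularity), 4)
#>   tt_ar   ct_ar       z    circ
#> 12.5712  9.4272  5.8949  0.9973
# analytic: Tt.Ar = 4*pi = 12.566, Ct.Ar = 3*pi = 9.425, Z = 5.890

# bending curve with recorded analytic truth
cv <- make_load_curve(stiffness = 669, yield_load = 154,
                      ultimate_load = 211, seed = 4)
bd <- bending_analysis(cv, span = 15, section_modulus = 3.19)
round(c(stiffness = bd$stiffness, yield = bd$yield_load,
        ultimate = bd$ultimate_load, strength = bd$tissue_strength), 1)
#> stiffness     yield  ultimate  strength
#>     669.4     159.0     211.6     248.8
```

The remodelling fractions equal the generator's realized truth exactly
(pre-registered masks are compared by integer set counting); the annulus
metrics sit within 2% of the π-formulas at this voxel size; the bending
numbers recover the generator's analytic truth (the 10%-loss yield of a
bilinear-hardening curve is `0.9·Y·(S−k)/(0.9·S−k)`, 159.1 N here, not
the nominal 154 N).

## End-to-end pipeline and acceptance script

`run_pipeline(demo_config(seed = 1))` generates three synthetic cohorts,
runs every stage (remodelling, morphometry, adipose, Raman, bending,
group statistics with a Brown–Forsythe gate and control-vs-group post
hocs, cross-metric regression) and writes `remodel.csv`,
`raman_params.csv`, `biomech.csv`, `metrics.csv`, `stats.csv` and
`run.log` into the configured output directory, deterministically for a
given seed.

`scripts/acceptance.R` re-runs that full pipeline from scratch against
the installed package and writes its JSON manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — volume core (calibration, segmentation, VOI, NIfTI+JSON I/O),
  rigid registration, remodelling, morphometry, Raman, bending, report.
- `src/` — Rcpp kernels: exact Euclidean distance transform, local
  thickness, connected components.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
- `vignettes/methods.Rmd` — the models, parameter choices, numerical
  conventions and limitations.
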