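# petmatch

Spatial concordance of SUV<sub>max</sub> and ADC<sub>min</sub> in PET/MRI
lesion analysis.

## The problem

In FDG-PET the hottest voxel of a lung tumor (the maximum standardized
uptake value, SUV<sub>max</sub>) and in diffusion-weighted MRI the most
diffusion-restricted voxel (the minimum apparent diffusion coefficient,
ADC<sub>min</sub>, in 10⁻⁶ mm²/s) are both used as aggressiveness
markers, and ADC<sub>min</sub> is sometimes proposed as a surrogate for
SUV<sub>max</sub>. Whether the two markers are numerically correlated
turns out to depend on whether they are *spatially* concordant: whether
the SUV<sub>max</sub> voxel and the ADC<sub>min</sub> voxel sit in the
same part of the tumor once the two scans are co-registered.

`petmatch` implements that spatial-concordance analysis as a reusable,
tested pipeline for radiology / nuclear-medicine researchers:

- axis-aligned 3D volumes with NIfTI I/O, world-coordinate geometry and
  resampling between PET and MRI grids;
- PET VOI segmentation by an iterative adaptive threshold
  `T = bg + β·(peak − bg)` (β = 0.41 by default), with metabolic tumor
  volume V_PET and maximum 3D diameter;
- lesion delineation on b = 800 s/mm² DWI, mask transfer onto the ADC
  map, and automated histogram refinement that removes near-zero ADC
  outliers from aerated lung at the lesion rim;
- rigid MRI→PET translation estimation, inter-reader registration
  differences, and the spatial-match threshold as the one-sided 95%
  upper limit `mean + 1.645·sd`, rounded to integer mm (6.0 ± 3.5 mm
  differences give the canonical 12 mm);
- the inter-extremum distance `D = ‖x_SUVmax − (x_ADCmin + t)‖` with
  match (D ≤ threshold) / mismatch classification, plus cross-parameter
  statistics in a 1 cm³ sphere (radius 6.2035 mm) restricted to the
  lesion: ADC@SUV<sub>max</sub>, ADC<sub>min</sub>@SUV<sub>max</sub>,
  ADC<sub>mean</sub>@SUV<sub>max</sub>, SUV@ADC<sub>min</sub>,
  SUV<sub>max</sub>@ADC<sub>min</sub>, SUV<sub>mean</sub>@ADC<sub>min</sub>;
- cohort statistics: Pearson/Spearman correlations stratified by match
  status and tumor size (3 cm cutoff), unpaired t comparisons, and
  Bland–Altman interobserver agreement;
- a synthetic phantom-cohort generator with full ground truth
  (ellipsoidal lesions, Gaussian SUV focus and ADC trough at a
  controllable offset, rim ADC outliers, reader-translation noise, and
  a tunable SUV<sub>max</sub>–ADC<sub>min</sub> coupling ρ), used to
  validate every stage against known answers;
- a bundled plain-text table of a 10-patient simultaneous PET/MRI
  cohort with per-reader measurements.

## Worked example

```r
library(petmatch)

# a phantom lesion: 19.5 mm between the SUV focus and the ADC trough,
# MRI frame displaced by (4, 6, -2) mm
spec <- lesion_spec(semi_axes = c(24, 18, 14),
                    suv_focus = c(7.5, 6.23, 0),
                    adc_focus = c(-7.5, -6.23, 0),
                    translation = c(4, 6, -2),
                    rim_outlier_frac = 0.05, seed = 19)
les <- make_lesion_pair(spec)

res <- analyze_lesion_pair(les$suv, les$adc, les$dwi,
                           translation_vector(4, 6, -2))
res$record[, c("suv_max", "adc_min", "v_pet_cm3", "v_mri_cm3",
               "distance_mm", "match")]
#>    suv_max  adc_min v_pet_cm3 v_mri_cm3 distance_mm    match
#> 1 8.147755 520.8621    24.525   24.5726     16.4485 mismatch
```

The measured distance (16.4 mm) recovers the generated 19.5 mm offset
to within a PET voxel diagonal (7.8 mm), both modality volumes agree
with the analytic ellipsoid volume of 25.3 cm³, and the lesion is
classified as a spatial mismatch at the 12 mm threshold. A whole
cohort runs the same way:

```r
sc  <- cohort_scenario(n = 15, rho = -0.8, offset_range = c(0, 6),
                       n_readers = 2, seed = 1)
out <- run_pipeline(run_config(mode = "synthetic", scenario = sc,
                               threshold = "derived"))
subset(out$correlations, stratum == "match" &
                         pair == "suv_max/adc_min")
#>    reader stratum            pair  n        r_p        p_p        r_s         p_s
#> 5       1   match suv_max/adc_min 12 -0.6973716 0.01170127 -0.8111888 0.001363315
#> 29      2   match suv_max/adc_min 13 -0.6528998 0.01554844 -0.7032967 0.007318570
```

With a generating coupling of ρ = −0.8 the match-stratum Pearson
coefficient comes back strongly negative for both emulated readers,
reproducing the mechanism by which spatial mismatch destroys the
numeric SUV–ADC correlation. (`threshold = "derived"` recomputes the
match threshold from that cohort's own two reader translation sets —
here 9 mm, since two emulated readers differ only by the generator's
2.5 mm per-axis noise.)

The bundled simultaneous-cohort table is summarized with:

```r
cohort_summary()$means[c("suv_max", "dist_r1")]
#> suv_max dist_r1
#>    10.7    22.6
verify_reference_cohort()   # every summary against its reference value
```

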