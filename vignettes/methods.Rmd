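---
title: "Methods: spatial concordance of SUVmax and ADCmin in PET/MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial concordance of SUVmax and ADCmin in PET/MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmatch)
```

## The analysis in one paragraph

A lung tumor imaged with FDG-PET and diffusion-weighted MRI yields two
candidate aggressiveness markers: the hottest PET voxel (SUVmax) and
the most diffusion-restricted voxel of the ADC map (ADCmin, in
10⁻⁶ mm²/s). `petmatch` measures whether those two voxels are
*spatially* concordant: the PET lesion is segmented, the ADC region of
interest is delineated on the b = 800 s/mm² DWI and cleaned of
low-value outliers, the two extremum voxels are located, the MRI
position is mapped into the PET world frame with a rigid translation
`t`, and the distance `D = ‖x_SUVmax − (x_ADCmin + t)‖` is compared
with a threshold derived from how accurately two independent readers
can co-register the scans at all. Lesions split into spatial match
(`D ≤` threshold) and mismatch groups, and all numeric SUV–ADC
correlations are then computed per stratum.

## Geometry and data model

Volumes are axis-aligned scalar grids with per-axis spacing and a
world origin; the world position of voxel `(i, j, k)` (1-based) is
`origin + (index − 1) · spacing` (voxel-center convention, axes
ordered x, y, z). Whether the original workstations used voxel-center
or corner coordinates is unknowable from the outputs; the center
convention is an internal choice and is applied consistently on both
grids, so inter-extremum distances are unaffected by it. Only diagonal
(axis-aligned, positively oriented) NIfTI affines are accepted: the
procedure being modelled uses pure translations, so rotations would
only arise from data this pipeline is not meant for, and rejecting
them loudly is safer than silently reorienting. NIfTI headers store
geometry as float32; round trips therefore preserve spacing and origin
to float32 precision and values to float32 precision (masks, stored as
uint8, round-trip exactly).

Typical grids are anisotropic — PET around 5 × 5 × 3.27 mm, EPI-DWI
around 2.6 × 2.6 × 5 mm — and all morphology (shells, spheres,
diameters) is therefore computed in millimetres, never in voxel
counts.

## PET VOI segmentation

The segmentation is an iterative source-to-background adaptive
threshold. From a seed inside the lesion, the initial threshold is
`β · peak` with the peak taken within 10 mm of the seed; each
iteration keeps the 26-connected component containing the seed of
voxels with `SUV ≥ T`, re-estimates the background `bg` as the mean
SUV in a shell (default width 10 mm) around the current mask, sets
`T ← bg + β (peak − bg)`, and stops when the mask stabilizes (default
cap 25 iterations; non-convergence returns the last mask with a
warning). The published family of adaptive-threshold methods this
emulates is not fully specified by its clinical description, and the
workstation variant actually used is unknown; `β` (default 0.41) and
the shell width are therefore exposed configuration, not a claim about
the original implementation. A seed whose uptake does not exceed the
local background raises a segmentation failure rather than growing a
background region.

From the mask follow the metabolic tumor volume `V_PET` (voxel count ×
voxel volume, cm³) and the maximum 3D diameter (largest pairwise
distance between voxel centers, computed over boundary voxels, which
contain all extremal points).

## ADC ROI: delineation, transfer, histogram refinement

Clinically the lesion is contoured manually on the b = 800 images and
copied onto the ADC map. The automated surrogate thresholds the DWI
volume by Otsu's method inside a bounding box around the seed (ties in
the between-class variance break toward the lower threshold, i.e. the
larger foreground) and keeps the seed's 26-connected component;
externally supplied NIfTI masks can be used instead. Transfer to the
ADC map is an identity copy on a shared grid, else nearest-neighbour
resampling.

ADC maps of lung lesions are contaminated at the rim by aerated lung,
which produces near-zero ADC voxels that would corrupt ADCmin. The
manual "inspect the ROI histogram and remove low outliers" step is
automated deterministically: bin the masked values (bin width
50 · 10⁻⁶ mm²/s, bins anchored at 0), find the widest run of empty
bins strictly below the histogram mode (ties between equally wide runs
go to the run nearest the mode), and remove all voxels strictly below
that run's upper edge. Because genuine tumor ADC sits well above zero,
the run between 0 and the true low tail is normally the widest, so the
rule removes rim outliers and never the mode; with no empty bin below
the mode, an optional percentile floor (default 1%) applies. The
refined mask is always a subset of the input and can only raise
ADCmin; a refinement that would empty the mask is an error.

## Registration accuracy and the match threshold

Reader alignment is modelled as a pure 3D translation mapping MRI
world coordinates into the PET frame. The automated estimate is the
difference of mask centroids, optionally refined by maximizing
normalized cross-correlation over a local translation grid (±10 mm,
2 mm steps, then ±2 mm at 1 mm). The registration accuracy of a
two-reader setup is summarized by the per-case Euclidean norms of the
difference of the readers' vectors; the spatial-match threshold is the
one-sided 95% upper limit of that distribution, `mean + 1.645 · sd`,
rounded half-up to integer millimetres. Reading the "95% upper limit"
as a one-sided normal quantile of the *difference distribution* is an
interpretation: it is the only standard formula that maps differences
of 6.0 ± 3.5 mm to the canonical 12 mm threshold (a mean-CI would
not), and it has the right meaning — separations below it cannot be
distinguished from registration error. The formula is documented and
the threshold can instead be fixed by the user.

## Extrema, distance, sphere statistics

Extrema are exact over masked voxels, with ties broken toward the
lowest linearized index (x fastest) and the tie count recorded, so
results are deterministic and auditable. The cross-parameter
statistics use a sphere of *volume* 1 cm³ — radius
`(3V/4π)^(1/3) = 6.2035 mm` — not radius 1 cm; the literal unit
reading. Spheres are restricted to the lesion mask so background or
rim voxels never enter the statistics (whether the original analysis
clipped its spheres to the tumor is unstated; restricting is the
conservative choice and gives the invariants
`ADCmin ≤ ADCmin@SUVmax` and `SUVmax ≥ SUVmax@ADCmin` by
construction). An empty sphere–mask intersection falls back to the
single nearest in-mask voxel with a warning. Cross-modal positions are
converted with the translation and sampled by nearest voxel — the
clinical quantities are voxel values, not interpolants.

## Cohort statistics

Pearson and Spearman coefficients are computed by `stats::cor`;
two-sided p-values for both use the t transform
`t = r √((n−2)/(1−r²))` with `n − 2` degrees of freedom (exact for
Pearson; for Spearman this large-sample approximation is used
deliberately so both coefficients are treated identically, and it is
why Spearman p-values differ slightly from `cor.test`'s exact small-n
method). Strata are: all lesions, spatial match, spatial mismatch,
diameter ≤ 3 cm, and diameter > 3 cm split by match status; strata
with n < 3 (or zero variance) produce NA rows rather than errors so
cohort runs never abort. Group comparisons use Student's pooled
t-test (Welch behind a flag) with a degenerate-variance guard: zero
pooled variance yields t = 0, p = 1 for equal means and a large finite
t with p ≈ 0 otherwise, flagged as degenerate. Bland–Altman agreement
reports the bias, 1.96·sd limits, and the count of pairs strictly
outside the limits. Comparisons against printed reference tables
round half-up to the displayed precision, matching how clinical
tables are typeset (base `round` is half-to-even).

## The synthetic phantom generator

No public per-voxel data exist for this analysis, so validation rests
on phantoms with known ground truth. Each lesion is an ellipsoid
(semi-axes in mm) on near-zero lung background; inside it, SUV is a
plateau plus a Gaussian focus at `p_S` and ADC a plateau minus a
Gaussian trough at `p_A` (widths default to one third of the smallest
semi-axis), so both extrema are smooth, unimodal and have unambiguous
true positions with `|p_S − p_A|` the true offset. The SUV plateau is
part of the model because a bare background-plus-bump lesion would
leave the adaptive threshold nothing to segment but the bump: the
plateau (default 5, amplitude default 4, background 0.4) makes the
whole ellipsoid the metabolic volume, as in a real tumor, while
keeping the converged threshold below the plateau. ADC and DWI are
rendered on the MRI grid in a frame displaced by the true translation;
a stated fraction of lesion-boundary ADC voxels is replaced by uniform
values in [0, 100) · 10⁻⁶ mm²/s to emulate aerated-lung rim outliers;
additive Gaussian noise is used (magnitude bias of MR noise is out of
scope — noise here only needs to perturb extrema realistically).
Defaults (ADC plateau 1300, trough depth 800, noise sd 0.1 SUV /
30 ADC / 2 DWI) put SUVmax near 9 and ADCmin near 500, the ranges
reported for lung tumors.

Cohorts draw diameters from a truncated normal (defaults mean 51 mm,
sd 31 mm, range 16–120 mm, emulating a surgical lung-tumor series),
random offset directions with offsets capped so both foci stay inside
the lesion, and per-lesion SUV amplitude and ADC trough depth from a
bivariate normal whose correlation is `−ρ`, so the cohort-level
SUVmax–ADCmin correlation targets `ρ` (a deeper trough lowers ADCmin).
Truncation of amplitudes/depths to physical ranges slightly attenuates
the realized correlation, which is why recovery is asserted as a sign,
not a magnitude. Each reader is the true translation plus isotropic
per-axis Gaussian noise (default sd 2.5 mm). Seeding: all cohort-level
draws happen under the master seed; lesion `i`'s voxel rendering uses
the derived seed `master + i`, so cohorts are reproducible and
individual lesions can be regenerated in isolation.

What the generator does **not** emulate: respiratory motion, PET
point-spread blur and partial-volume effects, EPI distortion, Rician
noise bias, multi-focal or cavitating tumors, and any rotational
misregistration. Passing phantom tests therefore shows the *pipeline
arithmetic* is correct (geometry, segmentation, refinement, distances,
statistics), not that the clinical acquisition chain is modelled.

## Validation problem sizes

The test-suite and acceptance checks use: exhaustive-scan oracles for
extremum and sphere statistics on grids up to 64³; 100 noise-free
phantoms with offsets uniform in [0, 40] mm for distance recovery
(asserted RMSE within one PET voxel diagonal, 7.79 mm) and for the
cross-modal volume correlation (asserted r > 0.95); and 100 seeded
cohorts of 15 matched lesions at ρ = −0.8 for coupling-sign recovery
in the match stratum (asserted in at least 95% of seeds). These sizes
give stable Monte-Carlo estimates while keeping a full run on a single
CPU in a few minutes.

## Known limitations

- Pure-translation registration only; rotations and deformations are
  out of scope by design.
- The adaptive-threshold β is a tunable stand-in for an unpublished
  workstation implementation; absolute V_PET values depend on it even
  though cross-modal volume *correlation* does not.
- The histogram gap rule is a deterministic surrogate for a manual
  step; histograms whose genuine low tail is sparser than the rim
  outlier band could in principle be over-trimmed, though the
  widest-gap rule makes this rare.
- Printed-table comparisons inherit the tables' own rounding; values
  are reproduced at displayed precision, not beyond it.
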