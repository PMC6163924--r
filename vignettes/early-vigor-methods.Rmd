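---
title: "Assessing early plant vigor from images and spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing early plant vigor from images and spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`earlyvigor` compares measurement routes for early vigor of winter wheat
stands — image-based canopy cover, narrow-band vegetation indices, an
emulated two-band active sensor, linear spectral unmixing, and an
exhaustive two-band index screen — against the reference traits dry
weight (DW, kg·ha⁻¹), nitrogen content (NC, %), nitrogen uptake
(Nup = DW·NC/100, kg·ha⁻¹) and canopy cover (CC, fraction). This
vignette explains the models, the tunable parameters, the synthetic data
the package validates itself on, and the design choices made where more
than one defensible reading existed.

## Canopy cover from RGB images

A quadrat image is converted to HSV (standard hexcone transform,
`grDevices::rgb2hsv`; hue reported in degrees, set to 0 where saturation
is 0). A pixel is vegetation iff hue lies in a window, saturation is at
least `sat_min` and value at least `val_min`; canopy cover is the exact
vegetation-pixel fraction. Defaults are hue ∈ [60°, 180°],
`sat_min = 0.15`, `val_min = 0.05`: the window brackets plant greens, the
saturation floor rejects gray or washed-out soil, and the value floor
only removes near-black pixels. Field workflows tune thresholds by eye
per measurement day; `calibrate_thresholds()` formalizes that step as a
grid search over (hue_min, hue_max, sat_min) maximizing mean pixel-wise
Jaccard overlap with reference masks, so the "manual" step becomes
reproducible. Ties go to the wider window, then the lower saturation
floor — the most inclusive rule among equals.

Cropping to the marked quadrat is a bounding-box crop of the four corner
points, without perspective rectification: the target imagery is
near-nadir and a warp would resample pixels, breaking exact pixel
counting. Morphological cleanup is off by default; an optional
minimum-component-size filter (4-neighborhood flood fill) is available
for real photographs with sensor speckle. PNG is the recommended format;
JPEG compression makes pixel counts quality-dependent.

## Vegetation indices

Spectra live on a strictly increasing grid, nominally 3.3 nm from 300 to
1140 nm. Index definitions name integer nominal bands; these are
resolved by *nearest-band lookup without interpolation*, matching how
narrow-band indices are computed from array spectrometers. Exact ties
break toward the lower wavelength. Nine indices are implemented
(`vi_definitions()`): NDVI, NDRE, PRI, WBI, MTCI, MCARI, EPVI, ATSAVI
and REIP. Two choices deserve note:

- **REIP** uses the Guyot–Baret linear-interpolation form
  `700 + 40·(((R668 + R778)/2 − R698) / (R738 − R698))`. Printed
  renderings of this formula are typographically ambiguous about
  precedence; the interpolation form is the one the red-edge literature
  defines, and it is what the package computes.
- **ATSAVI** hard-codes the standard adjustment constants (1.22, 0.03,
  soil factor 0.23) exactly as conventionally printed, without local
  soil-line calibration.

Zero denominators (e.g. REIP when `R738 = R698`) raise a classed
condition carrying the index name; `index_table()` converts these to
missing cells with a `missing_reason`, never silently dropping or
imputing them.

The active-sensor emulation (`greenseeker_ndvi()`) averages reflectance
over unweighted ±12.5 nm boxcars centered at 656 and 774 nm — the
published band centers and approximate width of the sensor class — and
returns the normalized difference. The true diode response function is
unpublished, so a boxcar is the assumption; the instrument's active
illumination and field-of-view geometry are not modeled.

## Linear spectral unmixing

The mixed spectrum is regressed by OLS on the soil and vegetation
endmember spectra *without an intercept*, and cover is estimated as
`β_veg / (β_veg + β_soil)`. The no-intercept default follows from the
estimator itself: with an intercept, a constant offset can absorb an
arbitrary share of the soil signal and the coefficient ratio loses its
meaning. An intercept is available as an option for sensitivity
analysis. Coefficients are deliberately unconstrained — no
non-negativity, no sum-to-one — so estimates outside [0, 1] remain
visible as diagnostics of endmember mismatch rather than being clipped
away. Bands below 400 nm are excluded by default (scattering-dominated),
and near-collinear endmembers (condition number > 1e8) raise an error
instead of returning an unstable ratio.

Useful identities that the tests exercise: exact recovery on noiseless
mixtures for any cover; swapping the endmember roles maps the estimate
c → 1 − c; a common positive rescaling of all three spectra leaves the
estimate unchanged; and a brightness-inflated soil endmember biases
sparse-canopy estimates relatively more than closed-canopy ones — the
soil-background failure mode that motivates image-based cover in the
first place.

## The band-pair screen ("contour maps")

For one trait and date, every pair of grid bands ≥ 400 nm defines a
normalized difference index; its squared Pearson correlation with the
trait across plots fills a symmetric matrix with an undefined diagonal.
Entries are undefined (NA) when the index is constant across plots or
any plot has a zero band sum; undefined entries are excluded
pairwise-complete from every aggregate and never imputed as zero —
the published screens do not state a rule, and imputation would
systematically drag means toward zero.

Across dates, matrices aggregate element-wise into a mean matrix and a
CV matrix (sample, n−1, standard deviation over mean). The reported
optimum is the argmax of the *mean* matrix, with its own CV
(`cv_at_best`), not the minimum CV. Argmax ties break toward the pair
with the smaller band distance, then the lower second wavelength —
arbitrary but deterministic. Band pairs classify into spectral groups by
VIS = 400–680, red edge = 680–740, NIR = 740–1140 nm, boundaries
belonging to the lower-named region.

Only the upper triangle is computed (the matrix is symmetric by
construction); the full matrix is materialized for plotting and export.

## Summary arithmetic and rounding

`build_summary()` correlates every method with every trait per date
(squared Pearson, two-sided p from the t transform with n − 2 df, stars
at 0.05/0.01/0.001 with strict inequalities, no multiple-testing
correction — the screening context reports raw per-correlation
significance). Mean and CV across dates include non-significant values
at their raw magnitude but require a value on every date: cells that are
truly missing propagate, because a mean over an unknown subset is not
reproducible.

Display rounding is half-up to two decimals (`round_half_up()`; R's
`round()` rounds half to even, which changes cells like 0.605). The gain
ratios of the best band-pair index over (a) the best of *all* other
methods and (b) the best of the nine established indices follow a mixed
policy that the shipped reference table pins down: per-date ratio cells
are computed from values at display precision, while mean-column ratios
divide by *unrounded* means. Applying this arithmetic to the published
per-date cells (`reference_summary()`) reproduces the published mean, CV
and ratio cells for every row with four printed values — except two
second-date best-sensor ratio cells that are internally inconsistent
with any single scan rule in the source table itself; the acceptance
test documents and excludes exactly those two. The published
NC mean-column ratio is likewise unreproducible under the stated
missing-value policy (its denominator row has only two printed dates)
and is reported as missing here.

## The synthetic trial

`trial_design()` builds a 36-plot split factorial (a nitrogen block:
2 N rates × 3 cultivars × 3 replicates; a density block: 3 sowing
densities × 2 cultivars × 3 replicates) over four dates labeled by
Zadok's growth stages 12–13, 21, 24 and 32. `growth_model()` sets the
study conditions: DW means 73, 213, 621, 1812 kg·ha⁻¹ (a roughly
constant relative growth rate interpolating the reported endpoints), NC
5.0, 5.0, 5.0, 4.6%, CC means 0.045, 0.18, 0.45, 0.84 (sigmoidal;
interior dates are interpolated, as only the endpoints are reported).
Plot effects are log-normal for DW with `plot_cv = 0.30` (keeps DW
positive; a typical plot-to-plot spread for small-plot trials), Gaussian
for NC with SD 0.35 percentage points truncated to [2, 7]%. From date 3
on, NC is drawn with correlation −0.6 against log DW, the
dilution trade-off that makes NC partially detectable through DW late in
the window. N uptake is always DW·NC/100 — an identity, never an
independent draw. Sowing density scales DW by `(density/250)^0.5`.

Canopy cover is a logistic function of log DW with a date-specific
intercept at the target mean cover, so cover saturates while DW keeps
growing — this reproduces the saturation phenomenon that makes CC lose
predictive power at stem elongation, and makes cover a deterministic
monotone function of DW within a date.

Spectra are linear soil/vegetation mixtures of parametric endmember
curves (brown soil ramp; vegetation with green bump, red trough,
red-edge sigmoid at 715 nm, NIR plateau with a shallow 970 nm water dip)
plus Gaussian noise, SD 0.005 reflectance units, clipped to [0, 1]. On
the first date only, noise above 1000 nm is multiplied by 4 — the
magnitude is not reported anywhere, and 4× is chosen so NIR/NIR-band
indices visibly destabilize on that date while the visible range stays
usable. The endmember curves are qualitatively realistic shapes, not
field measurements; recovery tests only require that they span a
plausible mixing geometry with a strong red edge (R780 − R670 ≥ 0.25
enforced).

Rendered images paint elongated elliptical "blades" (per-blade green
hue 95–150°, brightness jitter) over textured brown soil until the
target pixel count is reached; the last blade is trimmed pixel-wise, so
the returned ground truth is the exact green fraction and hits the
target to within one pixel. Default size is 600×600 (a parameter);
tests and the acceptance script use 128–256 px to keep runtimes in
seconds, which does not change the geometry of the test, only its
pixel resolution.

What the generator does *not* emulate: radiative transfer, BRDF or
sun-angle effects, 3-D canopy structure, weeds, specular soil moisture
effects, or chlorophyll-driven spectral shape changes — vegetation
spectra vary only through the mixing fraction. Consequently, passing
recovery tests shows the algorithms are correct and well-conditioned
under the stated noise model; it does not certify per-date R² levels on
real canopies, and no attempt is made to calibrate plot dispersion to
reproduce any published per-date R² exactly (the underlying field data
were never deposited).

## Numerical choices and degenerate inputs

- Nearest-band ties break toward the lower wavelength, with a 1e-9 nm
  guard against floating-point near-ties.
- Reflectance up to 1.5 is accepted but flagged (`overshoot`) —
  calibration against a white standard can exceed 1.
- Zero-variance traits make every screen entry undefined rather than
  raising; fewer than 3 plots raises a sample-size error.
- The correlation test requires ≥ 3 complete pairs and non-degenerate
  variance; `build_summary()` converts such failures into missing cells.
- All package errors are classed conditions (`ev_range_error`,
  `ev_undefined_value`, `ev_degenerate_error`, …) so pipelines can
  distinguish data problems from configuration problems.

## Problem sizes used in validation

The test suite and acceptance script validate at: 1000 Monte-Carlo
unmixing draws at noise SD 0.005; 50 rendered images spanning cover
0.02–0.95; 10⁴ null replicates at n = 36 for the type-I rate of the
correlation test; 100 seeded single-date sparse-stand trials for the
cover-vs-NDVI ranking; 10-band × 20-plot × 3-date instances against
brute-force oracles at 1e-12; and full 4 × 36 synthetic trials for the
end-to-end pipeline.

## Known limitations

- The HSV thresholds are a surrogate for a manual step; real image sets
  need per-campaign calibration (`calibrate_thresholds()`), and the
  defaults assume daylight color balance.
- Unmixing is strictly two-endmember and linear; shadowed soil, residue
  or non-linear mixing are out of scope by design.
- The band-pair screen selects in-sample maxima; no cross-validation of
  band selection is performed, so screened optima are optimistic and
  their value lies in the *pattern* (which spectral regions are high and
  stable), not the absolute R².
- The emulated active sensor shares the passive spectrum as input; the
  real instrument's independent illumination is not simulated.
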