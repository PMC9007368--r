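---
title: "Axial-length magnification correction of ETDRS macular thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axial-length magnification correction of ETDRS macular thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etdrsmag)
```

## The measurement problem

An OCT raster scan spans a fixed *visual angle*, not a fixed distance on the
retina. The physical size of the imaged area therefore grows with the eye's
axial length (AL): scanners convert angle to millimetres with a built-in eye
model calibrated to one assumed axial length (24.385 mm for the Spectralis;
24.46 mm for the Cirrus, 24.00 mm for the Copernicus — see
`DEVICE_AXIAL_LENGTHS`). For any eye that deviates from that assumption the
device-reported transverse scale is wrong by the factor

$$s_{\text{corrected}} = s_{\text{default}} \times \frac{AL}{AL_{\text{assumed}}},$$

which is the whole correction implemented here
(`corrected_transverse_scale()`). A nominal 6 mm scan actually covers
`actual_scan_extent(6, 21.5)` = 5.29 mm on a 21.5 mm eye and 6.96 mm on a
28.3 mm eye.

This matters for *regional* thickness because the retina is not flat in the
transverse direction: it is thinnest at the foveal pit, thickest in the
parafoveal annulus, and declines gently toward the periphery. When ETDRS
grid boundaries (central disc of 0.5 mm radius, inner ring to 1.5 mm, outer
ring to 3.0 mm, the rings split into nasal/superior/temporal/inferior
quadrants along the 45° diagonals) are drawn with the wrong millimetre
scale, each sector averages the wrong part of that profile. For an eye
*shorter* than the assumed axial length every true on-retina distance is
smaller than the device reports, so the uncorrected ("raw") grid is too
small in true millimetres: the raw central disc stays closer to the thin
pit centre and *under*-estimates the central mean, while the raw outer ring
sits closer to the thick parafovea than the true 1.5–3.0 mm annulus and
*over*-estimates. Longer-than-assumed eyes show the opposite pattern. The
package exists to quantify exactly this push-pull and to undo it.

The correction changes *where the sector boundaries fall* and nothing else:
thickness values are never resampled or rescaled (`build_grid()` with
`corrected = TRUE` rescales both transverse scales by the AL ratio — the
magnification acts on visual angle and is therefore isotropic in the
transverse plane — and the same thickness map is re-averaged).

## Pipeline

1. **Thickness extraction** (`surfaces_to_thickness()`): full retinal
   thickness is the axial ILM-to-RPE distance per A-scan, converted to µm
   via the axial resolution (3.9 µm/px by default) when surfaces arrive in
   pixels. A-scans where the surfaces cross are flagged invalid; more than
   10 % invalid pixels is treated as a segmentation failure.
2. **Fovea localisation** (`locate_fovea()`): minimum of a lightly smoothed
   thickness surface within 1.5 mm of the scan centre. The smoothing is a
   validity-aware 0.25 mm moving average — wide enough to suppress
   per-pixel noise, narrow enough not to displace a ≈0.35 mm-wide pit. The
   discrete minimum is refined to sub-pixel precision by quadratic
   interpolation per axis (the central 0.5 mm sector is sensitive to
   sub-pixel centre error; the other sectors are not). Ties break toward
   the scan centre. The 1.5 mm search radius reflects the scan protocol,
   which centres on the fovea; a wider search invites ectopic minima.
3. **Sector averaging** (`build_grid()`, `sector_means()`,
   `extract_eye()`): pixel-centre point-in-region membership (no area
   weighting), radial bins half-open with the inner boundary inclusive
   ([0, 0.5), [0.5, 1.5), [1.5, 3.0) mm), unweighted means over valid
   pixels. Raw and corrected variants are computed from the *same* map and
   the *same* fovea estimate.
4. **Cohort statistics** (`fit_correction_effect()`,
   `fit_al_interaction()`, `fit_group_contrast()`, `analyze_cohort()`):
   REML linear mixed models (lme4/lmerTest, Satterthwaite inference) on the
   long eye × correction-state × sector table.

### Conventions and tie-breaks

* **Laterality.** The horizontal direction nearer the optic disc is nasal:
  image right for OD, image left for OS by default (`nasal_side` overrides
  this if an export is oriented differently). The synthetic retina carries a
  configurable nasal asymmetry so the convention is testable: mirroring a
  map left-right and toggling OD/OS must leave all nine sector means
  unchanged.
* **Diagonals.** Pixels exactly on a 45° diagonal (to within a sub-nanometre
  epsilon, so floating-point noise in the centre estimate cannot split an
  exact tie) are assigned to the horizontal (nasal/temporal) quadrant. This
  particular tie-break is what makes the mirror invariance exact.
* **Truncation.** If part of a sector falls outside the scan, the estimated
  truncated area fraction is reported per sector and a warning is raised
  above 20 %.

## The statistical models

With thickness \(y_{ijk}\) for participant \(i\), eye \(j\), correction
state \(k\):

* **Correction main effect**:
  \(y = \beta_0 + \beta_1\,\text{corrected} + \text{sex} + \text{ethnicity}
  + b_{0i} + b_{1i}\,\text{corrected} + \varepsilon\), REML, with random
  intercepts and random correction-slopes per participant. The correction
  flag is the repeated within-eye factor both eyes share, which is why the
  random slope sits on it; the random intercept carries the correlation
  between a participant's two eyes. \(\beta_1\) is the mean corrected−raw
  difference: positive where raw underestimates.
* **AL interaction**: adds axial length and AL × correction. The
  interaction coefficient is the change in (corrected − raw) per mm of AL;
  its negative is the per-mm overestimation by raw measurements. Simple
  slopes of AL on raw and corrected data are fitted separately per state
  with random intercepts.
* **Group contrast**: myope (spherical equivalent ≤ −0.50 D, boundary
  inclusive) vs non-myope in place of axial length, separately per
  correction state.

Sex and ethnicity (three-level: Caucasian / East Asian / other-mixed) are
always included as fixed covariates when they vary. P-values use
Satterthwaite degrees of freedom; confidence intervals are Wald intervals
at those degrees of freedom; p-values are Bonferroni-adjusted across the
nine sectors within each term family (`adjust_pvalues()`). Significance is
two-sided at 0.05.

**Fallback ladder.** A singular or failed fit drops the random slope; if
the random-intercept fit also fails, the last resort is fixed-effects least
squares with cluster-robust (by participant) standard errors. The model
actually used is recorded in the `model` column of every effect row — no
fallback is silent.

## The synthetic retina and cohort

No real scans ship with the package; every downstream stage is exercised on
a generator whose defaults are frozen study conditions, not tuning knobs.

**Surface** (`pit_model()`): baseline + Gaussian parafoveal annulus −
Gaussian foveal pit,
\(T(r) = t_p + a_{para}e^{-(r-r_{peak})^2/2\sigma_{para}^2} -
a_{pit}e^{-r^2/2\sigma_{pit}^2}\), the simplest smooth shape with the right
anatomy (thin fovea, thick parafovea, gentle peripheral decline). Defaults
(270 + 70 @ 0.95 mm − 75, σ_pit 0.35 mm) give a foveal minimum near 240 µm,
inner-ring means near 333 µm and outer-ring means near 300 µm — plausible
for young adults, but explicitly *not* normative values. An optional
smooth nasal multiplier makes the nasal half thicker for orientation tests,
and optional linear AL-thinning terms (µm per mm of AL above 24.385)
inject true biology for recovery experiments; both default off/neutral.

**Scanner** (`simulate_scan()`): samples the surface at the *true*
on-retina pixel positions — default scale × AL/24.385 — adds i.i.d.
Gaussian per-A-scan noise (3 µm default), and stamps the map with the
*default* scales. That asymmetry (true sampling, wrong metadata) is the
magnification error, reproduced exactly as a real scanner commits it.

**Cohort** (`cohort_spec()`, `simulate_cohort()`): participant axial length
N(23.6, 0.9²) mm with interocular correlation 0.95 (shared participant
component + eye deviation); spherical equivalent falls linearly with AL
(−2 D/mm) around a threshold placed so the expected myope fraction is 23 %,
with refraction noise split into participant-level (0.45 D) and eye-level
(0.2 D) parts — refraction, like axial length, is strongly correlated
between a person's eyes, and a generator that ignores this floods the
cohort with implausible group-discordant pairs that distort the
within-participant information the mixed models use. Biological thickness
variation enters as whole-surface offsets: participant SD 10 µm, eye SD
5 µm (interocular thickness correlation 0.80, marginal SD ≈ 11 µm), plus a
+6 µm male offset. SNR scores are N(30, 5²), so a realistic few percent of
scans fail the <20 quality gate. All randomness flows from the single
integer seed; per-eye scans use deterministic sub-streams, and the global
RNG state is never disturbed.

The AL→refraction map is a crude emmetropization-failure model and the
offsets are uniform over the surface; the generator does not attempt
speckle, segmentation error, choroid, or spatially structured biological
variation. Passing tests therefore demonstrate correctness of the
*geometry and statistics*, not robustness to every property of real scans.

## Verification strategy

The reference for every sector quantity is 2-D Gauss–Legendre quadrature of
the continuous surface over the exact annular-sector boundaries
(`sector_truth()`), with raw-grid expectations obtained by scaling the
boundaries by AL/24.385 and AL-slopes of the raw means by central
differences (`magnification_slope_truth()`). Pixel extraction is required
to agree with quadrature within 0.5 µm on a densely resampled (512 × 512,
≈14 µm pixels) symmetric retina; masks are checked against brute-force
per-pixel classification.

## Numerical choices and known limitations

* **Sparse vertical sampling.** The 31-line protocol spaces B-scans ≈0.24 mm
  apart. Sector means use the rows as-is (no vertical interpolation,
  matching per-A-scan extraction). Consequence: as AL varies, the
  corrected grid's row membership changes in steps, which leaves a
  residual discretization trend of about −0.5 µm/mm on the corrected
  *central* sector mean (−0.1 to −0.3 µm/mm on vertically bounded sectors;
  horizontal and outer sectors are clean). This is well inside the
  confidence intervals at the cohort sizes used, and the dense-resampling
  oracle tests show the limit vanishes with row density, but
  single-eye central-sector values carry that raster limitation.
* **Plausibility gate.** Axial lengths outside 15–35 mm are a hard error,
  never a pass-through: a unit mistake (µm instead of mm) would otherwise
  silently corrupt every downstream sector.
* **Cylinder convention.** Minus-cylinder is assumed; `plus_cylinder = TRUE`
  converts. The spherical equivalent itself is convention-invariant.
* **Problem sizes.** Simulation-based checks in the test suite use the
  31-line raster at 256 A-scans per line (the smooth surface is amply
  sampled; device high-resolution mode records 1536), cohorts of 80–500
  participants, and 50–200 replicates per property, chosen to give stable
  rates at practical runtimes.
* The corneal-curvature contribution to magnification is treated as already
  handled inside the device's reported "Scaling X" (which is why corneal
  radius is carried as metadata only), and no three-variable
  Littmann/Bennett eye model is attempted: the correction is deliberately
  the single-ratio AL adjustment.

## A worked single eye

```{r}
geometry <- spectralis_geometry()
model <- pit_model()
eye <- eye_biometry("P001", "OD", axial_length = 22.5, sphere = -2.25,
                    cylinder = -0.5, snr = 32)
scan <- simulate_scan(model, geometry, eye, noise_sd = 3, seed = 7)
sectors <- extract_eye(scan)
reshape(sectors[, c("sector", "corrected", "mean_um")],
        idvar = "sector", timevar = "corrected", direction = "wide")
```

The short eye (22.5 mm < 24.385 mm) shows the signature pattern: the raw
central mean sits below the corrected one, the raw outer-ring means above.

## A worked cohort

```{r, eval = FALSE}
st <- simulate_sector_table(cohort_spec(n_participants = 300, seed = 1),
                            pit_model(), spectralis_geometry(n_ascans = 256))
effects <- analyze_cohort(st$table)
subset(effects, term == "correction")
```

On a default cohort the correction main effect is positive in the central
sector and negative across the outer ring, the AL × correction interaction
implies a central overestimation of roughly +2 µm per mm of AL by raw
measurements (outer temporal ≈ −3 µm/mm), and raw-data myope/non-myope
contrasts in non-central sectors attenuate toward zero once corrected —
the package's statistical reproduction of why magnification correction
matters.
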