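---
title: "Binocular field integration and driving-simulator analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocular field integration and driving-simulator analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oudrive)
```

This vignette is the package's own account of its models and the design
choices behind them: the binocular visual field derivation, the
eccentricity-weighted index, the driving-simulator outcome measures,
what the synthetic cohort generator does and does not emulate, and the
statistical stage.

## The binocular field model

Standard automated perimetry is monocular, but driving is binocular.
Given a pair of Humphrey-style fields — per-location threshold values
(TV, in dB of stimulus attenuation) and total deviations (TD, threshold
minus the age-normal expectation) — the package derives a theoretical
binocular field by **quadratic summation of linear sensitivities**. At
each location the two dB thresholds are converted to linear sensitivity,
combined root-sum-square, and converted back:

$$bTV = 10\log_{10}\sqrt{(10^{lTV/10})^2 + (10^{rTV/10})^2},$$

and identically for the *expected* binocular threshold
$\overline{bTV}$, using each eye's normative surface $TV - TD$. The
binocular total deviation is $bTD = bTV - \overline{bTV}$. Quadratic
summation has two properties worth keeping in mind: the binocular
estimate never falls below the better eye, and it exceeds the better
eye by at most $10\log_{10}\sqrt{2} \approx 1.505$ dB (attained when
the eyes are equal). Both are enforced as property tests.

Each $bTD$ is mapped to a 0–100 sensitivity score
$S = 100 - 100\,|bTD|/\overline{bTV}$ for $bTD<0$ and $S = 100$
otherwise. The raw expression goes negative once the deviation exceeds
the expected threshold (deep absolute defects); since the score's
defined range is 0 (fully impaired) to 100 (fully intact), the package
**floors S at 0**. This is a deliberate deviation from the literal
piecewise formula and is the only point where the implementation is not
a transcription of the displayed equations.

The binocular visual field index (OU-VFI) is the weighted mean

$$VFI = \frac{\sum S_{ij} W_{ij}}{\sum 100\, W_{ij}} \times 100\%,$$

with $W$ the five-ring eccentricity weighting (3.29 for the central
four points, then 1.28, 0.79, 0.57, 0.45 with increasing eccentricity),
reflecting the cortical over-representation of central vision. The ring
*boundaries* are not part of the published weighting scheme; the package
defaults to eccentricity cut-points at 5.7°, 12.8°, 19.0° and 25.5°,
chosen so that on the 24-2 grid the central four points (eccentricity
4.24°) form ring 1 and successive annuli fall in rings 2–5. They are a
documented convention and a parameter (`ring_boundaries`) everywhere
they are used. 30-2 grids reuse the same boundaries, with locations
beyond the last cut-point pooled into ring 5, because 24-2 and 30-2
fields are analyzed interchangeably.

### Grid geometry and merge rules

Grids live in visual-field coordinates (x positive toward the subject's
right, y positive superior), shared by both eyes. The 24-2 tests 54
locations: a symmetric core plus a two-point nasal extension at 27°,
which sits at $x=-27$ for OD and $x=+27$ for OS; the 30-2 tests 76
eye-symmetric locations. Because the nasal extension is one-sided, the
*per-eye* 24-2 grid is not mirror-symmetric — but the OS grid is exactly
the mirror of the OD grid, and the sum of weights is identical for the
two lateralities (both tested).

Binocular integration merges the pair on the **union** of tested
locations (56 for a 24-2 pair). At a location measured by only one eye —
the fellow eye's physiologic blind spot ($x=\pm15$, $y=\pm3$) or its
untested nasal column — the quadratic sum cannot be taken in dB space
with a "zero" for the missing eye (dB $\to -\infty$ is not a valid
input), so the seeing eye's TV/TD are used alone: the consistent
degenerate limit as the missing eye's linear sensitivity goes to 0.
These single-eye locations keep their ring weight, since the binocular
observer genuinely sees there. A blind-spot location is excluded (weight
0) only in *monocular* weighting, where it carries no disease
information. Mixed 24-2/30-2 pairs integrate on the coordinate
intersection. One naming note: this family of procedures is often
referred to in the clinical literature under "best location"
integration; what is implemented here is the quadratic-summation
derivation stated above, which rewards the better eye but is not a
pointwise maximum.

All dB↔linear conversions are base-10 exactly as written; equality
assertions in the test suite use 1e-6 dB / 1e-6 percentage points, and
the implementation is checked location-by-location against an
independently written per-location oracle on random fields.

## Driving-simulator outcomes

Telemetry is a 60 Hz uniformly sampled record of speed, steering-wheel
angle, and lateral/longitudinal acceleration from a straight two-lane
rural drive (3.6 m lanes, 88.5 km/h limit). "Variability" of a channel
is the **sample standard deviation over the full drive** — the standard
lane-maintenance dispersion metric; no detrending or segmentation is
applied, and repeated drives are aggregated by the model stage, not by
the metric. Over-limit fractions use a strict inequality, with limits
exact in SI units (55 mph = 24.5872 m/s, 60 mph = 26.8224 m/s;
1 mph = 0.44704 m/s). Accelerations are carried in the simulator's
native units — the magnitudes (~0.001–0.005) indicate non-SI units, so
the module is unit-agnostic for those channels.

The in-cab detection task (DSVF) presents stimuli over a 60°×20° grid,
four presentations per location; a location passes at a detection rate
*strictly* above 50%. A field-level DS-VFI applies the standard ring
weighting to the binary pass map (pass = 100, fail = 0). Rings are
assigned by the locations' **true visual-field eccentricities** rather
than rescaled to the task extent: the weights encode cortical
magnification, which is a function of absolute eccentricity, and a
grid-relative rescaling would leave no location in the central ring.

Simulated telemetry is an AR(1) perturbation around the channel
targets, parameterized by the *marginal* SD (innovations scaled by
$\sqrt{1-\phi^2}$) with $\phi = 0.98$ per sample at 60 Hz — a
correlation half-life of about 0.6 s, emulating smooth steering
corrections rather than white noise. The marginal parameterization is
what makes a recovered sample SD comparable to the planted value; with
a 600 s drive the AR(1) effective sample size (~360) keeps the sampling
error of the SD a few percent.

## The synthetic cohort

No patient data ship with the package; the generator produces cohorts
with the statistical structure the analysis assumes, and its defaults
are the study conditions: 25 glaucoma patients and 18 suspects, group
age distributions 69.8 ± 11.3 vs 60.3 ± 13.1 years, and matching group
means/SDs for acuity, MoCA and VFQ scores. Suspects always receive
normal fields (that is the clinical definition of the group); glaucoma
subjects draw from a mixture of defect archetypes (early arcuate, nasal
step, moderate diffuse, advanced) whose noise-free OU-VFIs span deep
loss to near-normal, so a seeded batch covers the wide severity range
(roughly 20–98%) that makes the logit transform necessary. Threshold
noise is Gaussian in dB (default SD 1.5 dB) around a hill-of-vision
expectation (30 dB at fixation, −0.5 dB per 3° of eccentricity), and
TD = TV − expected holds exactly by construction.

Vehicle-control outcomes are generated on the natural-log scale as the
planted linear combination of age, worst-eye acuity, logit OU-VFI, MoCA
total and VFQ driving score — coefficient defaults taken from the
fitted multivariable models (e.g. −0.1875 per logit of OU-VFI on log
steering variability) — plus a per-subject random intercept (SD 0.4)
and per-drive residual (SD 0.35). Variance components, unlike the
fixed effects, have no published reference values; the two SDs were
chosen once from the width of the published back-transformed group
confidence intervals for the variability outcomes (which imply a
between-subject log-scale SD of roughly 0.8 before covariates) and are
not tuned thereafter. The repeated-measures unit behind the original
mixed models is likewise unstated; the generator exposes
`drives_per_subject` (default 2, matching the two task runs) rather
than asserting it.

What the generator does **not** emulate: frequency-of-seeing response
curves and test-retest asymmetry of perimetry, learning/fatigue
effects, covariate correlations beyond the VFI–MoCA visuospatial link,
and real road geometry. Passing parameter-recovery tests therefore
demonstrates that the analysis stage is consistent and calibrated for
data of the assumed structure — not that real cohorts satisfy that
structure.

## Statistical stage

Group descriptives follow the study's battery: independent-sample
t-tests with a Levene pre-check at α = 0.05 choosing pooled vs
Welch–Satterthwaite (the variance-equality criterion is configurable,
since "when variance was unequal" admits several conventions), Wilcoxon
rank-sum for the discrete bounded MoCA scores, chi-squared for gender,
Spearman correlations for the VFI–MoCA screen. No multiplicity
correction is applied, matching the original p < 0.05 convention.

The multivariable model is
`log(outcome) ~ age + va_worst + exposure + moca_total + vfq_driving`
with a per-subject random intercept, fitted by REML (lme4), the
exposure being either the logit of OU-VFI or glaucoma group. Per-term
df/F/p use the **Kenward-Roger** small-sample correction by default;
the Satterthwaite option of the same model is used inside the
simulation-calibration loops, where hundreds of refits make the KR
cost material and the two are near-identical at these sizes. The logit
clamp ε = 0.005 keeps fully intact fields (VFI = 100%, every suspect)
finite and ordered; it is a sensitivity-flagged convention, as the
original handling of 100% values is unstated. Cohen's d per model term
is computed as $2t/\sqrt{df}$ (the paired formula choice is recorded
per estimate); with one drive per subject the random intercept is not
identifiable and the fit degrades to OLS with a message. Rows with
missing covariates are dropped listwise with a count.

Calibration is checked by simulation: 200 cohorts of 200 subjects at
the planted −0.1875 logit-OU coefficient give ~95% CI coverage, and 500
null cohorts (all effects zero, 60 subjects — a realistic pilot scale
chosen once) give uniform exposure-term p-values
(Kolmogorov–Smirnov). These sizes keep the full suite around a minute
of compute while leaving the Monte-Carlo error of a coverage estimate
near 1.5 percentage points.

## Degenerate inputs and numeric conventions

* `binocular_threshold` is evaluated as
  $\mathrm{hi} + 5\log_{10}(1 + 10^{(\mathrm{lo}-\mathrm{hi})/5})$,
  which is exact and avoids overflow for extreme dB values.
* Sensitivities require $\overline{bTV} > 0$; a non-positive normative
  value is a data error and is rejected, not clamped.
* Instrument "<0" threshold codes are out of scope: inputs are numeric
  dB, and negative values are accepted as given.
* All CSV writers print at 6 significant digits; reruns of the pipeline
  under the same configuration are byte-identical, which is asserted in
  the test suite.
* Every rejection carries a classed condition
  (`oudrive_error_<topic>`), so callers can distinguish schema errors
  from numeric ones.

## Known limitations

The derived OU-VFI consumes TV/TD and does not re-derive deviations
from a normative database, does not reproduce the instrument's native
monocular VFI (including its pattern-deviation-based ring logic for
depressed fields, whose role in the original derivation is unstated),
and offers no progression analysis. The driving module does not
reconstruct lane position from road geometry and has no hazard or curve
scenarios. The generator's independence assumptions between covariates
are a simplification; effect estimates from synthetic cohorts should be
read as calibration checks, not as clinical predictions.
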