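# oudrive

Binocular visual field integration and driving-simulator vehicle-control
analysis for clinical vision science.

Glaucoma takes the peripheral visual field first, and what matters for
everyday tasks like driving is the *binocular* field — yet standard
automated perimetry (Humphrey 24-2 / 30-2) is monocular, and studies of
lane maintenance need a single severity index per patient plus
quantitative vehicle-control outcomes. `oudrive` provides that tool
chain:

* **Binocular integration (OU-VFI).** From a pair of monocular
  threshold/total-deviation maps, a binocular threshold is derived per
  location by quadratic summation of linear sensitivities,

  $$bTV = 10\log_{10}\sqrt{(10^{lTV/10})^2+(10^{rTV/10})^2},$$

  the binocular total deviation $bTD = bTV - \overline{bTV}$ is taken
  against the same summation of the normative surfaces ($TV - TD$),
  mapped to a 0–100 sensitivity
  $S = \max\{0,\,100 - 100|bTD|/\overline{bTV}\}$ (100 where
  $bTD \ge 0$), and averaged with the five-ring eccentricity weighting
  (3.29 / 1.28 / 0.79 / 0.57 / 0.45) into a 0–100% index.
* **Driving metrics.** Velocity mean/SD/max, strict over-limit
  fractions (55 and 60 mph, exact SI conversion), and steering-wheel /
  lateral / longitudinal acceleration variabilities (sample SD over the
  drive) from 60 Hz telemetry; plus scoring of the in-cab
  stimulus-detection task (DSVF, pass = detection rate strictly > 50%).
* **Synthetic cohort generator.** Monocular field pairs with
  glaucomatous defect archetypes, AR(1) telemetry with plantable
  variability, and a 25 + 18 glaucoma/suspect cohort whose log-scale
  vehicle-control outcomes follow a planted multivariable model.
* **Analysis stage.** Group comparison battery (t/Welch with Levene
  pre-check, Wilcoxon, chi-squared, Spearman screens) and linear mixed
  models `log(outcome) ~ age + acuity + logit(OU-VFI) + MoCA + VFQ`
  with per-subject random intercepts and Kenward-Roger df.

## Worked example

```r
library(oudrive)

# a moderate diffuse defect, left eye 2 dB worse than right
pair <- simulate_monocular_pair("moderate_diffuse", asymmetry = 2,
                                noise_sd = 1.5, seed = 20201020)
bf <- integrate_fields(pair$left, pair$right)
bf
#> <binocular_field> 24-2, 56 locations
#>   OU-VFI 73.05%, mean bTD -7.85 dB
```

The pair merges onto the 56-location union frame (48 shared locations
plus each eye's view of the other's blind-spot column and nasal
extension); a fully normal pair scores exactly 100%, and this moderate
defect retains 73% of the weighted binocular field.

```r
m <- drive_metrics(simulate_telemetry(duration = 300, target_speed = 24.9,
                                      steering_sd = 0.75,
                                      lat_accel_sd = 0.0052, seed = 102))
round(m$steering_sd, 3);  round(m$pct_over_55, 3)
#> [1] 0.768
#> [1] 0.581
```

The analysis workflow lives in `analysis/` as numbered drivers writing
to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R       # 43-subject cohort + example fields
Rscript analysis/02_integrate_fields.R      # binocular integration walk-through
Rscript analysis/03_drive_metrics.R         # telemetry metrics + DSVF scoring
Rscript analysis/04_group_comparisons.R     # descriptive battery
Rscript analysis/05_vehicle_control_models.R  # mixed models (4 tables)
```

The final script prints, e.g., for log steering variability against
logit OU-VFI (one row per model effect):

```
         term estimate      se df f_value  p_value
4    logit_ou -0.19591 0.04320 37   20.56 5.88e-05
```

i.e. each logit of binocular field loss multiplies steering-wheel
variability by about exp(0.196) ≈ 1.22, independently of age, acuity,
MoCA and self-reported driving difficulty — the planted structure the
generator encodes and the model recovers.

The same stages are available as one call:
`run_pipeline(pipeline_config(seed = 1), "out/")`, which is
byte-reproducible under a fixed seed.

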