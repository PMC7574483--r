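#' Glaucomatous defect archetypes
#'
#' Named mean total-deviation offset patterns used by the field
#' generator. `normal` is zero everywhere; `early_arcuate` depresses a
#' superior arcuate (Bjerrum) annulus; `nasal_step` depresses the
#' superior nasal quadrant (respecting the horizontal midline);
#' `moderate_diffuse` combines a diffuse depression with a deeper
#' superior component; `advanced` is a deep diffuse loss with a
#' near-absolute superior hemifield. Offsets of `advanced` are at or
#' below those of `moderate_diffuse` at every location.
#'
#' @return Character vector of archetype names.
#' @export
defect_archetypes <- function() {
  c("normal", "early_arcuate", "nasal_step", "moderate_diffuse", "advanced")
}

#' Mean TD offsets of an archetype on a grid
#'
#' @param name One of [defect_archetypes()].
#' @param grid A `vf_grid` (the offsets depend on location and on the
#'   grid's eye: the nasal side is `x < 0` for OD, `x > 0` for OS).
#' @return Numeric vector of mean total-deviation offsets (dB, <= 0),
#'   one per grid location.
#' @export
archetype_offsets <- function(name, grid) {
  if (!inherits(grid, "vf_grid")) {
    ou_stop("`grid` must be a vf_grid", "grid")
  }
  name <- match.arg(name, defect_archetypes())
  x <- grid$x
  y <- grid$y
  ecc <- grid$eccentricity
  nasal <- if (identical(attr(grid, "eye"), "OS")) x > 0 else x < 0
  sup <- y > 0
  switch(name,
    normal = numeric(length(x)),
    early_arcuate = ifelse(sup & ecc >= 9 & ecc <= 22, -8, 0),
    nasal_step = ifelse(sup & nasal, -10, 0),
    moderate_diffuse = -6 + ifelse(sup, -6, 0),
    advanced = -20 + ifelse(sup, -8, 0)
  )
}

# age-normal hill of vision used by the generator: peak sensitivity at
# fixation declining linearly with eccentricity
normal_surface <- function(ecc, peak = 30, decline_per_3deg = 0.5) {
  peak - decline_per_3deg * ecc / 3
}

#' Simulate a monocular field pair
#'
#' Generates an OS/OD pair of threshold and total-deviation maps. The
#' expected threshold surface is a hill of vision with `peak` dB at
#' fixation declining `decline_per_3deg` dB per 3 degrees of
#' eccentricity. Each eye's threshold is expected surface + archetype
#' offset + Gaussian measurement noise, and TD is threshold minus
#' expected by construction, so the identity `td = tv - expected` the
#' integration equations rely on holds exactly.
#'
#' @param archetype Archetype name, see [defect_archetypes()].
#' @param asymmetry Inter-eye asymmetry in dB (>= 0): the right eye's
#'   defect offsets are relieved by this amount (never past 0), so the
#'   left eye is the worse eye. No effect on the `normal` archetype.
#' @param pattern `"24-2"` (default) or `"30-2"`.
#' @param noise_sd Gaussian measurement noise SD on thresholds, dB
#'   (default 1.5; 0 gives deterministic fields).
#' @param seed Optional integer seed; the pair is a pure function of the
#'   arguments given a seed.
#' @param peak,decline_per_3deg Normal-surface parameters (defaults 30
#'   dB and 0.5 dB / 3 deg).
#' @return List with [monocular_field()] elements `left` (OS) and
#'   `right` (OD).
#' @export
simulate_monocular_pair <- function(archetype = "normal", asymmetry = 0,
                                    pattern = "24-2", noise_sd = 1.5,
                                    seed = NULL, peak = 30,
                                    decline_per_3deg = 0.5) {
  if (!is.finite(asymmetry) || asymmetry < 0) {
    ou_stop("`asymmetry` must be a non-negative dB value", "simulate")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    ou_stop("`noise_sd` must be non-negative", "simulate")
  }
  if (!is.null(seed)) set.seed(seed)
  one_eye <- function(eye, relieve) {
    g <- vf_pattern(pattern, eye = eye)
    expected <- normal_surface(g$eccentricity, peak, decline_per_3deg)
    off <- archetype_offsets(archetype, g)
    if (relieve > 0) off <- ifelse(off < 0, pmin(0, off + relieve), off)
    td <- off + rnorm(nrow(g), sd = noise_sd)
    monocular_field(eye, pattern, g$x, g$y,
                    tv = expected + td, td = td)
  }
  left <- one_eye("OS", relieve = 0)
  right <- one_eye("OD", relieve = asymmetry)
  list(left = left, right = right)
}

#' Specification of a synthetic study cohort
#'
#' Bundles and validates everything the cohort generator needs: group
#' sizes, per-group covariate distributions, the archetype mixture for
#' the glaucoma group, measurement-noise and normal-surface settings for
#' the fields, and the planted regression structure of the vehicle
#' control outcomes. Defaults are the study conditions: 25 glaucoma
#' patients and 18 suspects; group means/SDs for age, visual acuity,
#' MoCA and VFQ as observed in that cohort; and fixed-effect
#' coefficients of the multivariable vehicle-control models (on the
#' natural-log outcome scale, with binocular VFI entering as a logit).
#'
#' @param n_glaucoma,n_suspect Group sizes (>= 1; suspects are the
#'   control group).
#' @param age,va_worst,moca_total,vfq_driving,vfq_peripheral,vfq_total
#'   Per-group `c(mean, sd)` pairs as a list with elements `glaucoma`
#'   and `suspect`.
#' @param p_female Per-group probability of female gender.
#' @param betas_steering,betas_lat_accel Named fixed-effect coefficients
#'   (`intercept`, `age`, `va_worst`, `logit_ou`, `moca_total`,
#'   `vfq_driving`) generating the log-scale outcome.
#' @param subject_sd SD of the per-subject random intercept (log units).
#' @param residual_sd Per-drive residual SD (log units). May be 0 for
#'   noise-free checks.
#' @param drives_per_subject Repeated drives per subject (>= 1).
#' @param glaucoma_mixture Named non-negative weights over the non-normal
#'   archetypes for glaucoma subjects (normalized internally). Suspects
#'   are always `normal` (normal fields by definition).
#' @param noise_sd Field measurement noise, dB.
#' @param asymmetry_sd SD of the half-normal inter-eye asymmetry draw, dB.
#' @param pattern Test pattern for the simulated fields.
#' @param logit_eps Clamp used when the planted model logit-transforms
#'   the VFI (see [logit_vfi()]).
#' @param seed Optional integer seed making [simulate_cohort()] a pure
#'   function of the spec.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_glaucoma = 25, n_suspect = 18,
    age = list(glaucoma = c(69.8, 11.3), suspect = c(60.3, 13.1)),
    va_worst = list(glaucoma = c(0.13, 0.12), suspect = c(0.06, 0.09)),
    moca_total = list(glaucoma = c(24.7, 3.0), suspect = c(25.4, 2.4)),
    vfq_driving = list(glaucoma = c(80.9, 13.5), suspect = c(87.8, 15.1)),
    vfq_peripheral = list(glaucoma = c(84.1, 16.4), suspect = c(93.3, 11.4)),
    vfq_total = list(glaucoma = c(87.8, 7.0), suspect = c(91.6, 7.6)),
    p_female = c(glaucoma = 11 / 25, suspect = 14 / 18),
    betas_steering = c(intercept = 3.1881, age = 0.0141,
                       va_worst = -1.9879, logit_ou = -0.1875,
                       moca_total = -0.0632, vfq_driving = -0.0308),
    betas_lat_accel = c(intercept = -1.6206, age = 0.0144,
                        va_worst = -1.9368, logit_ou = -0.1966,
                        moca_total = -0.0753, vfq_driving = -0.0293),
    subject_sd = 0.4, residual_sd = 0.35,
    drives_per_subject = 2,
    glaucoma_mixture = c(early_arcuate = 0.3, nasal_step = 0.2,
                         moderate_diffuse = 0.3, advanced = 0.2),
    noise_sd = 1.5, asymmetry_sd = 2,
    pattern = "24-2", logit_eps = 0.005, seed = NULL) {
  spec <- list(
    n_glaucoma = n_glaucoma, n_suspect = n_suspect, age = age,
    va_worst = va_worst, moca_total = moca_total,
    vfq_driving = vfq_driving, vfq_peripheral = vfq_peripheral,
    vfq_total = vfq_total, p_female = p_female,
    betas_steering = betas_steering, betas_lat_accel = betas_lat_accel,
    subject_sd = subject_sd, residual_sd = residual_sd,
    drives_per_subject = drives_per_subject,
    glaucoma_mixture = glaucoma_mixture, noise_sd = noise_sd,
    asymmetry_sd = asymmetry_sd, pattern = normalize_pattern(pattern),
    logit_eps = logit_eps, seed = seed
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_glaucoma < 1 || spec$n_suspect < 1) {
    ou_stop("group sizes must be >= 1", "spec")
  }
  if (spec$drives_per_subject < 1) {
    ou_stop("drives_per_subject must be >= 1", "spec")
  }
  if (!is.finite(spec$residual_sd) || spec$residual_sd < 0 ||
      !is.finite(spec$subject_sd) || spec$subject_sd < 0) {
    ou_stop("variance components must be non-negative", "spec")
  }
  need <- c("intercept", "age", "va_worst", "logit_ou", "moca_total",
            "vfq_driving")
  for (b in c("betas_steering", "betas_lat_accel")) {
    if (!all(need %in% names(spec[[b]]))) {
      ou_stop(sprintf("%s must name coefficients %s", b,
                      paste(need, collapse = ", ")), "spec")
    }
  }
  mx <- spec$glaucoma_mixture
  if (any(mx < 0) || sum(mx) <= 0 ||
      !all(names(mx) %in% setdiff(defect_archetypes(), "normal"))) {
    ou_stop("glaucoma_mixture must be non-negative weights over the defect archetypes",
            "spec")
  }
  invisible(TRUE)
}

# Precomputed union-frame geometry for the vectorized many-subject
# integration (same merge rules as integrate_fields(), on index vectors).
integration_frame <- function(pattern, ring_boundaries = vf_ring_boundaries(),
                              ring_weights = vf_ring_weights(),
                              peak = 30, decline_per_3deg = 0.5) {
  od <- vf_pattern(pattern, "OD")
  os <- vf_pattern(pattern, "OS")
  odk <- paste(od$x, od$y)
  osk <- paste(os$x, os$y)
  keys <- union(osk, odk)
  li <- match(keys, osk)
  ri <- match(keys, odk)
  xy <- do.call(rbind, strsplit(keys, " "))
  x <- as.numeric(xy[, 1]); y <- as.numeric(xy[, 2])
  ecc <- sqrt(x^2 + y^2)
  # an eye contributes only where tested and not at its own blind spot
  l_ok <- !is.na(li) & !(x == -15 & abs(y) == 3)
  r_ok <- !is.na(ri) & !(x == 15 & abs(y) == 3)
  list(
    l_idx = li, r_idx = ri, l_ok = l_ok, r_ok = r_ok,
    l_expected = normal_surface(sqrt(os$x^2 + os$y^2), peak, decline_per_3deg),
    r_expected = normal_surface(sqrt(od$x^2 + od$y^2), peak, decline_per_3deg),
    weight = ring_weights[findInterval(ecc, ring_boundaries) + 1L]
  )
}

# OU-VFI for many subjects at once. l_td: n_subjects x n_OS-locations
# matrix of left-eye TDs (OS grid order); r_td likewise on the OD grid.
ou_vfi_batch <- function(l_td, r_td, frame) {
  n <- nrow(l_td)
  nl <- length(frame$l_idx)
  l_tv <- matrix(rep(frame$l_expected, each = n), n) + l_td
  r_tv <- matrix(rep(frame$r_expected, each = n), n) + r_td
  L <- frame$l_idx; R <- frame$r_idx
  lok <- matrix(rep(frame$l_ok, each = n), n)
  rok <- matrix(rep(frame$r_ok, each = n), n)
  ltv <- l_tv[, ifelse(is.na(L), 1L, L), drop = FALSE]; ltv[!lok] <- NA
  ltd <- l_td[, ifelse(is.na(L), 1L, L), drop = FALSE]; ltd[!lok] <- NA
  rtv <- r_tv[, ifelse(is.na(R), 1L, R), drop = FALSE]; rtv[!rok] <- NA
  rtd <- r_td[, ifelse(is.na(R), 1L, R), drop = FALSE]; rtd[!rok] <- NA
  la <- 10^(ltv / 5); ra <- 10^(rtv / 5)
  le <- 10^((ltv - ltd) / 5); re <- 10^((rtv - rtd) / 5)
  btv <- 5 * log10(ifelse(lok, la, 0) + ifelse(rok, ra, 0))
  ebtv <- 5 * log10(ifelse(lok, le, 0) + ifelse(rok, re, 0))
  # single-eye locations degenerate to the seeing eye's dB values exactly
  btv[lok & !rok] <- ltv[lok & !rok]
  ebtv[lok & !rok] <- (ltv - ltd)[lok & !rok]
  btv[rok & !lok] <- rtv[rok & !lok]
  ebtv[rok & !lok] <- (rtv - rtd)[rok & !lok]
  btd <- btv - ebtv
  s <- ifelse(btd >= 0, 100, pmax(0, 100 - 100 * abs(btd) / ebtv))
  as.numeric(s %*% frame$weight) / sum(frame$weight)
}

draw_group <- function(n, ms) pmax(0, rnorm(n, ms[1], ms[2]))

#' Simulate a study cohort with plantable regression effects
#'
#' Generates, per subject: group, age, gender, worst-eye visual acuity
#' (logMAR), a simulated monocular field pair (suspects always normal;
#' glaucoma subjects drawn from the archetype mixture) integrated into
#' an OU-VFI, MoCA total and visuospatial/executive sub-score, and
#' NEI-VFQ sub-scores. Vehicle-control outcomes are then generated on
#' the natural-log scale as the planted linear combination of age,
#' acuity, logit OU-VFI, MoCA total and VFQ driving score, plus a
#' per-subject random intercept and a per-drive residual, with
#' `drives_per_subject` repeated rows per subject. The whole table is a
#' pure function of the spec when `spec$seed` is set.
#'
#' @param spec A [cohort_spec()].
#' @param materialize_telemetry If `TRUE`, also simulate a telemetry
#'   trace per drive whose planted channel SDs are that drive's
#'   steering/acceleration outcomes, attached as the `telemetry`
#'   attribute (list named `<subject>_<drive>`), so that
#'   [drive_metrics()] approximately reproduces the planted values.
#' @param telemetry_duration Trace length in seconds when materialized.
#' @return A tibble (one row per subject-drive) with columns
#'   `subject_id`, `group`, `archetype`, `age`, `gender`, `va_worst`,
#'   `ou_vfi`, `moca_total`, `moca_visuospatial`, `vfq_total`,
#'   `vfq_peripheral`, `vfq_driving`, `drive`, `steering_sd`,
#'   `lat_accel_sd`, `mean_velocity`, `velocity_sd`, `max_velocity`,
#'   `pct_over_55`, `pct_over_60`, `long_accel_sd`; attribute `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            materialize_telemetry = FALSE,
                            telemetry_duration = 60) {
  if (!inherits(spec, "cohort_spec")) {
    ou_stop("`spec` must come from cohort_spec()", "spec")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_glaucoma + spec$n_suspect
  group <- rep(c("glaucoma", "suspect"), c(spec$n_glaucoma, spec$n_suspect))
  gl <- group == "glaucoma"

  mix <- spec$glaucoma_mixture / sum(spec$glaucoma_mixture)
  archetype <- rep("normal", n)
  archetype[gl] <- sample(names(mix), sum(gl), replace = TRUE, prob = mix)
  asymmetry <- abs(rnorm(n, 0, spec$asymmetry_sd))

  # fields: mean offsets per eye + Gaussian dB noise, integrated in batch
  od <- vf_pattern(spec$pattern, "OD")
  os <- vf_pattern(spec$pattern, "OS")
  off_os <- vapply(defect_archetypes(), archetype_offsets,
                   numeric(nrow(os)), grid = os)
  off_od <- vapply(defect_archetypes(), archetype_offsets,
                   numeric(nrow(od)), grid = od)
  l_mu <- t(off_os[, archetype, drop = FALSE])
  r_mu <- t(off_od[, archetype, drop = FALSE])
  relieve <- matrix(asymmetry, n, nrow(od))
  r_mu <- ifelse(r_mu < 0, pmin(0, r_mu + relieve), r_mu)
  l_td <- l_mu + matrix(rnorm(n * nrow(os), sd = spec$noise_sd), n)
  r_td <- r_mu + matrix(rnorm(n * nrow(od), sd = spec$noise_sd), n)
  frame <- integration_frame(spec$pattern)
  ou_vfi <- pmin(100, pmax(0, ou_vfi_batch(l_td, r_td, frame)))

  pick <- function(field) {
    ms <- spec[[field]]
    ifelse(gl, rnorm(n, ms$glaucoma[1], ms$glaucoma[2]),
           rnorm(n, ms$suspect[1], ms$suspect[2]))
  }
  age <- round(pick("age"))
  va <- round(pmax(0, pick("va_worst")), 2)
  moca <- pmin(30, pmax(0, round(pick("moca_total"))))
  vfq_d <- pmin(100, pmax(0, pick("vfq_driving")))
  vfq_p <- pmin(100, pmax(0, pick("vfq_peripheral")))
  vfq_t <- pmin(100, pmax(0, pick("vfq_total")))
  gender <- ifelse(rbinom(n, 1, ifelse(gl, spec$p_female["glaucoma"],
                                       spec$p_female["suspect"])) == 1,
                   "female", "male")
  lo <- logit_vfi(ou_vfi, eps = spec$logit_eps)
  z <- if (sd(lo) > 0) (lo - mean(lo)) / sd(lo) else numeric(n)
  moca_vs <- pmin(5, pmax(0, round(3.8 + 0.9 * (0.45 * z +
                                                sqrt(1 - 0.45^2) * rnorm(n)))))

  planted <- function(betas) {
    betas[["intercept"]] + betas[["age"]] * age +
      betas[["va_worst"]] * va + betas[["logit_ou"]] * lo +
      betas[["moca_total"]] * moca + betas[["vfq_driving"]] * vfq_d
  }
  mu_st <- planted(spec$betas_steering) + rnorm(n, 0, spec$subject_sd)
  mu_la <- planted(spec$betas_lat_accel) + rnorm(n, 0, spec$subject_sd)

  k <- spec$drives_per_subject
  idx <- rep(seq_len(n), each = k)
  nd <- n * k
  log_st <- mu_st[idx] + rnorm(nd, 0, spec$residual_sd)
  log_la <- mu_la[idx] + rnorm(nd, 0, spec$residual_sd)

  mean_v <- rep(rnorm(n, 24.85, 1.2), each = k) + rnorm(nd, 0, 0.2)
  vel_sd <- exp(rep(rnorm(n, log(1.58), 0.35), each = k) +
                rnorm(nd, 0, 0.1))
  max_v <- mean_v + 2.2 * vel_sd + abs(rnorm(nd, 0, 0.3))
  long_sd <- exp(rnorm(nd, log(0.02), 0.4))
  p55 <- 1 - stats::pnorm((55 * MPS_PER_MPH - mean_v) / vel_sd)
  p60 <- 1 - stats::pnorm((60 * MPS_PER_MPH - mean_v) / vel_sd)

  out <- tibble(
    subject_id = sprintf("S%03d", idx),
    group = group[idx], archetype = archetype[idx],
    age = age[idx], gender = gender[idx], va_worst = va[idx],
    ou_vfi = ou_vfi[idx], moca_total = moca[idx],
    moca_visuospatial = moca_vs[idx],
    vfq_total = vfq_t[idx], vfq_peripheral = vfq_p[idx],
    vfq_driving = vfq_d[idx],
    drive = rep(seq_len(k), n),
    steering_sd = exp(log_st), lat_accel_sd = exp(log_la),
    mean_velocity = mean_v, velocity_sd = vel_sd, max_velocity = max_v,
    pct_over_55 = p55, pct_over_60 = p60, long_accel_sd = long_sd
  )
  if (materialize_telemetry) {
    traces <- lapply(seq_len(nd), function(i) {
      simulate_telemetry(
        duration = telemetry_duration,
        target_speed = out$mean_velocity[i], speed_sd = out$velocity_sd[i],
        steering_sd = out$steering_sd[i],
        lat_accel_sd = out$lat_accel_sd[i],
        long_accel_sd = out$long_accel_sd[i]
      )
    })
    names(traces) <- paste0(out$subject_id, "_", out$drive)
    attr(out, "telemetry") <- traces
  }
  attr(out, "spec") <- spec
  out
}
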