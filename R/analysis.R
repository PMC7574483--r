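#' Logit transform of a visual field index
#'
#' Maps a 0-100% index to the log-odds scale, expanding the compressed
#' upper range (most intact fields sit between 90 and 100%) so the index
#' can enter linear models. The proportion is clamped into
#' `[eps, 1 - eps]` first, keeping fully intact (100%) and fully
#' impaired (0%) fields finite and ordered.
#'
#' @param vfi Index in percent, 0-100 (vectorized).
#' @param eps Clamp width on the proportion scale (default 0.005, i.e.
#'   100% maps to logit(0.995) = 5.293).
#' @return Log-odds values.
#' @examples
#' logit_vfi(c(50, 98.1, 100))
#' @export
logit_vfi <- function(vfi, eps = 0.005) {
  if (any(!is.finite(vfi)) || any(vfi < 0) || any(vfi > 100)) {
    ou_stop("`vfi` must lie in [0, 100]", "logit")
  }
  if (eps <= 0 || eps >= 0.5) {
    ou_stop("`eps` must lie in (0, 0.5)", "logit")
  }
  p <- pmin(1 - eps, pmax(eps, vfi / 100))
  log(p / (1 - p))
}

#' Natural-log transform for positive outcomes
#'
#' Vehicle-control variabilities are right-skewed and modelled on the
#' natural-log scale; `exp()` is the exact back-transform, and the
#' back-transformed mean of log values is the geometric mean.
#'
#' @param y Positive values.
#' @return `log(y)`.
#' @export
log_outcome <- function(y) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    ou_stop("`y` must be strictly positive", "log_outcome")
  }
  log(y)
}

#' Between-group comparisons of clinical characteristics
#'
#' Runs the descriptive comparison battery on a cohort table (collapsed
#' to one row per subject): continuous clinical variables by independent
#' two-sample t-test, with a Levene variance-equality pre-check (at
#' `levene_alpha`) selecting the pooled or Welch-Satterthwaite form;
#' MoCA scores by Wilcoxon rank-sum test; gender by chi-squared test;
#' and a Spearman correlation screen of the binocular VFI against the
#' MoCA scores. Zero-variance variables are flagged and skipped with a
#' warning rather than tested.
#'
#' @param cohort Cohort tibble (as from [simulate_cohort()] or read from
#'   file); needs `subject_id`, `group`, and whichever of the standard
#'   clinical columns are present.
#' @param continuous Continuous variables to compare (defaults to those
#'   present among age, acuity, OU-VFI and VFQ scores).
#' @param levene_alpha Significance level of the variance pre-check
#'   (default 0.05).
#' @return Tibble with columns `variable`, `test`, `estimate`
#'   (glaucoma minus suspect difference, or correlation), `statistic`,
#'   `df`, `p_value`, `note`.
#' @export
group_comparisons <- function(cohort,
                              continuous = NULL,
                              levene_alpha = 0.05) {
  d <- cohort[!duplicated(cohort$subject_id), , drop = FALSE]
  if (length(unique(d$group)) != 2) {
    ou_stop("cohort must contain exactly two groups", "comparisons")
  }
  g <- factor(d$group, levels = c("suspect", "glaucoma"))
  if (is.null(continuous)) {
    continuous <- intersect(
      c("age", "va_worst", "ou_vfi", "vfq_total", "vfq_peripheral",
        "vfq_driving"), names(d))
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- tibble(...)

  for (v in continuous) {
    x <- d[[v]]
    if (sd(x) == 0) {
      ou_warn(sprintf("'%s' has zero variance; test skipped", v),
              "zero_variance")
      add(variable = v, test = "t (skipped)", estimate = 0,
          statistic = NA_real_, df = NA_real_, p_value = NA_real_,
          note = "zero variance")
      next
    }
    lev <- car::leveneTest(x ~ g)
    pooled <- lev[["Pr(>F)"]][1] >= levene_alpha
    tt <- t.test(x ~ g, var.equal = pooled)
    add(variable = v,
        test = if (pooled) "t (pooled)" else "t (Welch)",
        estimate = unname(tt$estimate[2] - tt$estimate[1]),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value,
        note = sprintf("Levene p = %.3g", lev[["Pr(>F)"]][1]))
  }
  for (v in intersect(c("moca_total", "moca_visuospatial"), names(d))) {
    x <- d[[v]]
    if (sd(x) == 0) {
      ou_warn(sprintf("'%s' has zero variance; test skipped", v),
              "zero_variance")
      next
    }
    wt <- suppressWarnings(wilcox.test(x ~ g))
    add(variable = v, test = "Wilcoxon rank-sum",
        estimate = median(x[g == "glaucoma"]) - median(x[g == "suspect"]),
        statistic = unname(wt$statistic), df = NA_real_,
        p_value = wt$p.value, note = "")
  }
  if ("gender" %in% names(d) && length(unique(d$gender)) > 1) {
    ct <- suppressWarnings(chisq.test(table(d$group, d$gender)))
    add(variable = "gender", test = "chi-squared",
        estimate = NA_real_, statistic = unname(ct$statistic),
        df = unname(ct$parameter), p_value = ct$p.value, note = "")
  }
  if ("ou_vfi" %in% names(d)) {
    for (v in intersect(c("moca_total", "moca_visuospatial"), names(d))) {
      if (sd(d[[v]]) == 0 || sd(d$ou_vfi) == 0) next
      sp <- suppressWarnings(
        cor.test(d$ou_vfi, d[[v]], method = "spearman"))
      add(variable = paste0("ou_vfi~", v), test = "Spearman",
          estimate = unname(sp$estimate), statistic = unname(sp$statistic),
          df = NA_real_, p_value = sp$p.value, note = "")
    }
  }
  do.call(rbind, rows)
}

#' Multivariable model of a vehicle-control outcome
#'
#' Fits the study's multivariable model: the natural log of a
#' vehicle-control variability outcome against age, worst-eye visual
#' acuity, a disease-burden exposure (logit of the binocular VFI, or
#' glaucoma group), MoCA total score and VFQ driving sub-score, with a
#' per-subject random intercept over repeated drives. Degrees of
#' freedom, F and p per term use the Kenward-Roger small-sample
#' correction by default (Satterthwaite available as a faster option).
#' With only one drive per subject the random intercept is not
#' estimable and the model degrades to ordinary least squares, with a
#' message.
#'
#' A standardized effect size is reported per term: Cohen's
#' d = 2t / sqrt(df) for continuous terms and the group contrast.
#'
#' @param cohort Cohort tibble, one row per subject-drive.
#' @param outcome `"steering_sd"` or `"lat_accel_sd"`.
#' @param exposure `"logit_ou"` (logit-transformed `ou_vfi`) or
#'   `"group"` (glaucoma vs suspect).
#' @param ddf Denominator-df method for the mixed model,
#'   `"Kenward-Roger"` (default) or `"Satterthwaite"`.
#' @param logit_eps Clamp for the logit transform.
#' @return Tibble with columns `term`, `estimate`, `se`, `df`,
#'   `t_value`, `f_value`, `p_value`, `cohens_d`, plus attributes
#'   `fit` (the model object) and `method` (`"lmm"` or `"ols"`).
#' @export
fit_vehicle_control_model <- function(cohort,
                                      outcome = c("steering_sd",
                                                  "lat_accel_sd"),
                                      exposure = c("logit_ou", "group"),
                                      ddf = c("Kenward-Roger",
                                              "Satterthwaite"),
                                      logit_eps = 0.005) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  ddf <- match.arg(ddf)
  need <- c("subject_id", "age", "va_worst", "moca_total", "vfq_driving",
            outcome, if (exposure == "logit_ou") "ou_vfi" else "group")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    ou_stop(paste("cohort is missing column(s):",
                  paste(miss, collapse = ", ")), "model")
  }
  d <- data.frame(
    subject_id = cohort$subject_id,
    log_y = log_outcome(cohort[[outcome]]),
    age = cohort$age, va_worst = cohort$va_worst,
    moca_total = cohort$moca_total, vfq_driving = cohort$vfq_driving
  )
  d$exposure <- if (exposure == "logit_ou") {
    logit_vfi(cohort$ou_vfi, eps = logit_eps)
  } else {
    factor(cohort$group, levels = c("suspect", "glaucoma"))
  }
  cc <- complete.cases(d)
  if (sum(!cc) > 0) {
    message(sprintf("dropping %d row(s) with missing covariates",
                    sum(!cc)))
    d <- d[cc, , drop = FALSE]
  }
  fixed <- log_y ~ age + va_worst + exposure + moca_total + vfq_driving
  mm <- model.matrix(fixed, d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    ou_stop(paste("design is rank deficient; collinear term(s):",
                  paste(bad, collapse = ", ")), "model")
  }
  repeated <- any(table(d$subject_id) >= 2)
  if (repeated) {
    fit <- lmerTest::lmer(
      log_y ~ age + va_worst + exposure + moca_total + vfq_driving +
        (1 | subject_id),
      data = d, control = lme4::lmerControl(calc.derivs = FALSE))
    ct <- coef(summary(fit, ddf = ddf))
    method <- "lmm"
  } else {
    message("single drive per subject: fitting ordinary least squares")
    fit <- lm(fixed, data = d)
    ct <- coef(summary(fit))
    ct <- cbind(ct[, 1:2], df = fit$df.residual, ct[, 3:4])
    method <- "ols"
  }
  term <- rownames(ct)
  term[term == "exposure"] <- exposure
  term[term == "exposureglaucoma"] <- "group_glaucoma"
  tval <- unname(ct[, grep("^t value", colnames(ct))])
  dfs <- unname(ct[, "df"])
  out <- tibble(
    term = term,
    estimate = unname(ct[, "Estimate"]),
    se = unname(ct[, "Std. Error"]),
    df = dfs,
    t_value = tval,
    f_value = tval^2,
    p_value = unname(ct[, grep("^Pr", colnames(ct))]),
    cohens_d = 2 * tval / sqrt(dfs)
  )
  out$cohens_d[out$term == "(Intercept)"] <- NA_real_
  attr(out, "fit") <- fit
  attr(out, "method") <- method
  attr(out, "outcome") <- outcome
  out
}
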