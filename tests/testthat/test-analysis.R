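# small deterministic cohort builder for model-property tests: planted
# structure but no reliance on the full generator
toy_cohort <- function(n = 30, drives = 2, beta_expo = -0.2, seed = 1,
                       group_gap = 0) {
  set.seed(seed)
  age <- round(rnorm(n, 66, 12))
  va <- round(pmax(0, rnorm(n, 0.1, 0.1)), 2)
  moca <- pmin(30, pmax(15, round(rnorm(n, 25, 2.7))))
  vfq <- pmin(100, pmax(30, rnorm(n, 84, 14)))
  group <- rep(c("glaucoma", "suspect"), length.out = n)
  vfi <- ifelse(group == "glaucoma", runif(n, 30, 98), runif(n, 96, 100))
  lo <- logit_vfi(vfi)
  mu <- -1.5 + beta_expo * lo + group_gap * (group == "glaucoma") +
    rnorm(n, 0, 0.3)
  idx <- rep(seq_len(n), each = drives)
  tibble::tibble(
    subject_id = sprintf("S%02d", idx), group = group[idx],
    age = age[idx], gender = "female", va_worst = va[idx],
    ou_vfi = vfi[idx], moca_total = moca[idx],
    vfq_driving = vfq[idx],
    drive = rep(seq_len(drives), n),
    steering_sd = exp(mu[idx] + rnorm(n * drives, 0, 0.25)),
    lat_accel_sd = exp(mu[idx] - 4 + rnorm(n * drives, 0, 0.25))
  )
}

test_that("logit transform matches closed forms and clamps the endpoints", {
  expect_equal(logit_vfi(50), 0)
  expect_equal(logit_vfi(98.1), log(0.981 / 0.019), tolerance = 1e-12)
  expect_equal(logit_vfi(98.1), 3.944, tolerance = 1e-4)
  expect_equal(logit_vfi(100), log(0.995 / 0.005), tolerance = 1e-12)
  expect_equal(logit_vfi(0), -log(0.995 / 0.005), tolerance = 1e-12)
  expect_true(all(diff(logit_vfi(seq(0, 100, 0.5))) >= 0))  # ordered
  expect_error(logit_vfi(101), class = "oudrive_error_logit")
  expect_error(logit_vfi(-0.1), class = "oudrive_error_logit")
})

test_that("log transform round-trips and back-transforms geometrically", {
  expect_equal(log_outcome(1), 0)
  set.seed(3)
  y <- exp(rnorm(50))
  expect_equal(exp(log_outcome(y)), y, tolerance = 1e-12)
  expect_error(log_outcome(0), class = "oudrive_error_log_outcome")
  expect_error(log_outcome(-2), class = "oudrive_error_log_outcome")
  # lognormal identity: geometric mean of back-transformed CI bounds
  # equals the back-transformed point estimate
  fit <- lm(log_outcome(y) ~ 1)
  ci <- exp(confint(fit))
  expect_equal(sqrt(ci[1] * ci[2]), exp(coef(fit)[[1]]), tolerance = 1e-9)
})

test_that("identical groups compare as null", {
  half <- toy_cohort(n = 16, drives = 1)
  twin <- half
  twin$subject_id <- paste0(half$subject_id, "b")
  twin$group <- ifelse(half$group == "glaucoma", "suspect", "glaucoma")
  co <- rbind(half, twin)  # every value present once in each group
  res <- group_comparisons(co)
  tt <- res[grepl("^t ", res$test), ]
  expect_true(all(abs(tt$estimate) < 1e-9))
  expect_true(all(tt$p_value > 0.999))
})

test_that("a planted two-SD mean shift is detected with high power", {
  hits <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    co <- tibble::tibble(
      subject_id = sprintf("S%02d", 1:40),
      group = rep(c("glaucoma", "suspect"), each = 20),
      age = rnorm(40, 65, 1) + 2 * (rep(c(1, 0), each = 20))
    )
    res <- group_comparisons(co, continuous = "age")
    hits <- hits + (res$p_value[1] < 0.05)
  }
  expect_gt(hits / 100, 0.95)
})

test_that("Spearman screen reports perfect monotone association", {
  co <- toy_cohort(n = 20, drives = 1)
  co$moca_total <- rank(co$ou_vfi)  # strictly monotone in VFI
  res <- group_comparisons(co)
  expect_equal(res$estimate[res$variable == "ou_vfi~moca_total"], 1)
})

test_that("zero-variance variables are flagged and skipped", {
  co <- toy_cohort(n = 12, drives = 1)
  co$va_worst <- 0.1
  expect_warning(res <- group_comparisons(co),
                 class = "oudrive_warning_zero_variance")
  row <- res[res$variable == "va_worst", ]
  expect_true(is.na(row$p_value))
  expect_match(row$note, "zero variance")
})

test_that("single-drive cohorts fall back to the equivalent OLS fit", {
  co <- toy_cohort(n = 40, drives = 1, seed = 6)
  expect_message(res <- fit_vehicle_control_model(co, "steering_sd",
                                                  "logit_ou"),
                 "ordinary least squares")
  expect_equal(attr(res, "method"), "ols")
  ref <- lm(log(steering_sd) ~ age + va_worst + logit_vfi(ou_vfi) +
              moca_total + vfq_driving, data = co)
  expect_equal(res$estimate, unname(coef(ref)), tolerance = 1e-9)
})

test_that("mixed model recovers a planted exposure effect", {
  co <- toy_cohort(n = 60, drives = 2, beta_expo = -0.2, seed = 12)
  res <- fit_vehicle_control_model(co, "steering_sd", "logit_ou")
  row <- res[res$term == "logit_ou", ]
  expect_lt(abs(row$estimate - (-0.2)), 2.5 * row$se)
  expect_lt(row$p_value, 0.01)
  expect_true(all(res$se > 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # F = t^2 and d = 2t/sqrt(df) bookkeeping
  expect_equal(res$f_value, res$t_value^2, tolerance = 1e-12)
  expect_equal(res$cohens_d[-1], 2 * res$t_value[-1] / sqrt(res$df[-1]),
               tolerance = 1e-12)
})

test_that("a planted group gap shows as glaucoma > suspect", {
  co <- toy_cohort(n = 50, drives = 2, beta_expo = 0, group_gap = 0.8,
                   seed = 21)
  res <- fit_vehicle_control_model(co, "steering_sd", "group")
  row <- res[res$term == "group_glaucoma", ]
  expect_gt(row$estimate, 0)
  expect_lt(row$p_value, 0.01)
})

test_that("model estimates are affine- and permutation-invariant", {
  co <- toy_cohort(n = 40, drives = 2, seed = 9)
  base <- fit_vehicle_control_model(co, "steering_sd", "logit_ou")
  shifted <- co
  shifted$age <- shifted$age + 10
  res <- fit_vehicle_control_model(shifted, "steering_sd", "logit_ou")
  keep <- base$term != "(Intercept)"
  expect_equal(res$estimate[keep], base$estimate[keep], tolerance = 1e-6)
  expect_false(isTRUE(all.equal(res$estimate[1], base$estimate[1])))

  perm <- co[sample(nrow(co)), ]
  res2 <- fit_vehicle_control_model(perm, "steering_sd", "logit_ou")
  expect_equal(res2$estimate, base$estimate, tolerance = 1e-9)
  expect_equal(res2$p_value, base$p_value, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming the culprit", {
  co <- toy_cohort(n = 30, drives = 2, seed = 2)
  co$va_worst <- 0.1  # constant: collinear with the intercept
  err <- tryCatch(fit_vehicle_control_model(co, "steering_sd", "logit_ou"),
                  error = identity)
  expect_s3_class(err, "oudrive_error_model")
  expect_match(conditionMessage(err), "va_worst")
})

test_that("rows with missing covariates are dropped with a notice", {
  co <- toy_cohort(n = 30, drives = 2, seed = 5)
  co$moca_total[3] <- NA
  expect_message(res <- fit_vehicle_control_model(co, "steering_sd",
                                                  "logit_ou"),
                 "dropping 1 row")
  expect_s3_class(res, "tbl_df")
  expect_error(fit_vehicle_control_model(co[, -1], "steering_sd",
                                         "logit_ou"),
               class = "oudrive_error_model")
})
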