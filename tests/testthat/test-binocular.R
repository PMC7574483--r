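test_that("binocular threshold matches closed-form worked examples", {
  # equal eyes gain exactly 10*log10(sqrt(2)) dB
  expect_equal(binocular_threshold(30, 30), 30 + 10 * log10(sqrt(2)),
               tolerance = 1e-9)
  expect_equal(binocular_threshold(30, 30), 31.5051, tolerance = 1e-4)
  expect_equal(binocular_threshold(30, 0), 30.0000021714713,
               tolerance = 1e-9)
  expect_equal(binocular_threshold(20, 30), 30.0216068689,
               tolerance = 1e-6)
  expect_error(binocular_threshold(NA, 30), class = "oudrive_error_nonfinite")
  expect_error(binocular_threshold(30, Inf), class = "oudrive_error_nonfinite")
})

test_that("binocular summation is bounded by the better eye and +1.50515 dB", {
  set.seed(42)
  l <- runif(1e4, -10, 40)
  r <- runif(1e4, -10, 40)
  b <- binocular_threshold(l, r)
  hi <- pmax(l, r)
  expect_true(all(b >= hi))
  expect_true(all(b <= hi + 1.50515))
  # ceiling is attained exactly at equality
  expect_equal(binocular_threshold(l, l), l + 10 * log10(sqrt(2)),
               tolerance = 1e-9)
})

test_that("expected binocular threshold uses the normative surfaces", {
  expect_equal(expected_binocular_threshold(28, -2, 30, 0),
               binocular_threshold(30, 30), tolerance = 1e-12)
  expect_equal(expected_binocular_threshold(30, 0, 30, 0),
               31.5051, tolerance = 1e-4)
  # any TV/TD pair with the same normative value gives the same result
  expect_equal(expected_binocular_threshold(25, -5, 20, -10),
               31.5051, tolerance = 1e-4)
})

test_that("binocular total deviation is observed minus expected", {
  expect_equal(binocular_total_deviation(28, -2, 30, 0), -0.777447662773,
               tolerance = 1e-6)  # frozen from the scalar oracle
  expect_equal(binocular_total_deviation(30, 0, 30, 0), 0, tolerance = 1e-12)
  # one-eye-only location degenerates to the seeing eye's monocular TD
  expect_equal(binocular_total_deviation(28, -2, NA, NA), -2)
  expect_equal(binocular_total_deviation(NA, NA, 24, -6), -6)
  expect_error(binocular_total_deviation(NA, NA, NA, NA),
               class = "oudrive_error_merge")
})

test_that("sensitivity transform is piecewise, clamped and continuous", {
  expect_equal(vf_sensitivity(0, 31.5), 100)
  expect_equal(vf_sensitivity(2.3, 31.5), 100)  # at/above expectation
  expect_equal(vf_sensitivity(-0.7767, 31.5051), 97.5346848605,
               tolerance = 1e-6)
  # deep absolute defect: raw formula would go to -26.96, floored at 0
  expect_equal(vf_sensitivity(-40, 31.5051), 0)
  # continuity at btd = 0
  expect_equal(vf_sensitivity(-1e-9, 30), 100, tolerance = 1e-7)
  expect_error(vf_sensitivity(-1, 0), class = "oudrive_error_sensitivity")
  expect_error(vf_sensitivity(-1, -5), class = "oudrive_error_sensitivity")
})

test_that("weighted VFI is the weighted mean of sensitivities", {
  w <- vf_weights(vf_pattern("24-2"))$weight
  expect_equal(weighted_vfi(rep(100, length(w)), w), 100)
  expect_equal(weighted_vfi(rep(0, length(w)), w), 0)
  expect_equal(weighted_vfi(c(100, 0), c(3.29, 0.45)), 100 * 329 / 374,
               tolerance = 1e-9)
  expect_error(weighted_vfi(c(100, 100), c(0, 0)), class = "oudrive_error_vfi")
  expect_error(weighted_vfi(c(100, NA), c(1, 1)), class = "oudrive_error_vfi")
})

test_that("fully normal fields integrate to OU-VFI of exactly 100", {
  bf <- integrate_fields(flat_field("OS", 0), flat_field("OD", 0))
  expect_equal(bf$vfi, 100)
  expect_equal(bf$data$btd, rep(0, nrow(bf$data)), tolerance = 1e-12)
  expect_equal(bf$data$s, rep(100, nrow(bf$data)))
  # union frame of the 24-2: 54 per eye, 48 shared
  expect_equal(nrow(bf$data), 56)
  expect_equal(sum(bf$data$n_eyes == 1), 8)
})

test_that("uniform monocular depression gives the frozen oracle OU-VFI", {
  # left eye normal, right eye TD = -10 dB everywhere, flat 30 dB surface;
  # value frozen from the independent scalar oracle
  bf <- integrate_fields(flat_field("OS", 0), flat_field("OD", -10))
  expect_equal(bf$vfi, 94.2000391414, tolerance = 1e-6)
  both <- bf$data$n_eyes == 2
  expect_equal(unique(round(bf$data$btv[both], 6)), 30.021607)
  expect_equal(unique(round(bf$data$btd[both], 6)), -1.483543)
})

test_that("integration is symmetric in the eyes", {
  set.seed(7)
  pair <- random_pair()
  a <- integrate_fields(pair$left, pair$right)
  b <- integrate_fields(pair$right, pair$left)
  expect_equal(a$vfi, b$vfi)
  expect_equal(a$data, b$data)
  expect_error(integrate_fields(pair$right, pair$right),
               class = "oudrive_error_integrate")
})

test_that("integration matches the independent per-location oracle", {
  set.seed(123)
  for (i in 1:20) {
    pair <- random_pair()
    got <- integrate_fields(pair$left, pair$right)
    ref <- oracle_integrate(field_df(pair$left), field_df(pair$right))
    expect_equal(got$vfi, ref$vfi, tolerance = 1e-6)
    m <- match(paste(got$data$x, got$data$y), paste(ref$data$x, ref$data$y))
    expect_equal(got$data$btv, ref$data$btv[m], tolerance = 1e-6)
    expect_equal(got$data$btd, ref$data$btd[m], tolerance = 1e-6)
    expect_equal(got$data$s, ref$data$s[m], tolerance = 1e-6)
    # internal consistency at every location
    expect_equal(got$data$btd, got$data$btv - got$data$expected_btv,
                 tolerance = 1e-9)
  }
})

test_that("worsening any single location never raises the OU-VFI", {
  set.seed(11)
  pair <- random_pair()
  base <- integrate_fields(pair$left, pair$right)$vfi
  g <- pair$left$data
  idx <- sample(which(is.finite(g$td)), 12)
  for (i in idx) {
    for (delta in c(2, 8, 25)) {
      worse <- g
      worse$tv[i] <- worse$tv[i] - delta   # deviation worsens with it:
      worse$td[i] <- worse$td[i] - delta   # normative part held fixed
      f <- monocular_field("OS", "24-2", worse$x, worse$y, worse$tv,
                           worse$td)
      expect_lte(integrate_fields(f, pair$right)$vfi, base + 1e-9)
    }
  }
})

test_that("mixed 24-2 / 30-2 pairs integrate on the intersection", {
  os24 <- flat_field("OS", 0, pattern = "24-2")
  g30 <- vf_pattern("30-2", eye = "OD")
  od30 <- monocular_field("OD", "30-2", g30$x, g30$y,
                          tv = rep(30, 76), td = rep(0, 76))
  bf <- integrate_fields(os24, od30)
  # every OS 24-2 location (including its nasal column) is in the 30-2
  expect_equal(nrow(bf$data), 54)
  expect_equal(bf$vfi, 100)
})
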