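#' Binocular threshold by quadratic summation
#'
#' Combines left- and right-eye perimetric thresholds into a binocular
#' threshold estimate. Decibel thresholds are converted to linear
#' sensitivity (`10^(TV/10)`), combined by quadratic (root-sum-square)
#' summation, and converted back:
#' \deqn{bTV = 10 \log_{10} \sqrt{(10^{lTV/10})^2 + (10^{rTV/10})^2}}
#' The binocular estimate is never below the better eye and never more
#' than \eqn{10\log_{10}\sqrt{2} \approx 1.505} dB above it (the
#' binocular summation ceiling, reached when the eyes are equal).
#'
#' @param l_tv,r_tv Left/right threshold values in dB (vectorized; may be
#'   negative for measured absolute defects).
#' @return Binocular threshold in dB.
#' @examples
#' binocular_threshold(30, 30)  # 31.5051
#' @export
binocular_threshold <- function(l_tv, r_tv) {
  check_finite(l_tv, "l_tv")
  check_finite(r_tv, "r_tv")
  # 10*log10(sqrt(a^2 + b^2)) with a = 10^(l/10): algebraically
  # 5*log10(10^(l/5) + 10^(r/5)), evaluated stably around the larger term
  hi <- pmax(l_tv, r_tv)
  lo <- pmin(l_tv, r_tv)
  hi + 5 * log10(1 + 10^((lo - hi) / 5))
}

#' Expected binocular threshold from normative monocular surfaces
#'
#' The same quadratic summation applied to each eye's age-normal
#' expected threshold, `TV - TD` (threshold value minus total deviation).
#'
#' @param l_tv,l_td,r_tv,r_td Monocular TV and TD in dB (vectorized).
#' @return Expected binocular threshold in dB.
#' @export
expected_binocular_threshold <- function(l_tv, l_td, r_tv, r_td) {
  check_finite(l_td, "l_td")
  check_finite(r_td, "r_td")
  binocular_threshold(l_tv - l_td, r_tv - r_td)
}

#' Binocular total deviation at one location
#'
#' Observed minus expected binocular threshold,
#' `bTD = bTV - expected bTV`. Where only one eye contributes (the
#' fellow eye's blind spot, or a location outside its tested pattern,
#' passed as `NA`) the quadratic sum degenerates to the seeing eye's
#' single term, so bTD equals that eye's monocular TD.
#'
#' @param l_tv,l_td,r_tv,r_td Monocular TV/TD in dB; `NA` marks an eye
#'   with no measurement at the location. Vectorized.
#' @return Binocular total deviation in dB.
#' @export
binocular_total_deviation <- function(l_tv, l_td, r_tv, r_td) {
  m <- merge_locations(l_tv, l_td, r_tv, r_td)
  m$btv - m$expected_btv
}

# single-eye fallback merge shared by binocular_total_deviation() and
# integrate_fields(); inputs may contain NA meaning "eye not measured here"
merge_locations <- function(l_tv, l_td, r_tv, r_td) {
  n <- max(length(l_tv), length(r_tv))
  l_tv <- rep_len(as.numeric(l_tv), n); l_td <- rep_len(as.numeric(l_td), n)
  r_tv <- rep_len(as.numeric(r_tv), n); r_td <- rep_len(as.numeric(r_td), n)
  has_l <- is.finite(l_tv) & is.finite(l_td)
  has_r <- is.finite(r_tv) & is.finite(r_td)
  if (any(!has_l & !has_r)) {
    ou_stop("location with no measurement in either eye", "merge")
  }
  btv <- expected <- numeric(n)
  both <- has_l & has_r
  if (any(both)) {
    btv[both] <- binocular_threshold(l_tv[both], r_tv[both])
    expected[both] <- expected_binocular_threshold(
      l_tv[both], l_td[both], r_tv[both], r_td[both])
  }
  lo <- has_l & !has_r
  btv[lo] <- l_tv[lo]; expected[lo] <- l_tv[lo] - l_td[lo]
  ro <- has_r & !has_l
  btv[ro] <- r_tv[ro]; expected[ro] <- r_tv[ro] - r_td[ro]
  list(btv = btv, expected_btv = expected,
       n_eyes = as.integer(has_l) + as.integer(has_r))
}

#' Pointwise sensitivity from binocular total deviation
#'
#' Maps binocular total deviation to a 0-100 sensitivity score: 100
#' wherever the location is at or above its normative expectation
#' (`btd >= 0`), otherwise the percent of the expected threshold that
#' remains, floored at 0:
#' \deqn{S = \max\{0,\; 100 - 100\,|bTD|/\overline{bTV}\}\ (bTD<0);\quad
#'       S = 100\ (bTD \ge 0)}
#' The floor is a deliberate deviation from the literal piecewise
#' formula, which goes negative once the deviation exceeds the expected
#' threshold (deep absolute defects); the score's defined range is
#' 0 (fully impaired) to 100 (fully intact).
#'
#' @param btd Binocular total deviation, dB (vectorized).
#' @param expected_btv Expected binocular threshold, dB; must be > 0.
#' @return Sensitivity in percent, 0-100.
#' @export
vf_sensitivity <- function(btd, expected_btv) {
  check_finite(btd, "btd")
  check_finite(expected_btv, "expected_btv")
  if (any(expected_btv <= 0)) {
    ou_stop("expected_btv must be positive (degenerate normative value)",
            "sensitivity")
  }
  ifelse(btd >= 0, 100, pmax(0, 100 - 100 * abs(btd) / expected_btv))
}

#' Eccentricity-weighted visual field index
#'
#' Weighted mean of pointwise sensitivities,
#' \deqn{VFI = \sum S_{ij} W_{ij} \big/ \sum 100\, W_{ij} \times 100\%,}
#' so an all-intact map (S = 100 everywhere) scores exactly 100% and an
#' all-impaired one 0%. Locations with weight 0 (blind spots) do not
#' contribute.
#'
#' @param s Sensitivities in percent (0-100); must be defined wherever
#'   `w > 0`.
#' @param w Non-negative weights, e.g. the `weight` column from
#'   [vf_weights()].
#' @return The index, percent in \[0, 100\].
#' @examples
#' weighted_vfi(c(100, 0), c(3.29, 0.45))  # 87.97
#' @export
weighted_vfi <- function(s, w) {
  if (length(s) != length(w)) {
    ou_stop("s and w must have equal length", "vfi")
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    ou_stop("weights must be finite and non-negative", "vfi")
  }
  if (sum(w) <= 0) {
    ou_stop("all weights are zero", "vfi")
  }
  use <- w > 0
  if (any(!is.finite(s[use]))) {
    ou_stop("s must be defined wherever w > 0", "vfi")
  }
  sum(s[use] * w[use]) / sum(100 * w[use]) * 100
}

#' Integrate two monocular fields into a binocular field
#'
#' Runs the full binocular derivation on an OD/OS pair: per location,
#' observed and expected binocular thresholds by quadratic summation of
#' linear sensitivities, their difference (binocular total deviation),
#' the 0-100 sensitivity transform, and finally the eccentricity-weighted
#' binocular visual field index (OU-VFI).
#'
#' The two fields are merged on the union of their tested locations
#' (restricted to the coordinate intersection when the patterns differ,
#' e.g. a 24-2 paired with a 30-2). At a location measured by only one
#' eye — the fellow eye's physiologic blind spot, or its untested nasal
#' column — the seeing eye's values are used alone, the consistent
#' degenerate limit of the summation. Every merged location keeps its
#' eccentricity-ring weight; a location is dropped only if neither eye
#' measured it. The arguments may be given in either order; the result is
#' symmetric in the eyes.
#'
#' @param left,right [monocular_field()] objects, one OD and one OS (any
#'   argument order).
#' @param ring_boundaries,ring_weights Ring configuration passed to the
#'   weighting step; defaults [vf_ring_boundaries()], [vf_ring_weights()].
#' @return A list of class `binocular_field`: `data` (per-location tibble
#'   with `x`, `y`, `eccentricity`, `ring`, `weight`, the monocular
#'   inputs, `btv`, `expected_btv`, `btd`, `s`, `n_eyes`), scalar `vfi`,
#'   and `pattern`.
#' @examples
#' pair <- simulate_monocular_pair("normal", noise_sd = 0, seed = 1)
#' integrate_fields(pair$left, pair$right)$vfi  # 100
#' @export
integrate_fields <- function(left, right,
                             ring_boundaries = vf_ring_boundaries(),
                             ring_weights = vf_ring_weights()) {
  if (!inherits(left, "monocular_field") ||
      !inherits(right, "monocular_field")) {
    ou_stop("left and right must be monocular_field objects", "integrate")
  }
  eyes <- c(left$eye, right$eye)
  if (setequal(eyes, c("OD", "OS"))) {
    if (left$eye == "OD") { tmp <- left; left <- right; right <- tmp }
  } else {
    ou_stop(sprintf("need one OD and one OS field, got %s and %s",
                    eyes[1], eyes[2]), "integrate")
  }
  check_ring_config(ring_boundaries, ring_weights)

  l <- left$data   # OS
  r <- right$data  # OD
  lkey <- paste(l$x, l$y)
  rkey <- paste(r$x, r$y)
  keys <- if (left$pattern == right$pattern) {
    union(lkey, rkey)
  } else {
    intersect(lkey, rkey)
  }
  if (length(keys) == 0) {
    ou_stop("fields share no test locations", "integrate")
  }
  li <- match(keys, lkey)
  ri <- match(keys, rkey)
  x <- ifelse(is.na(li), r$x[ri], l$x[li])
  y <- ifelse(is.na(li), r$y[ri], l$y[li])
  l_tv <- ifelse(is.na(li), NA_real_, l$tv[li])
  l_td <- ifelse(is.na(li), NA_real_, l$td[li])
  r_tv <- ifelse(is.na(ri), NA_real_, r$tv[ri])
  r_td <- ifelse(is.na(ri), NA_real_, r$td[ri])

  seen <- (is.finite(l_tv) & is.finite(l_td)) |
          (is.finite(r_tv) & is.finite(r_td))
  if (!any(seen)) {
    ou_stop("no location measured in either eye", "integrate")
  }
  keep <- which(seen)
  m <- merge_locations(l_tv[keep], l_td[keep], r_tv[keep], r_td[keep])
  btd <- m$btv - m$expected_btv
  s <- vf_sensitivity(btd, m$expected_btv)

  ecc <- sqrt(x[keep]^2 + y[keep]^2)
  ring <- findInterval(ecc, ring_boundaries) + 1L
  w <- ring_weights[ring]

  data <- tibble(
    x = x[keep], y = y[keep], eccentricity = ecc, ring = ring, weight = w,
    l_tv = l_tv[keep], l_td = l_td[keep],
    r_tv = r_tv[keep], r_td = r_td[keep],
    btv = m$btv, expected_btv = m$expected_btv, btd = btd, s = s,
    n_eyes = m$n_eyes
  )
  data <- data[order(-data$y, data$x), ]
  structure(
    list(data = data,
         vfi = weighted_vfi(data$s, data$weight),
         pattern = if (left$pattern == right$pattern) left$pattern
                   else paste(sort(c(left$pattern, right$pattern)),
                              collapse = "/")),
    class = "binocular_field"
  )
}

#' @exportS3Method base::print
print.binocular_field <- function(x, ...) {
  cat(sprintf("<binocular_field> %s, %d locations\n",
              x$pattern, nrow(x$data)))
  cat(sprintf("  OU-VFI %.2f%%, mean bTD %.2f dB\n",
              x$vfi, mean(x$data$btd)))
  invisible(x)
}

check_finite <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x))) {
    ou_stop(sprintf("`%s` must be finite", name), "nonfinite")
  }
  invisible(TRUE)
}
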