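#' Monocular visual field
#'
#' Bundles one eye's threshold values (TV, dB) and total deviations (TD,
#' dB) on a perimetry pattern. TD is TV minus the age-normal expected
#' threshold at that location, so `tv - td` recovers the normative
#' surface; both must be finite at every non-blind-spot location. Values
#' at the eye's own blind-spot locations are stored as `NA`.
#'
#' @param eye `"OD"` or `"OS"`.
#' @param pattern `"24-2"` or `"30-2"`.
#' @param x,y Location coordinates (degrees, visual-field frame). Must
#'   match the tested locations of `vf_pattern(pattern, eye)` exactly
#'   (any order, no duplicates).
#' @param tv,td Threshold value and total deviation (dB) per location.
#'   Values below 0 dB (instrument-measured absolute defects) are
#'   accepted as given.
#' @param reliability Optional named list with fixation-loss /
#'   false-positive / false-negative fractions, carried as metadata.
#' @return A list of class `monocular_field` with elements `eye`,
#'   `pattern`, `data` (tibble `x`, `y`, `tv`, `td`) and `reliability`.
#' @examples
#' g <- vf_pattern("24-2", eye = "OD")
#' f <- monocular_field("OD", "24-2", g$x, g$y,
#'                      tv = rep(30, nrow(g)), td = rep(0, nrow(g)))
#' @export
monocular_field <- function(eye = c("OD", "OS"), pattern, x, y, tv, td,
                            reliability = NULL) {
  eye <- match.arg(eye)
  pattern <- normalize_pattern(pattern)
  n <- length(x)
  if (length(y) != n || length(tv) != n || length(td) != n) {
    ou_stop("x, y, tv, td must have equal length", "field")
  }
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ou_stop(sprintf("duplicate test location (%s)", dup), "field")
  }
  grid <- vf_pattern(pattern, eye = eye)
  gkey <- paste(grid$x, grid$y)
  if (!setequal(key, gkey)) {
    missing <- setdiff(gkey, key)
    extra <- setdiff(key, gkey)
    ou_stop(sprintf(
      "locations do not match the %s %s grid (%d missing, %d unknown)",
      pattern, eye, length(missing), length(extra)), "field")
  }
  ord <- match(gkey, key)
  tv <- as.numeric(tv)[ord]
  td <- as.numeric(td)[ord]
  blind <- if (eye == "OD") grid$blind_od else grid$blind_os
  bad <- !blind & (!is.finite(tv) | !is.finite(td))
  if (any(bad)) {
    ou_stop(sprintf(
      "tv and td must be finite at every non-blind-spot location (%d bad)",
      sum(bad)), "field")
  }
  tv[blind] <- NA_real_
  td[blind] <- NA_real_
  structure(
    list(eye = eye, pattern = pattern,
         data = tibble(x = grid$x, y = grid$y, tv = tv, td = td),
         reliability = reliability),
    class = "monocular_field"
  )
}

#' @exportS3Method base::print
print.monocular_field <- function(x, ...) {
  ok <- is.finite(x$data$td)
  cat(sprintf("<monocular_field> %s %s, %d locations\n",
              x$eye, x$pattern, nrow(x$data)))
  cat(sprintf("  TD mean %.2f dB (range %.1f to %.1f)\n",
              mean(x$data$td[ok]), min(x$data$td[ok]), max(x$data$td[ok])))
  invisible(x)
}
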