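#' Standard automated perimetry test patterns
#'
#' Builds the test-location grid of a Humphrey-style static perimetry
#' pattern in visual-field coordinates: `x` in degrees of visual angle,
#' positive toward the subject's right; `y` positive superior. Both eyes
#' share this frame, so binocular overlay is coordinate-identical; only
#' the blind-spot column and the nasal extension differ by laterality.
#'
#' The 24-2 pattern tests 54 locations on the 6-degree offset lattice
#' (all coordinates odd multiples of 3): the core extends to 21 degrees
#' with corners trimmed at `|x| + |y| > 30`, plus two nasal points at 27
#' degrees (`x = -27` for OD, `x = +27` for OS, at `y = +-3`). The 30-2
#' pattern tests 76 locations (`|x| + |y| <= 36`) and is the same for
#' both eyes. Mirroring an OD grid through `x -> -x` yields the OS grid.
#'
#' @param pattern `"24-2"` or `"30-2"`.
#' @param eye Which eye's tested locations to return, `"OD"` (right,
#'   default) or `"OS"` (left).
#' @return A tibble of class `vf_grid` with columns `x`, `y`,
#'   `eccentricity` (Euclidean distance from fixation, degrees),
#'   `blind_od`, `blind_os` (physiologic blind-spot flags at
#'   `x = +15` / `x = -15`, `y = +-3`, where those locations exist in the
#'   grid), and attributes `pattern` and `eye`.
#' @examples
#' g <- vf_pattern("24-2")
#' nrow(g)            # 54
#' vf_pattern("30-2") # 76 locations, eye-symmetric
#' @export
vf_pattern <- function(pattern = c("24-2", "30-2"), eye = c("OD", "OS")) {
  pattern <- normalize_pattern(pattern)
  eye <- match.arg(eye)
  step <- seq(-27, 27, by = 6)
  g <- expand.grid(x = step, y = step)
  if (pattern == "30-2") {
    g <- g[abs(g$x) + abs(g$y) <= 36, , drop = FALSE]
  } else {
    core <- abs(g$x) <= 21 & abs(g$y) <= 21 & abs(g$x) + abs(g$y) <= 30
    nasal_x <- if (eye == "OD") -27 else 27
    nasal <- g$x == nasal_x & abs(g$y) == 3
    g <- g[core | nasal, , drop = FALSE]
  }
  g <- g[order(-g$y, g$x), , drop = FALSE]
  out <- tibble(
    x = as.numeric(g$x),
    y = as.numeric(g$y),
    eccentricity = sqrt(g$x^2 + g$y^2),
    blind_od = g$x == 15 & abs(g$y) == 3,
    blind_os = g$x == -15 & abs(g$y) == 3
  )
  structure(out,
    pattern = pattern, eye = eye,
    class = c("vf_grid", class(out))
  )
}

normalize_pattern <- function(pattern) {
  if (length(pattern) > 1) pattern <- pattern[[1]]
  if (!is.character(pattern) || length(pattern) != 1 || is.na(pattern)) {
    ou_stop("`pattern` must be a single string", "pattern")
  }
  p <- gsub("[ _]", "-", toupper(pattern))
  p <- sub("^P", "", p)
  if (!p %in% c("24-2", "30-2")) {
    ou_stop(sprintf("unknown test pattern '%s' (supported: 24-2, 30-2)",
                    pattern), "pattern")
  }
  p
}

#' Default eccentricity ring boundaries
#'
#' Upper eccentricity bounds (degrees) of rings 1-4; ring 5 is open-ended
#' so that 30-2 locations beyond the outermost boundary are pooled into
#' the peripheral ring. The boundaries are a convention chosen so that on
#' the 24-2 grid the four central points (eccentricity 4.24 deg) form
#' ring 1 and successive annuli fall in rings 2-5; they are a parameter
#' everywhere they are used, since the ring membership of published
#' weighting schemes is not standardized.
#' @export
vf_ring_boundaries <- function() c(5.7, 12.8, 19.0, 25.5)

#' Published five-ring VFI weights
#'
#' Per-ring weights of the eccentricity weighting used by the visual
#' field index: central/paracentral points count most (cortical
#' magnification), peripheral points least.
#' @export
vf_ring_weights <- function() c(3.29, 1.28, 0.79, 0.57, 0.45)

#' Assign eccentricity rings and VFI weights to a perimetry grid
#'
#' Partitions the grid into five concentric rings by eccentricity and
#' attaches the per-ring weight to every location. The grid's own eye's
#' physiologic blind-spot locations get weight 0: an absolute scotoma
#' present in every healthy eye carries no information about disease.
#'
#' @param grid A `vf_grid` from [vf_pattern()].
#' @param ring_boundaries Strictly increasing upper bounds (degrees) of
#'   rings 1-4; default [vf_ring_boundaries()]. Locations beyond the last
#'   boundary fall in ring 5.
#' @param ring_weights Positive, strictly decreasing 5-vector of per-ring
#'   weights; default [vf_ring_weights()].
#' @param zero_blind Zero the weight at the grid eye's blind-spot
#'   locations (default `TRUE`).
#' @return The grid tibble with added columns `ring` (1-5) and `weight`.
#' @examples
#' w <- vf_weights(vf_pattern("24-2"))
#' w$weight[w$eccentricity < 5.7]   # the central four carry 3.29
#' @export
vf_weights <- function(grid,
                       ring_boundaries = vf_ring_boundaries(),
                       ring_weights = vf_ring_weights(),
                       zero_blind = TRUE) {
  if (!inherits(grid, "vf_grid")) {
    ou_stop("`grid` must be a vf_grid (see vf_pattern())", "grid")
  }
  check_ring_config(ring_boundaries, ring_weights)
  ring <- findInterval(grid$eccentricity, ring_boundaries) + 1L
  out <- grid
  out$ring <- ring
  out$weight <- ring_weights[ring]
  if (zero_blind) {
    eye <- attr(grid, "eye")
    blind <- if (identical(eye, "OS")) out$blind_os else out$blind_od
    out$weight[blind] <- 0
  }
  out
}

check_ring_config <- function(ring_boundaries, ring_weights) {
  if (length(ring_boundaries) != 4 || any(!is.finite(ring_boundaries)) ||
      any(diff(ring_boundaries) <= 0) || ring_boundaries[1] <= 0) {
    ou_stop("`ring_boundaries` must be 4 strictly increasing positive values",
            "ring_config")
  }
  if (length(ring_weights) != 5 || any(!is.finite(ring_weights)) ||
      any(ring_weights <= 0) || any(diff(ring_weights) >= 0)) {
    ou_stop("`ring_weights` must be 5 positive strictly decreasing values",
            "ring_config")
  }
  invisible(TRUE)
}

#' Export a grid or weight matrix as CSV
#'
#' Writes columns `x_deg`, `y_deg` and, when present, `ring` and
#' `weight`, at fixed precision so reruns are byte-identical.
#'
#' @param grid A `vf_grid`, weighted or not.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vf_grid <- function(grid, path) {
  if (!inherits(grid, "vf_grid")) {
    ou_stop("`grid` must be a vf_grid", "grid")
  }
  out <- data.frame(x_deg = grid$x, y_deg = grid$y)
  if (!is.null(grid$ring)) out$ring <- grid$ring
  if (!is.null(grid$weight)) out$weight <- fmt_num(grid$weight)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed 6-significant-digit text form used by every CSV writer
fmt_num <- function(x) formatC(x, format = "g", digits = 6)
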