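#' @rdname drive_metrics
#' @format NULL
#' @export
MPS_PER_MPH <- 0.44704

#' Vehicle-control outcome measures from a telemetry trace
#'
#' Summarizes one drive's uniformly sampled vehicle state into the
#' lane-maintenance and speed-control outcomes: mean, variability
#' (sample standard deviation over the full drive) and maximum of
#' velocity; the fraction of samples strictly above each speed limit;
#' and the sample standard deviations of steering-wheel angle and of
#' lateral and longitudinal acceleration. Accelerations are carried in
#' the simulator's native units (the module is unit-agnostic).
#'
#' @param trace A `telemetry_trace` from [telemetry_trace()],
#'   [simulate_telemetry()] or [read_telemetry()].
#' @param limit_55,limit_60 Speed limits in m/s; defaults are exactly 55
#'   and 60 mph (1 mph = 0.44704 m/s).
#' @return A tibble with one row: `mean_velocity`, `velocity_sd`,
#'   `max_velocity`, `pct_over_55`, `pct_over_60` (fractions in \[0,1\]),
#'   `steering_sd`, `lat_accel_sd`, `long_accel_sd`, `n_samples`,
#'   `duration_s`.
#' @examples
#' tr <- simulate_telemetry(duration = 10, seed = 1)
#' drive_metrics(tr)
#' @export
drive_metrics <- function(trace,
                          limit_55 = 55 * MPS_PER_MPH,
                          limit_60 = 60 * MPS_PER_MPH) {
  trace <- as_telemetry_trace(trace)
  n <- nrow(trace)
  if (n == 0) ou_stop("empty telemetry trace", "telemetry")
  if (n < 2) {
    ou_stop("at least 2 samples are required for variability measures",
            "telemetry")
  }
  tibble(
    mean_velocity = mean(trace$speed),
    velocity_sd = sd(trace$speed),
    max_velocity = max(trace$speed),
    pct_over_55 = mean(trace$speed > limit_55),
    pct_over_60 = mean(trace$speed > limit_60),
    steering_sd = sd(trace$steer),
    lat_accel_sd = sd(trace$lat_acc),
    long_accel_sd = sd(trace$long_acc),
    n_samples = n,
    duration_s = trace$t[n] - trace$t[1]
  )
}

#' Construct / validate a telemetry trace
#'
#' @param t Timestamps in seconds, strictly increasing and uniform at
#'   `sample_rate` (to 1e-6 s).
#' @param speed Vehicle speed, m/s, non-negative.
#' @param steer Steering-wheel angle, degrees.
#' @param lat_acc,long_acc Lateral / longitudinal acceleration in the
#'   simulator's native units.
#' @param sample_rate Sampling rate, Hz.
#' @return A tibble of class `telemetry_trace` with attribute
#'   `sample_rate`.
#' @export
telemetry_trace <- function(t, speed, steer, lat_acc, long_acc,
                            sample_rate = 60) {
  n <- length(t)
  if (n == 0) ou_stop("empty telemetry trace", "telemetry")
  lens <- c(length(speed), length(steer), length(lat_acc), length(long_acc))
  if (any(lens != n)) {
    ou_stop("all telemetry channels must have the same length", "telemetry")
  }
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || any(abs(dt - 1 / sample_rate) > 1e-6)) {
      ou_stop(sprintf(
        "timestamps must increase uniformly at %g Hz (tolerance 1e-6 s)",
        sample_rate), "telemetry")
    }
  }
  if (any(!is.finite(speed)) || any(speed < 0)) {
    ou_stop("speed must be finite and non-negative", "telemetry")
  }
  out <- tibble(t = as.numeric(t), speed = as.numeric(speed),
                steer = as.numeric(steer), lat_acc = as.numeric(lat_acc),
                long_acc = as.numeric(long_acc))
  structure(out, sample_rate = sample_rate,
            class = c("telemetry_trace", class(out)))
}

as_telemetry_trace <- function(x) {
  if (inherits(x, "telemetry_trace")) return(x)
  if (is.data.frame(x) &&
      all(c("t", "speed", "steer", "lat_acc", "long_acc") %in% names(x))) {
    rate <- attr(x, "sample_rate")
    if (is.null(rate)) {
      rate <- if (nrow(x) > 1) 1 / median(diff(x$t)) else 60
    }
    return(telemetry_trace(x$t, x$speed, x$steer, x$lat_acc, x$long_acc,
                           sample_rate = rate))
  }
  ou_stop("not a telemetry trace (need columns t, speed, steer, lat_acc, long_acc)",
          "telemetry")
}

#' Simulate driving-simulator telemetry
#'
#' Generates a stationary drive on a straight road: each channel is an
#' AR(1) perturbation around its target with the requested *marginal*
#' standard deviation (innovation variance scaled by `1 - ar_coef^2`),
#' emulating the smooth, autocorrelated corrections of real
#' lane-keeping. Speed is floored at 0.
#'
#' @param duration Drive length, seconds.
#' @param sample_rate Sampling rate, Hz (default 60).
#' @param target_speed Mean speed, m/s (default 24.6, just under a 88.5
#'   km/h limit).
#' @param speed_sd,steering_sd,lat_accel_sd,long_accel_sd Marginal SDs of
#'   the four channels (m/s, degrees, simulator units, simulator units).
#' @param ar_coef AR(1) coefficient per sample (default 0.98 at 60 Hz, a
#'   correlation half-life of about 0.6 s).
#' @param seed Optional integer; same seed gives an identical trace.
#' @return A `telemetry_trace`.
#' @export
simulate_telemetry <- function(duration = 300, sample_rate = 60,
                               target_speed = 24.6,
                               speed_sd = 1.5, steering_sd = 0.75,
                               lat_accel_sd = 0.003, long_accel_sd = 0.02,
                               ar_coef = 0.98, seed = NULL) {
  if (duration <= 0 || sample_rate <= 0) {
    ou_stop("duration and sample_rate must be positive", "telemetry")
  }
  sds <- c(speed_sd, steering_sd, lat_accel_sd, long_accel_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    ou_stop("channel SDs must be non-negative", "telemetry")
  }
  if (abs(ar_coef) >= 1) {
    ou_stop("ar_coef must lie in (-1, 1) for a stationary trace",
            "telemetry")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, as.integer(round(duration * sample_rate)))
  ar1 <- function(marginal_sd) {
    if (marginal_sd == 0) return(numeric(n))
    e <- rnorm(n, sd = marginal_sd * sqrt(1 - ar_coef^2))
    e[1] <- rnorm(1, sd = marginal_sd)   # stationary start
    as.numeric(stats::filter(e, ar_coef, method = "recursive"))
  }
  telemetry_trace(
    t = (seq_len(n) - 1) / sample_rate,
    speed = pmax(0, target_speed + ar1(speed_sd)),
    steer = ar1(steering_sd),
    lat_acc = ar1(lat_accel_sd),
    long_acc = ar1(long_accel_sd),
    sample_rate = sample_rate
  )
}

#' Default in-cab detection-task grid
#'
#' Test locations of the driving-simulator visual field (DSVF) task:
#' a 60 x 20 degree field (horizontal x vertical total visual angle)
#' sampled on the 6-degree offset lattice, `x` at +-3..27 and `y` at
#' +-3, +-9 (40 locations).
#'
#' @return Tibble with columns `x`, `y`.
#' @export
dsvf_grid <- function() {
  g <- expand.grid(x = seq(-27, 27, 6), y = c(-9, -3, 3, 9))
  g <- g[order(-g$y, g$x), ]
  tibble(x = as.numeric(g$x), y = as.numeric(g$y))
}

#' Score the driving-simulator visual field detection task
#'
#' Each grid location is presented several times (four in the standard
#' protocol); a location passes when its detection rate is *strictly*
#' greater than 50%. A field-level index (DS-VFI) is computed from the
#' binary pass map with the standard eccentricity-ring weighting (pass
#' scores 100, fail 0). Locations are binned into rings by their true
#' visual-field eccentricity: cortical magnification, which the weights
#' encode, is a function of absolute eccentricity, not of position
#' relative to the task's 60 x 20 degree extent, so the perimetric ring
#' boundaries apply to the task grid unchanged.
#'
#' @param responses Data frame with columns `x`, `y` (degrees,
#'   visual-field frame), `presentations`, `hits` (one row per location;
#'   `0 <= hits <= presentations`, `presentations >= 1`).
#' @param ring_boundaries,ring_weights Ring configuration (defaults as in
#'   [vf_weights()]).
#' @return A list of class `dsvf_result`: `data` (per-location tibble
#'   with `detection_rate`, `passed`, `ring`, `weight`), `ds_vfi`
#'   (percent), `n_pass`, `n_locations`.
#' @examples
#' resp <- dsvf_grid()
#' resp$presentations <- 4
#' resp$hits <- 4
#' score_dsvf(resp)$ds_vfi  # 100
#' @export
score_dsvf <- function(responses,
                       ring_boundaries = vf_ring_boundaries(),
                       ring_weights = vf_ring_weights()) {
  need <- c("x", "y", "presentations", "hits")
  miss <- setdiff(need, names(responses))
  if (length(miss)) {
    ou_stop(paste("responses is missing column(s):",
                  paste(miss, collapse = ", ")), "dsvf")
  }
  p <- responses$presentations
  h <- responses$hits
  if (any(p < 1) || any(p != round(p))) {
    ou_stop("presentations must be whole numbers >= 1", "dsvf")
  }
  if (any(h < 0) || any(h > p)) {
    ou_stop("hits must lie between 0 and presentations", "dsvf")
  }
  check_ring_config(ring_boundaries, ring_weights)
  rate <- h / p
  passed <- rate > 0.5
  ecc <- sqrt(responses$x^2 + responses$y^2)
  ring <- findInterval(ecc, ring_boundaries) + 1L
  w <- ring_weights[ring]
  data <- tibble(
    x = responses$x, y = responses$y,
    presentations = as.integer(p), hits = as.integer(h),
    detection_rate = rate, passed = passed, ring = ring, weight = w
  )
  structure(
    list(data = data,
         ds_vfi = weighted_vfi(ifelse(passed, 100, 0), w),
         n_pass = sum(passed), n_locations = nrow(data)),
    class = "dsvf_result"
  )
}

#' @exportS3Method base::print
print.dsvf_result <- function(x, ...) {
  cat(sprintf("<dsvf_result> %d/%d locations passed, DS-VFI %.1f%%\n",
              x$n_pass, x$n_locations, x$ds_vfi))
  invisible(x)
}
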