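#' Finely sampled blood activity curve
#'
#' A `blood_curve` is a tibble of (time, activity) samples for arterial (or
#' simulated ground-truth) blood, at arbitrary, strictly increasing sample
#' times. Activity is a concentration (Bq/mL) unless the curve represents raw
#' monitor counts.
#'
#' @param time_s Sample times in seconds, strictly increasing, length >= 2.
#' @param activity Activity at each sample; finite.
#' @param tracer Optional [tracer_constants()] attached as metadata.
#' @param calibrated Logical; `TRUE` once sensitivity/decay corrections have
#'   been applied.
#' @param units Units label, default `"Bq/mL"`.
#' @return A tibble of class `blood_curve` with columns `time_s`, `activity`.
#' @export
blood_curve <- function(time_s, activity, tracer = NULL, calibrated = FALSE,
                        units = "Bq/mL") {
  time_s <- as.double(time_s)
  activity <- as.double(activity)
  if (length(time_s) < 2L) stop("a blood_curve needs at least 2 samples")
  if (length(time_s) != length(activity)) stop("time_s and activity lengths differ")
  if (anyNA(time_s) || !all(is.finite(time_s))) stop("time_s must be finite")
  if (is.unsorted(time_s, strictly = TRUE)) stop("time_s must be strictly increasing")
  if (anyNA(activity) || !all(is.finite(activity))) stop("activity must be finite")
  if (!is.null(tracer) && !is_tracer(tracer)) stop("tracer must be tracer_constants()")
  out <- tibble::new_tibble(
    tibble::tibble(time_s = time_s, activity = activity),
    class = "blood_curve"
  )
  attr(out, "tracer") <- tracer
  attr(out, "calibrated") <- isTRUE(calibrated)
  attr(out, "units") <- units
  out
}

is_blood_curve <- function(x) inherits(x, "blood_curve")

curve_meta <- function(curve) {
  list(
    tracer = attr(curve, "tracer"),
    calibrated = attr(curve, "calibrated"),
    units = attr(curve, "units")
  )
}

with_curve_meta <- function(curve, template, ...) {
  dots <- list(...)
  meta <- curve_meta(template)
  meta[names(dots)] <- dots
  blood_curve(curve$time_s, curve$activity,
    tracer = meta$tracer, calibrated = meta$calibrated, units = meta$units
  )
}

#' Frame-resolution time activity curve (TAC)
#'
#' A `tac` holds one activity value per frame of a schedule, for a VOI or a
#' voxel. The schedule columns are carried alongside the values so a TAC is
#' self-describing.
#'
#' @param schedule A [frame_schedule()].
#' @param value Numeric vector, one finite value per frame.
#' @param units Units label: `"Bq/mL"` or `"Bq/g"`.
#' @return A tibble of class `tac` with the schedule columns plus `value`.
#' @export
tac <- function(schedule, value, units = "Bq/mL") {
  assert_schedule(schedule)
  value <- as.double(value)
  if (length(value) != nrow(schedule)) {
    stop("need exactly one value per frame (", nrow(schedule), " frames, got ",
      length(value), " values)")
  }
  if (anyNA(value) || !all(is.finite(value))) stop("TAC values must be finite")
  out <- tibble::new_tibble(
    tibble::tibble(
      frame = schedule$frame, start_s = schedule$start_s, end_s = schedule$end_s,
      duration_s = schedule$duration_s, mid_s = schedule$mid_s, value = value
    ),
    class = "tac"
  )
  attr(out, "units") <- units
  out
}

is_tac <- function(x) inherits(x, "tac")

tac_schedule <- function(x) frame_schedule(x$start_s, x$end_s)

tac_units <- function(x) attr(x, "units")

assert_same_schedule <- function(a, b, tol = 1e-6) {
  if (nrow(a) != nrow(b) ||
    max(abs(a$start_s - b$start_s)) > tol ||
    max(abs(a$end_s - b$end_s)) > tol) {
    stop("frame schedules do not match")
  }
  invisible(TRUE)
}

# Exact running integral of the piecewise-linear interpolant of (time, act),
# evaluated at arbitrary points, with constant extrapolation: 0 before the
# first sample, the last sample value after the last. Pre-arrival activity is
# physically zero; holding the last value past the end minimizes
# tail-truncation bias. Trapezoid cumulation is exact for piecewise-linear
# integrands; vectorized over evaluation points.
cum_integral_at <- function(time_s, activity, pts) {
  n <- length(time_s)
  Q <- c(0, cumsum((activity[-1L] + activity[-n]) / 2 * diff(time_s)))
  t0 <- time_s[1L]
  tn <- time_s[n]
  yn <- activity[n]
  out <- numeric(length(pts))
  after <- pts >= tn
  out[after] <- Q[n] + yn * (pts[after] - tn)
  inside <- pts > t0 & !after
  if (any(inside)) {
    p <- pts[inside]
    k <- findInterval(p, time_s)
    frac <- (p - time_s[k]) / (time_s[k + 1L] - time_s[k])
    vp <- activity[k] + (activity[k + 1L] - activity[k]) * frac
    out[inside] <- Q[k] + (activity[k] + vp) / 2 * (p - time_s[k])
  }
  out
}

#' Average a blood curve over the frames of a schedule
#'
#' Resamples a finely sampled curve to frame resolution by averaging the
#' piecewise-linear interpolant of the curve over each frame interval
#' `[start_s, end_s)`. The curve is extrapolated as 0 before its first sample
#' and as its last value after its last sample.
#'
#' @param curve A [blood_curve()].
#' @param schedule A [frame_schedule()].
#' @return A [tac()] on `schedule`, in the curve's units.
#' @examples
#' sched <- default_frame_schedule()
#' cv <- blood_curve(seq(0, 240, 0.5), rep(7, 481))
#' all(frame_average(cv, sched)$value == 7)
#' @export
frame_average <- function(curve, schedule) {
  if (!is_blood_curve(curve)) stop("expected a blood_curve")
  assert_schedule(schedule)
  if (curve$time_s[1L] >= max(schedule$end_s)) {
    stop("curve lies entirely after the schedule")
  }
  iv <- cum_integral_at(curve$time_s, curve$activity, schedule$end_s) -
    cum_integral_at(curve$time_s, curve$activity, schedule$start_s)
  vals <- iv / schedule$duration_s
  tac(schedule, vals, units = attr(curve, "units") %||% "Bq/mL")
}

#' Convert a TAC between per-mL and per-g units
#'
#' Measured concentrations in Bq/mL are converted to Bq/g with an assumed
#' myocardial tissue density of 1.05 g/mL (and back).
#'
#' @param x A [tac()].
#' @param direction `"to_per_g"` (divide by density) or `"to_per_ml"`
#'   (multiply by density).
#' @param density_g_ml Tissue density, g/mL.
#' @return A [tac()] with converted values and updated units tag.
#' @export
density_convert <- function(x, direction = c("to_per_g", "to_per_ml"),
                            density_g_ml = 1.05) {
  if (!is_tac(x)) stop("expected a tac")
  direction <- match.arg(direction)
  u <- tac_units(x)
  if (direction == "to_per_g") {
    if (!identical(u, "Bq/mL")) stop("expected units Bq/mL, got ", u)
    tac(tac_schedule(x), x$value / density_g_ml, units = "Bq/g")
  } else {
    if (!identical(u, "Bq/g")) stop("expected units Bq/g, got ", u)
    tac(tac_schedule(x), x$value * density_g_ml, units = "Bq/mL")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
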