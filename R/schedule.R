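#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds the start and end time of every reconstructed frame,
#' in seconds from injection start. Frames are half-open intervals
#' `[start_s, end_s)`; they may be contiguous or gapped but never overlap.
#' Derived columns `duration_s` and `mid_s` are always present.
#'
#' @param start_s Numeric vector of frame start times (s), strictly increasing.
#' @param end_s Numeric vector of frame end times (s), elementwise `> start_s`.
#'
#' @return A tibble of class `frame_schedule` with columns `frame`, `start_s`,
#'   `end_s`, `duration_s`, `mid_s`.
#' @examples
#' sched <- default_frame_schedule()
#' nrow(sched)          # 32 frames
#' sum(sched$duration_s) # 240 s acquisition
#' @export
frame_schedule <- function(start_s, end_s) {
  start_s <- as.double(start_s)
  end_s <- as.double(end_s)
  if (length(start_s) != length(end_s) || length(start_s) < 1L) {
    stop("start_s and end_s must be non-empty vectors of equal length")
  }
  if (anyNA(start_s) || anyNA(end_s) || !all(is.finite(c(start_s, end_s)))) {
    stop("frame times must be finite")
  }
  if (is.unsorted(start_s, strictly = TRUE)) {
    stop("start_s must be strictly increasing")
  }
  if (!all(end_s > start_s)) {
    stop("end_s must exceed start_s for every frame")
  }
  if (length(start_s) > 1L && any(start_s[-1L] < end_s[-length(end_s)] - 1e-9)) {
    stop("frames must not overlap")
  }
  tibble::new_tibble(
    tibble::tibble(
      frame = seq_along(start_s),
      start_s = start_s,
      end_s = end_s,
      duration_s = end_s - start_s,
      mid_s = (start_s + end_s) / 2
    ),
    class = "frame_schedule"
  )
}

#' @rdname frame_schedule
#' @details `default_frame_schedule()` returns the 32-frame, 4-minute dynamic
#'   cardiac schedule 20 x 3 s, 6 x 10 s, 6 x 20 s used throughout the package
#'   as the default acquisition.
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(3, 20), rep(10, 6), rep(20, 6))
  end <- cumsum(dur)
  frame_schedule(start_s = end - dur, end_s = end)
}

is_frame_schedule <- function(x) inherits(x, "frame_schedule")

assert_schedule <- function(x) {
  if (!is_frame_schedule(x)) stop("expected a frame_schedule")
  invisible(x)
}

#' Read or write a frame schedule as JSON
#'
#' Schedules are serialized as a JSON list of `[start_s, end_s]` pairs.
#'
#' @param path Path to a JSON file.
#' @param schedule A [frame_schedule()].
#' @return `read_frame_schedule()` returns a [frame_schedule()];
#'   `write_frame_schedule()` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  m <- jsonlite::fromJSON(path)
  if (is.list(m)) m <- do.call(rbind, m)
  if (!is.matrix(m) || ncol(m) != 2L) {
    stop("schedule JSON must be a list of [start_s, end_s] pairs")
  }
  frame_schedule(start_s = m[, 1L], end_s = m[, 2L])
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  assert_schedule(schedule)
  jsonlite::write_json(
    Map(c, schedule$start_s, schedule$end_s),
    path,
    digits = NA
  )
  invisible(path)
}

#' Physical constants for a PET tracer
#'
#' @param name Tracer name, one of `"rb82"` (rubidium-82) or `"o15_water"`
#'   (oxygen-15 water).
#' @return A list with elements `name`, `half_life_s`, `lambda_s` (decay
#'   constant, 1/s), and `positron_range` (a qualitative class: rubidium-82
#'   emits much more energetic positrons than oxygen-15, hence poorer
#'   intrinsic resolution).
#' @examples
#' tracer_constants("rb82")$lambda_s # log(2) / 76.38
#' @export
tracer_constants <- function(name = c("rb82", "o15_water")) {
  name <- match.arg(name)
  half_life <- switch(name, rb82 = 76.38, o15_water = 122.24)
  structure(
    list(
      name = name,
      half_life_s = half_life,
      lambda_s = log(2) / half_life,
      positron_range = switch(name, rb82 = "long", o15_water = "medium")
    ),
    class = "tracer_constants"
  )
}

is_tracer <- function(x) inherits(x, "tracer_constants")
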