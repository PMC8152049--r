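#' Frame schedules for dynamic PET acquisitions
#'
#' A frame schedule is a tibble with columns `frame_start_s` and
#' `frame_duration_s` (both in seconds) describing a contiguous sequence of
#' acquisition frames starting at injection (t = 0). All time-activity curves
#' in the package live on such a grid.
#'
#' `frame_schedule()` builds a schedule from frame durations;
#' `schedule_from_blocks()` builds one from (count, duration) blocks as used in
#' protocol descriptions and YAML configs; `default_frame_schedule()` returns
#' the 50-frame, 60-minute dynamic liver protocol (6 x 5 s, 3 x 10 s, 6 x 20 s,
#' 14 x 30 s, 10 x 60 s, 5 x 120 s, 6 x 300 s).
#'
#' @param durations_s Numeric vector of strictly positive frame durations in
#'   seconds; frames are laid out contiguously from t = 0.
#' @return A tibble with columns `frame_start_s`, `frame_duration_s`.
#' @examples
#' sched <- default_frame_schedule()
#' nrow(sched)                      # 50 frames
#' sum(sched$frame_duration_s)      # 3600 s = 60 min
#' @export
frame_schedule <- function(durations_s) {
  if (length(durations_s) == 0) {
    abort("a frame schedule needs at least one frame")
  }
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    abort("frame durations must be finite and strictly positive")
  }
  tibble::tibble(
    frame_start_s = cumsum(c(0, durations_s[-length(durations_s)])),
    frame_duration_s = as.numeric(durations_s)
  )
}

#' @rdname frame_schedule
#' @param blocks A data frame with columns `count` and `duration_s`: each row
#'   contributes `count` consecutive frames of `duration_s` seconds.
#' @export
schedule_from_blocks <- function(blocks) {
  stopifnot(is.data.frame(blocks), all(c("count", "duration_s") %in% names(blocks)))
  frame_schedule(rep(blocks$duration_s, times = blocks$count))
}

#' @rdname frame_schedule
#' @export
default_frame_schedule <- function() {
  schedule_from_blocks(tibble::tibble(
    count      = c(6, 3, 6, 14, 10, 5, 6),
    duration_s = c(5, 10, 20, 30, 60, 120, 300)
  ))
}

#' Validate a frame schedule
#'
#' Checks the schedule invariants: columns present, strictly positive
#' durations, first frame starting at 0, and contiguity
#' (`start[i+1] == start[i] + duration[i]`). Errors name the first offending
#' row.
#'
#' @param schedule A frame-schedule tibble.
#' @return The schedule, invisibly, if valid.
#' @export
validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("frame_start_s", "frame_duration_s") %in% names(schedule))) {
    abort("schedule must have columns frame_start_s and frame_duration_s")
  }
  if (nrow(schedule) == 0) abort("schedule has no frames")
  st <- schedule$frame_start_s
  du <- schedule$frame_duration_s
  if (any(!is.finite(st)) || any(!is.finite(du))) {
    bad <- which(!is.finite(st) | !is.finite(du))[1]
    abort(sprintf("non-finite schedule entry at row %d", bad))
  }
  if (any(du <= 0)) {
    abort(sprintf("non-positive frame duration at row %d", which(du <= 0)[1]))
  }
  if (st[1] != 0) abort("first frame must start at t = 0")
  if (nrow(schedule) > 1) {
    gap <- which(abs(st[-1] - (st + du)[-nrow(schedule)]) > 1e-9)
    if (length(gap) > 0) {
      abort(sprintf("frames not contiguous at row %d", gap[1] + 1))
    }
  }
  invisible(schedule)
}

#' Frame midpoint times
#'
#' @param schedule A frame-schedule tibble (seconds).
#' @return Numeric vector of frame midpoints in minutes, strictly increasing.
#' @examples
#' frame_midpoints(default_frame_schedule())[1]   # 2.5 s = 0.0417 min
#' @export
frame_midpoints <- function(schedule) {
  validate_schedule(schedule)
  (schedule$frame_start_s + schedule$frame_duration_s / 2) / 60
}

#' Frame end times in seconds
#' @noRd
frame_ends_s <- function(schedule) {
  schedule$frame_start_s + schedule$frame_duration_s
}
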