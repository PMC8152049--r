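#' Build a tidy time-activity curve
#'
#' TACs are stored in long ("tidy") form: one row per frame per VOI curve,
#' with columns `frame_start_s`, `frame_duration_s`, `voi_label`, `measure`
#' (`"mean"` or `"max"`, i.e. SUVmean- or SUVmax-derived) and `value` (SUV).
#' Negative values are tolerated only for measured/noisy curves (noise can
#' undershoot); model predictions are never negative.
#'
#' @param schedule A frame-schedule tibble.
#' @param values Numeric vector of per-frame SUV values, one per frame.
#' @param voi_label Label of the volume of interest (e.g. "aorta",
#'   "portal_vein", "reference", "lesion01").
#' @param measure `"mean"` or `"max"`.
#' @return A tidy TAC tibble.
#' @export
tac_tibble <- function(schedule, values, voi_label, measure = "mean") {
  validate_schedule(schedule)
  measure <- match.arg(measure, c("mean", "max"))
  if (length(values) != nrow(schedule)) {
    abort(sprintf("got %d values for %d frames", length(values), nrow(schedule)))
  }
  if (any(!is.finite(values))) abort("TAC values must be finite")
  tibble::tibble(
    frame_start_s = schedule$frame_start_s,
    frame_duration_s = schedule$frame_duration_s,
    voi_label = voi_label,
    measure = measure,
    value = as.numeric(values)
  )
}

#' Extract the schedule of a tidy TAC table
#'
#' @param tacs A tidy TAC tibble (possibly holding several curves on the same
#'   schedule).
#' @return A frame-schedule tibble.
#' @export
tac_schedule <- function(tacs) {
  sched <- dplyr::distinct(tacs, .data$frame_start_s, .data$frame_duration_s)
  sched <- dplyr::arrange(sched, .data$frame_start_s)
  validate_schedule(sched)
  sched
}

#' Read and write TAC CSV files
#'
#' The on-disk format is wide: columns `frame_start_s` and `frame_duration_s`
#' (the shared schedule), then one column per curve named
#' `"<voi_label>__<measure>"`. `read_tacs()` validates the schedule on read and
#' reports the offending row of any contiguity violation; `write_tacs()`
#' writes values at full round-trip precision so write-then-read is an
#' identity.
#'
#' @param path Path to a CSV file.
#' @return `read_tacs()` returns a tidy TAC tibble (see [tac_tibble()]).
#' @export
read_tacs <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("frame_start_s", "frame_duration_s") %in% names(wide))) {
    abort("TAC CSV must have frame_start_s and frame_duration_s columns")
  }
  validate_schedule(wide[c("frame_start_s", "frame_duration_s")])
  curve_cols <- setdiff(names(wide), c("frame_start_s", "frame_duration_s"))
  if (length(curve_cols) == 0) abort("TAC CSV contains no curve columns")
  bad <- curve_cols[!grepl("^.+__(mean|max)$", curve_cols)]
  if (length(bad) > 0) {
    abort(sprintf("curve column '%s' is not named <voi_label>__<measure>", bad[1]))
  }
  long <- tidyr::pivot_longer(wide, dplyr::all_of(curve_cols),
                              names_to = c("voi_label", "measure"),
                              names_pattern = "^(.*)__(mean|max)$",
                              values_to = "value")
  dplyr::arrange(long, .data$voi_label, .data$measure, .data$frame_start_s)
}

#' @rdname read_tacs
#' @param tacs A tidy TAC tibble; every curve must share one schedule.
#' @export
write_tacs <- function(tacs, path) {
  validate_schedule(tac_schedule(tacs))
  wide <- tidyr::pivot_wider(tacs,
                             id_cols = c("frame_start_s", "frame_duration_s"),
                             names_from = c("voi_label", "measure"),
                             names_sep = "__",
                             values_from = "value")
  wide <- dplyr::arrange(wide, .data$frame_start_s)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Pull one curve's values out of a tidy TAC table
#'
#' @inheritParams tac_schedule
#' @param voi_label,measure Which curve to extract.
#' @return Numeric vector of per-frame values in frame order.
#' @export
tac_values <- function(tacs, voi_label, measure = "mean") {
  cur <- dplyr::filter(tacs, .data$voi_label == .env$voi_label,
                       .data$measure == .env$measure)
  if (nrow(cur) == 0) {
    abort(sprintf("no curve '%s' with measure '%s'", voi_label, measure))
  }
  dplyr::arrange(cur, .data$frame_start_s)$value
}
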