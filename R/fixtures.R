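#' Packaged deployment-summary fixtures
#'
#' Small plain-text tables shipped with the package for tests, examples and
#' desk-scale reproduction of the published study's summary arithmetic.
#'
#' `fixture_table1()` returns the per-deployment video/nursing budget: tag-on
#' time, hours of video, hours of good-quality video, number of successful
#' nursing events, mean and total nursing duration, and percent of good
#' video spent nursing, for the four calf deployments.
#'
#' `fixture_table2()` returns the per-event comparison: one row per nursing
#' event (11 calf, 3 mother) with its duration, dive phase, and nursing vs
#' phase-matched non-nursing mean speed, ODBA and fluke-stroke rate.
#'
#' `fixture_event_log()` returns an [event_log()] whose nursing event
#' durations and dive phases match `fixture_table2()` row-for-row, with
#' proximity, foraging and poor-video intervals consistent with the
#' published budgets. Absolute start times are synthetic (the raw tag
#' records are not deposited), so only durations, counts and interval
#' arithmetic on this log are meaningful — not absolute timing.
#'
#' @return A `data.frame` (or [event_log()] for `fixture_event_log()`).
#' @name fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nursekin")
  if (!nzchar(p)) stop(sprintf("fixture '%s' not found", file), call. = FALSE)
  p
}

#' @rdname fixtures
#' @export
fixture_table1 <- function() {
  data.table::fread(fixture_path("table1_deployments.tsv"), sep = "\t",
                    data.table = FALSE)
}

#' @rdname fixtures
#' @export
fixture_table2 <- function() {
  df <- data.table::fread(fixture_path("table2_events.tsv"), sep = "\t",
                          data.table = FALSE)
  stopifnot(sum(df$role == "calf") == 11L, sum(df$role == "mother") == 3L)
  df
}

#' @rdname fixtures
#' @export
fixture_event_log <- function() {
  read_event_log(fixture_path("event_log_synthetic_times.tsv"))
}
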