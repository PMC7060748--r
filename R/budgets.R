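#' Per-deployment nursing time budget
#'
#' Counts successful nursing events per deployment and expresses their
#' total duration as a percentage of the good-quality video time (the
#' analyzable denominator). Durations are exact interval arithmetic;
#' report rounding (whole seconds, two-decimal percentages) is applied
#' only by [report_tables()].
#'
#' @param events An [event_log()].
#' @param good_video_s Named numeric vector of good-quality video seconds
#'   per deployment (names = deployment ids). Must be positive.
#' @return A data.frame: `deployment_id`, `n_events`, `mean_duration_s`,
#'   `total_nursing_s`, `percent_of_good_video`.
#' @export
nursing_budget <- function(events, good_video_s) {
  if (any(good_video_s <= 0)) stop("good_video_s must be positive", call. = FALSE)
  deps <- names(good_video_s)
  if (is.null(deps)) stop("good_video_s must be named by deployment", call. = FALSE)
  rows <- lapply(deps, function(dep) {
    nur <- events[events$event_type == "nursing" &
                    events$deployment_id == dep, , drop = FALSE]
    dur <- nur$end_s - nur$start_s
    tot <- sum(dur)
    data.frame(deployment_id = dep,
               n_events = nrow(nur),
               mean_duration_s = if (nrow(nur)) mean(dur) else 0,
               total_nursing_s = tot,
               percent_of_good_video = 100 * tot / good_video_s[[dep]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mother-calf proximity budget
#'
#' Time the calf spent in close proximity to its mother's ventral side
#' without nursing: the exact interval difference
#' `proximity \ nursing`, expressed in seconds and as a percentage of
#' good-quality video.
#'
#' @param events An [event_log()] containing `proximity` and `nursing`
#'   intervals for one deployment (filter first if the log holds several).
#' @param good_video_s Good-quality video seconds (scalar).
#' @return A one-row data.frame: `proximity_s`, `nursing_in_proximity_s`,
#'   `proximity_nonnursing_s`, `percent_nonnursing_proximity`,
#'   `percent_proximity`.
#' @export
proximity_budget <- function(events, good_video_s) {
  prox <- events_iv(events, types = "proximity")
  nur <- events_iv(events, types = "nursing")
  prox_s <- iv_length(iv_union(prox))
  overlap_s <- iv_length(iv_intersect(prox, nur))
  nonnur <- iv_length(iv_diff(prox, nur))
  data.frame(proximity_s = prox_s,
             nursing_in_proximity_s = overlap_s,
             proximity_nonnursing_s = nonnur,
             percent_nonnursing_proximity = 100 * nonnur / good_video_s,
             percent_proximity = 100 * prox_s / good_video_s)
}

#' Shortest nursing-to-foraging gaps
#'
#' For every nursing event, the shortest time between it and any foraging
#' event (lunge, dragging or bottom feeding) in the same deployment's
#' log, treating intervals as closed (overlap gives a gap of 0). Nursing
#' events in deployments whose log records no foraging are flagged
#' undetermined (`NA`).
#'
#' @param events An [event_log()].
#' @return A data.frame with one row per nursing event: `deployment_id`,
#'   `start_s`, `end_s`, `gap_s` (NA if undetermined), `nearest_type`.
#' @export
nursing_foraging_gaps <- function(events) {
  nur <- events[events$event_type == "nursing", , drop = FALSE]
  if (nrow(nur) == 0L)
    stop("event log contains no nursing events", call. = FALSE)
  fora <- events[events$event_type %in% foraging_types(), , drop = FALSE]
  gap_one <- function(dep, s, e) {
    f <- fora[fora$deployment_id == dep, , drop = FALSE]
    if (nrow(f) == 0L) return(list(gap = NA_real_, type = NA_character_))
    gaps <- pmax(0, pmax(f$start_s - e, s - f$end_s))
    k <- which.min(gaps)
    list(gap = gaps[k], type = f$event_type[k])
  }
  res <- Map(gap_one, nur$deployment_id, nur$start_s, nur$end_s)
  data.frame(deployment_id = nur$deployment_id,
             start_s = nur$start_s, end_s = nur$end_s,
             gap_s = vapply(res, `[[`, numeric(1L), "gap"),
             nearest_type = vapply(res, `[[`, character(1L), "type"),
             stringsAsFactors = FALSE, row.names = NULL)
}
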