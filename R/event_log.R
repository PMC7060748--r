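#' Behavioral event logs
#'
#' An event log is a table of typed, labeled time intervals scored from the
#' tag video: nursing (calf rostrum on the mammary gland with milk seen at
#' release), probable nursing (contact without milk confirmation), close
#' mother-calf proximity, foraging behaviors (lunge, dragging,
#' bottom_feeding), and poor-quality video to exclude from analysis.
#' Intervals are closed-open `[start_s, end_s)` on the sensor time base.
#'
#' @param deployment_id,event_type,start_s,end_s,note Vectors of equal
#'   length (note defaults to "").
#' @return A `data.frame` of class `event_log`.
#' @export
event_log <- function(deployment_id = character(), event_type = character(),
                      start_s = numeric(), end_s = numeric(), note = "") {
  df <- data.frame(deployment_id = as.character(deployment_id),
                   event_type = as.character(event_type),
                   start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   note = if (length(deployment_id)) as.character(note) else character(),
                   stringsAsFactors = FALSE)
  validate_event_log(df)
}

event_types <- function() c("nursing", "probable_nursing", "proximity",
                            "lunge", "dragging", "bottom_feeding",
                            "poor_video")

foraging_types <- function() c("lunge", "dragging", "bottom_feeding")

validate_event_log <- function(df) {
  bad <- setdiff(unique(df$event_type), event_types())
  if (length(bad))
    stop(sprintf("unknown event_type: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (any(df$end_s <= df$start_s))
    stop("event end_s must exceed start_s", call. = FALSE)
  # same-type intervals may not overlap within a deployment
  if (nrow(df) > 1L) {
    sp <- split(df, list(df$deployment_id, df$event_type), drop = TRUE)
    for (g in sp) {
      if (nrow(g) < 2L) next
      g <- g[order(g$start_s), ]
      if (any(g$start_s[-1L] < g$end_s[-nrow(g)]))
        stop(sprintf("overlapping %s intervals in deployment %s",
                     g$event_type[1L], g$deployment_id[1L]), call. = FALSE)
    }
  }
  class(df) <- c("event_log", "data.frame")
  df
}

#' Read an event log from delimited text
#'
#' Expects columns `deployment_id,event_type,start_s,end_s,note` (tab- or
#' comma-separated). Rows are validated: known event types, positive
#' durations, no same-type overlap within a deployment.
#'
#' @param path File path.
#' @return An [event_log()].
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = "deployment_id"))
  if (nrow(df) == 0L) return(event_log())
  need <- c("deployment_id", "event_type", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop(sprintf("event log missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  if (is.null(df$note)) df$note <- ""
  df$note[is.na(df$note)] <- ""
  event_log(df$deployment_id, df$event_type, df$start_s, df$end_s, df$note)
}

#' Write an event log to delimited text
#' @param events An [event_log()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_event_log <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  data.table::fwrite(as.data.frame(events), path, sep = "\t")
  invisible(path)
}

# Intervals (matrix) of given types for one deployment; types NULL = all.
events_iv <- function(events, deployment_id = NULL, types = NULL) {
  df <- events
  if (!is.null(deployment_id)) df <- df[df$deployment_id %in% deployment_id, , drop = FALSE]
  if (!is.null(types)) df <- df[df$event_type %in% types, , drop = FALSE]
  if (nrow(df) == 0L) return(iv_empty())
  iv(df$start_s, df$end_s)
}

# Check nursing events sit inside the record's time span.
check_events_in_record <- function(events, record) {
  nur <- events[events$event_type == "nursing" &
                  events$deployment_id == record$deployment_id, , drop = FALSE]
  span_end <- record$t[length(record$t)] + 1 / record$fs
  if (nrow(nur) && (any(nur$start_s < record$t[1L]) || any(nur$end_s > span_end)))
    stop("nursing intervals must lie inside the record's time span", call. = FALSE)
  invisible(TRUE)
}
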