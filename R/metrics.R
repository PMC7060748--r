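#' Circular mean of angles
#'
#' Mean direction via the resultant vector, `atan2(mean(sin), mean(cos))`,
#' as required for angular quantities such as pitch, roll or heading.
#'
#' @param angles Numeric vector of angles in radians (non-empty).
#' @return Mean angle in `(-pi, pi]`.
#' @export
circular_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("circular mean of an empty set", call. = FALSE)
  s <- mean(sin(angles)); c_ <- mean(cos(angles))
  if (sqrt(s^2 + c_^2) < 1e-12)
    stop("circular mean undefined: resultant length ~ 0", call. = FALSE)
  out <- atan2(s, c_)
  if (out <= -pi) out <- out + 2 * pi
  out
}

#' Kinematic summary of one analysis segment
#'
#' Computes, over the samples in `[start_s, end_s)`: minimum, maximum and
#' mean depth; mean speed (if the channel is present); mean ODBA;
#' fluke-stroke rate (strokes whose detected time falls inside the
#' segment, divided by segment duration); and circular means of pitch and
#' roll.
#'
#' @param segment One-row segment (list or data.frame row) with `start_s`,
#'   `end_s` and identity fields.
#' @param processed A `processed_record` from [process_record()].
#' @return A one-row data.frame of class `segment_metrics`.
#' @export
segment_metrics <- function(segment, processed) {
  stopifnot(inherits(processed, "processed_record"))
  s <- segment$start_s; e <- segment$end_s
  sel <- processed$t >= s & processed$t < e
  if (sum(sel) < 2L)
    stop("segment spans fewer than 2 samples", call. = FALSE)
  strokes <- sum(processed$stroke_times >= s & processed$stroke_times < e)
  data.frame(
    deployment_id = segment$deployment_id %||% processed$deployment_id,
    role = segment$role %||% processed$role,
    start_s = s, end_s = e,
    phase = segment$phase %||% NA_character_,
    is_nursing = segment$is_nursing %||% NA,
    source = segment$source %||% NA_character_,
    min_depth = min(processed$depth[sel]),
    max_depth = max(processed$depth[sel]),
    mean_depth = mean(processed$depth[sel]),
    mean_speed = if (is.null(processed$speed)) NA_real_ else mean(processed$speed[sel]),
    mean_odba = mean(processed$odba[sel]),
    fsr = strokes / (e - s),
    circ_mean_pitch = circular_mean(processed$pitch[sel]),
    circ_mean_roll = circular_mean(processed$roll[sel]),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metrics for a whole segment table
#'
#' @param segments Segment data.frame from [build_segment_table()].
#' @param processed_list Named list of `processed_record`s, keyed by
#'   deployment id.
#' @return A data.frame with one metrics row per segment.
#' @export
segment_metrics_table <- function(segments, processed_list) {
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    pr <- processed_list[[seg$deployment_id]]
    if (is.null(pr)) stop(sprintf("no processed record for %s", seg$deployment_id),
                          call. = FALSE)
    segment_metrics(seg, pr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
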