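#' Write report tables for an analysis run
#'
#' Emits delimited summary tables mirroring the standard presentation of
#' a nursing-kinematics analysis:
#'
#' * `deployment_budget.tsv` — per-deployment nursing budget (event count,
#'   mean and total duration, percent of good video), durations rounded to
#'   whole seconds (round-half-to-even) and percentages to two decimals;
#' * `nursing_comparison.tsv` — one row per nursing event with its phase
#'   and its nursing vs phase-matched non-nursing mean speed, ODBA and
#'   FSR (speeds to one decimal, ODBA/FSR to four);
#' * `phase_summary.tsv` — mean ODBA and FSR by role, phase and nursing
#'   status (the per-phase comparison content);
#' * `run_metadata.json` — seeds and configuration echoes.
#'
#' @param metrics Segment metrics table ([segment_metrics_table()]).
#' @param results Optional named list of `comparison_result`s.
#' @param budgets Optional data.frame from [nursing_budget()].
#' @param dir Output directory (created if needed).
#' @param metadata Optional list appended to the metadata JSON.
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(metrics, results = NULL, budgets = NULL,
                          dir = ".", metadata = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  if (!is.null(budgets)) {
    b <- budgets
    b$mean_duration_s <- round(b$mean_duration_s)
    b$total_nursing_s <- round(b$total_nursing_s)
    b$percent_of_good_video <- round(b$percent_of_good_video, 2L)
    p <- file.path(dir, "deployment_budget.tsv")
    utils::write.table(b, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }

  cmp <- nursing_comparison_table(metrics)
  p <- file.path(dir, "nursing_comparison.tsv")
  utils::write.table(cmp, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  ps <- phase_summary_table(metrics)
  p <- file.path(dir, "phase_summary.tsv")
  utils::write.table(ps, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  meta <- c(metadata,
            list(n_segments = if (is.null(metrics)) 0L else nrow(metrics)))
  if (!is.null(results))
    meta$model <- lapply(results, function(r)
      list(response = r$response, nursing_estimate = r$nursing_estimate,
           F = r$F, numdf = r$numdf, dendf = r$dendf, p = r$p))
  p <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

# One row per nursing event: event metrics next to the mean of the
# phase-matched sampled segments of the same deployment and phase.
nursing_comparison_table <- function(metrics) {
  cols <- c("deployment_id", "duration_s", "phase",
            "nursing_speed", "nonnursing_speed",
            "nursing_odba", "nonnursing_odba",
            "nursing_fsr", "nonnursing_fsr")
  if (is.null(metrics) || nrow(metrics) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$deployment_id <- character(0); out$phase <- character(0)
    return(out[, cols])
  }
  nur <- metrics[metrics$is_nursing %in% TRUE, , drop = FALSE]
  base <- metrics[metrics$is_nursing %in% FALSE, , drop = FALSE]
  rows <- lapply(seq_len(nrow(nur)), function(i) {
    b <- base[base$deployment_id == nur$deployment_id[i] &
                base$phase == nur$phase[i], , drop = FALSE]
    data.frame(deployment_id = nur$deployment_id[i],
               duration_s = round(nur$end_s[i] - nur$start_s[i]),
               phase = nur$phase[i],
               nursing_speed = round(nur$mean_speed[i], 1L),
               nonnursing_speed = round(mean(b$mean_speed), 1L),
               nursing_odba = round(nur$mean_odba[i], 4L),
               nonnursing_odba = round(mean(b$mean_odba), 4L),
               nursing_fsr = round(nur$fsr[i], 4L),
               nonnursing_fsr = round(mean(b$fsr), 4L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$phase, out$deployment_id), cols]
}

phase_summary_table <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0L)
    return(data.frame(role = character(), phase = character(),
                      nursing = logical(), n = integer(),
                      mean_odba = numeric(), mean_fsr = numeric()))
  agg <- stats::aggregate(cbind(mean_odba, fsr) ~ role + phase + is_nursing,
                          data = metrics, FUN = mean)
  cnt <- stats::aggregate(start_s ~ role + phase + is_nursing, data = metrics,
                          FUN = length)
  out <- merge(agg, cnt, by = c("role", "phase", "is_nursing"))
  names(out) <- c("role", "phase", "nursing", "mean_odba", "mean_fsr", "n")
  out$mean_odba <- round(out$mean_odba, 4L)
  out$mean_fsr <- round(out$mean_fsr, 4L)
  out[order(out$role, out$phase, out$nursing),
      c("role", "phase", "nursing", "n", "mean_odba", "mean_fsr")]
}
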