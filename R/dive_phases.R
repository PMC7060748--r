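#' Detect dives in a depth series
#'
#' A dive is a maximal interval in which depth exceeds
#' `surface_threshold_m` and attains at least `min_dive_depth_m`
#' (breath-to-breath segmentation). Interval bounds are placed at the
#' threshold crossings, on the closed-open sample grid.
#'
#' @param depth Numeric depth series, m, positive down, uniform rate.
#' @param fs Sampling rate, Hz.
#' @param t Optional time vector; defaults to `(0:(n-1))/fs`.
#' @param surface_threshold_m Depth above which samples count as submerged.
#' @param min_dive_depth_m Minimum maximum-depth for an excursion to count
#'   as a dive.
#' @return A data.frame with `dive`, `start_s`, `end_s`, `max_depth_m`
#'   (zero rows if no dives).
#' @export
detect_dives <- function(depth, fs, t = NULL, surface_threshold_m = 1,
                         min_dive_depth_m = 5) {
  n <- length(depth)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  sub <- depth > surface_threshold_m
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    mx <- max(depth[i0:i1])
    if (mx >= min_dive_depth_m)
      out[[length(out) + 1L]] <- data.frame(start_s = t[i0],
                                            end_s = t[i1] + 1 / fs,
                                            max_depth_m = mx,
                                            i0 = i0, i1 = i1)
  }
  if (!length(out))
    return(data.frame(dive = integer(), start_s = numeric(),
                      end_s = numeric(), max_depth_m = numeric(),
                      i0 = integer(), i1 = integer()))
  res <- do.call(rbind, out)
  cbind(dive = seq_len(nrow(res)), res)
}

#' Partition one dive into descending, horizontal and ascending phases
#'
#' The descending phase runs from the dive start through the first
#' attainment of the dive's maximum depth. The ascending phase is the
#' maximal (earliest-starting) suffix after maximum depth that begins with
#' the depth actually decreasing and within which, scanning forward, depth
#' never rises more than `ascent_excursion_limit_m` above its running
#' minimum — the whale is committed to surfacing, modulo excursions of
#' less than roughly an adult body length. The horizontal phase is
#' whatever lies between; it may be empty (V-shaped dives, where the whale
#' orients to the surface immediately after maximum depth). Pitch is
#' deliberately not used: a nursing calf's pitch is confounded by the
#' behavior itself.
#'
#' Sample-level semantics: samples `1..imax` (first maximum) are
#' descending, samples `j..n` are ascending where `j` is the earliest
#' index after `imax` with `depth[j] < depth[j-1]` whose suffix obeys the
#' excursion rule, and anything between is horizontal. Interval bounds are
#' the closed-open edges of those sample runs.
#'
#' Sample-level semantics: samples `1..imax` (first maximum) are
#' descending and samples `j..n` are ascending, where `j` is the earliest
#' index after `imax` at which the whale has started a committed
#' decrease: depth is strictly decreasing into `j`, the decrease carries
#' on to at least `ascent_commit_tol_m` below `depth[j]` before depth
#' ever rises back above `depth[j]` (so sub-tolerance pressure ripple on
#' a flat bottom cannot anchor an ascent), and the whole suffix from `j`
#' obeys the excursion rule. Anything between descending and ascending is
#' horizontal; for a V-shaped dive the ascent starts immediately after
#' maximum depth and no horizontal samples remain. Re-descents smaller
#' than the excursion limit stay inside the ascent; larger ones push the
#' ascent start past the excursion.
#'
#' @param depth Depth samples of the dive (from [detect_dives()] bounds).
#' @param fs Sampling rate, Hz.
#' @param t Optional time vector for the samples.
#' @param ascent_excursion_limit_m Allowed re-descent within the ascent, m.
#' @param ascent_commit_tol_m Sustained decrease required before a sample
#'   can anchor the ascent, m.
#' @return A data.frame of phase rows (`phase`, `start_s`, `end_s`), in
#'   order descending, (horizontal,) ascending.
#' @export
classify_phases <- function(depth, fs, t = NULL,
                            ascent_excursion_limit_m = 10,
                            ascent_commit_tol_m = 0.2) {
  n <- length(depth)
  if (n < 2L) stop("dive segment too short to classify", call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  dt <- 1 / fs
  if (any(!is.finite(depth)))
    stop("degenerate dive segment: non-finite depth", call. = FALSE)
  imax <- which.max(depth)  # first attainment (which.max takes the first tie)
  suffix_ok <- function(j) {
    d <- depth[j:n]
    all(d - cummin(d) <= ascent_excursion_limit_m)
  }
  # does the decrease into j continue at least tol down before any rise
  # back above depth[j]? (record end counts as committed)
  committed <- function(j) {
    for (k in j:n) {
      if (depth[k] <= depth[j] - ascent_commit_tol_m) return(TRUE)
      if (depth[k] > depth[j]) return(FALSE)
    }
    TRUE
  }
  j <- n
  cand <- which(diff(depth) < 0) + 1L
  cand <- cand[cand > imax]
  for (jc in cand) if (committed(jc) && suffix_ok(jc)) { j <- jc; break }
  # boundaries sit on the sample grid so lookups are float-exact
  desc_end <- if (imax < n) t[imax + 1L] else t[n]
  rows <- data.frame(phase = "descending", start_s = t[1L], end_s = desc_end)
  if (j > imax + 1L)
    rows <- rbind(rows, data.frame(phase = "horizontal",
                                   start_s = desc_end, end_s = t[j]))
  rows <- rbind(rows, data.frame(phase = "ascending",
                                 start_s = t[j], end_s = t[n] + dt))
  rows
}

#' Build the dive-phase table for a whole record
#'
#' Runs [detect_dives()] and [classify_phases()] over a processed record's
#' depth channel.
#'
#' @param record A [tag_record()] (typically at the 10 Hz analysis rate).
#' @param surface_threshold_m,min_dive_depth_m See [detect_dives()].
#' @param ascent_excursion_limit_m See [classify_phases()].
#' @return A data.frame of class `dive_phase_table`: `dive`, `phase`,
#'   `start_s`, `end_s`, `max_depth_m`.
#' @export
dive_phase_table <- function(record, surface_threshold_m = 1,
                             min_dive_depth_m = 5,
                             ascent_excursion_limit_m = 10) {
  stopifnot(inherits(record, "tag_record"))
  dv <- detect_dives(record$depth, record$fs, record$t,
                     surface_threshold_m, min_dive_depth_m)
  rows <- list()
  for (i in seq_len(nrow(dv))) {
    idx <- dv$i0[i]:dv$i1[i]
    ph <- classify_phases(record$depth[idx], record$fs, record$t[idx],
                          ascent_excursion_limit_m)
    ph$dive <- dv$dive[i]
    ph$max_depth_m <- dv$max_depth_m[i]
    rows[[i]] <- ph
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phase = character(), start_s = numeric(), end_s = numeric(),
               dive = integer(), max_depth_m = numeric())
  out <- out[, c("dive", "phase", "start_s", "end_s", "max_depth_m")]
  class(out) <- c("dive_phase_table", "data.frame")
  out
}

#' Phase label at a time point
#'
#' @param table A [dive_phase_table()].
#' @param t Numeric vector of times, seconds.
#' @return Character vector: `"descending"`, `"horizontal"`,
#'   `"ascending"`, or `"surface"` for times outside all dives.
#' @export
phase_of <- function(table, t) {
  out <- rep("surface", length(t))
  if (nrow(table) == 0L) return(out)
  ord <- order(table$start_s)
  starts <- table$start_s[ord]
  k <- findInterval(t, starts)
  hit <- k >= 1L
  hit[hit] <- t[hit] < table$end_s[ord][k[hit]]
  out[hit] <- table$phase[ord][k[hit]]
  out
}
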