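#' Randomly sample phase-matched non-nursing segments
#'
#' Emulates the randomized baseline-selection procedure used for
#' nursing/non-nursing comparisons: draw a uniformly random start time
#' within the deployment, then scan forward to the first admissible
#' window — a `window_s`-long segment lying entirely within one contiguous
#' interval of the requested dive phase and overlapping no nursing,
#' probable-nursing or poor-video interval, nor any previously selected
#' segment. Repeats until `n` pairwise-disjoint segments are found.
#'
#' Feasibility is checked exactly before sampling: greedy earliest-fit
#' packing of the admissible start set yields the maximum number of
#' disjoint windows; if that is below `n` the sampler stops with an error
#' naming the achievable maximum. A draw cap (1e5) guards against
#' livelock on fragmented phases.
#'
#' @param record A [tag_record()] / processed record (defines the
#'   deployment time span and id).
#' @param phases A [dive_phase_table()] for the record.
#' @param events An [event_log()]; exclusion intervals are taken from it.
#' @param phase Phase label to match ("descending", "horizontal",
#'   "ascending").
#' @param n Number of segments to draw.
#' @param window_s Segment length, seconds. The 30 s default covers the
#'   mean nursing event duration (23 s) plus one standard deviation (7 s).
#' @param seed Integer seed; equal inputs and seed reproduce the same
#'   segments.
#' @param exclude Optional matrix/data.frame of extra exclusion intervals
#'   (columns start, end), e.g. segments already chosen for other phases.
#' @return A data.frame of analysis segments: `deployment_id`, `role`,
#'   `start_s`, `end_s`, `phase`, `is_nursing` (FALSE), `source`
#'   ("sampled").
#' @export
sample_nonnursing <- function(record, phases, events, phase, n,
                              window_s = 30, seed = 1L, exclude = NULL) {
  stopifnot(n >= 1, window_s > 0)
  dep <- record$deployment_id
  span_end <- record$t[length(record$t)] + 1 / record$fs
  ph <- phases[phases$phase == phase, , drop = FALSE]
  if (nrow(ph) == 0L)
    stop(sprintf("phase '%s' does not occur in the phase table", phase),
         call. = FALSE)
  excl <- rbind(events_iv(events, dep, c("nursing", "probable_nursing",
                                         "poor_video")),
                if (!is.null(exclude) && nrow(exclude))
                  iv(exclude[, 1L], exclude[, 2L]))
  admissible <- admissible_starts(iv(ph$start_s, ph$end_s), excl, window_s)
  cap <- pack_capacity(admissible, window_s)
  if (cap < n)
    stop(sprintf(paste0("cannot place %d disjoint %g s windows in phase ",
                        "'%s': achievable maximum is %d"),
                 n, window_s, phase, cap), call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  chosen <- iv_empty()
  starts <- numeric(0)
  draws <- 0L
  while (length(starts) < n) {
    draws <- draws + 1L
    if (draws > 1e5L)
      stop("draw cap reached while sampling non-nursing segments", call. = FALSE)
    adm <- admissible_starts(iv(ph$start_s, ph$end_s),
                             rbind(excl, chosen), window_s)
    u <- stats::runif(1L, 0, span_end)
    s <- first_start_at_or_after(adm, u)
    if (is.na(s)) next
    starts <- c(starts, s)
    chosen <- rbind(chosen, c(s, s + window_s))
  }
  data.frame(deployment_id = dep, role = record$role,
             start_s = starts, end_s = starts + window_s,
             phase = phase, is_nursing = FALSE, source = "sampled",
             stringsAsFactors = FALSE)
}

# Closed set of admissible window START times: within each phase interval
# [a, b] a start s is admissible iff [s, s+w) stays inside ([a, b-w]) and
# [s, s+w) misses every exclusion (s outside (e1-w, e2) for each [e1,e2)).
# Returned as closed intervals [lo, hi] with hi >= lo (possibly points).
admissible_starts <- function(phase_iv, excl, w) {
  out <- list()
  excl <- iv_union(excl)
  for (i in seq_len(nrow(phase_iv))) {
    a <- phase_iv[i, 1L]; b <- phase_iv[i, 2L] - w
    if (b < a) next
    pieces <- list(c(a, b))
    for (j in seq_len(nrow(excl))) {
      lo <- excl[j, 1L] - w; hi <- excl[j, 2L] # forbidden OPEN interval (lo, hi)
      nxt <- list()
      for (p in pieces) {
        if (hi <= p[1L] || lo >= p[2L]) { nxt[[length(nxt) + 1L]] <- p; next }
        if (lo >= p[1L]) nxt[[length(nxt) + 1L]] <- c(p[1L], lo)
        if (hi <= p[2L]) nxt[[length(nxt) + 1L]] <- c(hi, p[2L])
      }
      pieces <- nxt
    }
    out <- c(out, pieces)
  }
  if (!length(out)) return(iv_empty())
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

# maximum number of disjoint w-windows placeable on the admissible start
# set: greedy earliest-fit is optimal for equal-length windows.
pack_capacity <- function(adm, w) {
  count <- 0L
  cursor <- -Inf
  repeat {
    s <- first_start_at_or_after(adm, cursor)
    if (is.na(s)) break
    count <- count + 1L
    cursor <- s + w
    # subsequent windows must not overlap: next admissible start >= s + w
  }
  count
}

first_start_at_or_after <- function(adm, u) {
  for (i in seq_len(nrow(adm))) {
    if (adm[i, 2L] < u) next
    return(max(adm[i, 1L], u))
  }
  NA_real_
}

#' Build the full nursing/non-nursing segment table
#'
#' Emits one analysis segment per successful nursing event (at its true
#' duration), copies calf nursing timestamps onto the paired mother's
#' record, and draws `n_calf` (default 15) or `n_mother` (default 9)
#' phase-matched non-nursing segments per deployment for each dive phase
#' in which that individual nursed.
#'
#' @param deployments A list; each element is a list with components
#'   `record` (processed record), `phases` ([dive_phase_table()]), and
#'   optionally `mother_of` (the deployment_id of the calf whose nursing
#'   timestamps this mother record inherits).
#' @param events An [event_log()] holding nursing events on the calf
#'   deployments (plus any probable-nursing/poor-video exclusions).
#' @param n_calf,n_mother Non-nursing segments per phase per deployment.
#' @param window_s Non-nursing window length, seconds.
#' @param seed Integer seed for the segment sampler.
#' @return A data.frame of analysis segments (`deployment_id`, `role`,
#'   `start_s`, `end_s`, `phase`, `is_nursing`, `source`).
#' @export
build_segment_table <- function(deployments, events, n_calf = 15L,
                                n_mother = 9L, window_s = 30, seed = 1L) {
  segs <- list()
  for (k in seq_along(deployments)) {
    d <- deployments[[k]]
    rec <- d$record
    dep <- rec$deployment_id
    nur <- events[events$event_type == "nursing" &
                    events$deployment_id == dep, , drop = FALSE]
    if (nrow(nur) == 0L && !is.null(d$mother_of))
      nur <- events[events$event_type == "nursing" &
                      events$deployment_id == d$mother_of, , drop = FALSE]
    if (nrow(nur) == 0L) next
    nur_phase <- majority_phase(d$phases, nur$start_s, nur$end_s)
    segs[[length(segs) + 1L]] <- data.frame(
      deployment_id = dep, role = rec$role,
      start_s = nur$start_s, end_s = nur$end_s,
      phase = nur_phase, is_nursing = TRUE, source = "event",
      stringsAsFactors = FALSE)
    n_per <- if (rec$role == "calf") n_calf else n_mother
    chosen <- iv(nur$start_s, nur$end_s)
    for (ph in unique(nur_phase)) {
      if (ph == "surface") next
      smp <- sample_nonnursing(rec, d$phases, events, ph, n_per, window_s,
                               seed = seed + k * 1009L + nchar(ph),
                               exclude = chosen)
      chosen <- rbind(chosen, iv(smp$start_s, smp$end_s))
      segs[[length(segs) + 1L]] <- smp
    }
  }
  if (!length(segs))
    return(data.frame(deployment_id = character(), role = character(),
                      start_s = numeric(), end_s = numeric(),
                      phase = character(), is_nursing = logical(),
                      source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# phase covering the majority of each interval (ties: earlier phase row)
majority_phase <- function(phases, start_s, end_s) {
  vapply(seq_along(start_s), function(i) {
    ov <- pmin(phases$end_s, end_s[i]) - pmax(phases$start_s, start_s[i])
    ov[ov < 0] <- 0
    surf <- (end_s[i] - start_s[i]) - sum(ov)
    if (!nrow(phases) || max(ov) < surf) return("surface")
    phases$phase[which.max(ov)]
  }, character(1L))
}
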