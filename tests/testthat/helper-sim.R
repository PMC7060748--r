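# Shared simulation shortcuts and independent brute-force oracles.
# Simulations in tests run at a reduced acceleration rate (50 Hz) and short
# durations so the suite stays fast; rates and effect sizes are the
# generator defaults.

quick_cfg <- function(seed, duration_s = 900, fs_hi = 50, ...) {
  sim_config(seed = seed, duration_s = duration_s, fs_hi = fs_hi, ...)
}

plan_duration <- function(plan, slack_s = 120) {
  sum(plan$surface_s + plan$max_depth / plan$descent_rate + plan$bottom_s +
        (plan$max_depth + 2 * ifelse(is.null(plan$excursion_m), 0, plan$excursion_m)) /
        plan$ascent_rate) + slack_s
}

# a mother-calf pair over a multi-dive plan with nursing events placed in
# the requested ground-truth phases
sim_study_pair <- function(seed, n_dives = 6, event_phases = c("horizontal", "descending"),
                           event_durations = c(25, 20), fs_hi = 50) {
  plan <- default_dive_plan(n_dives)
  dur <- plan_duration(plan)
  cfg0 <- sim_config(seed = seed, duration_s = dur, fs_hi = fs_hi, dive_plan = plan)
  ds <- simulate_depth_profile(cfg0)
  ph <- sim_phase_intervals(ds)
  ne <- do.call(rbind, lapply(seq_along(event_phases), function(i) {
    cand <- ph[ph$phase == event_phases[i] &
                 (ph$end_s - ph$start_s) > event_durations[i] + 10, ]
    row <- cand[1L + (i - 1L) %% nrow(cand), ]
    data.frame(start_s = row$start_s + 5, duration_s = event_durations[i],
               phase = event_phases[i])
  }))
  cfg <- sim_config(seed = seed, duration_s = dur, fs_hi = fs_hi,
                    dive_plan = plan, nursing_events = ne)
  simulate_pair(cfg)
}

# ---- independent oracles -------------------------------------------------

# Sample-by-sample phase rule, written as a literal scan (no cummin/rle
# shortcuts): descending = 1..first max; ascending starts at the earliest
# sample j after the max with (i) depth strictly decreasing into j,
# (ii) the decrease continuing at least tol below depth[j] before any
# rise back above it, and (iii) a suffix that never rises more than
# limit above its running minimum; horizontal is the remainder.
oracle_phases <- function(depth, limit = 10, tol = 0.2) {
  n <- length(depth)
  imax <- 1L
  for (i in seq_len(n)) if (depth[i] > depth[imax]) imax <- i
  suffix_ok <- function(j) {
    m <- depth[j]
    for (k in j:n) {
      if (depth[k] < m) m <- depth[k]
      if (depth[k] - m > limit) return(FALSE)
    }
    TRUE
  }
  committed <- function(j) {
    for (k in j:n) {
      if (depth[k] <= depth[j] - tol) return(TRUE)
      if (depth[k] > depth[j]) return(FALSE)
    }
    TRUE
  }
  j <- n
  if (imax < n) {
    for (cand in (imax + 1L):n) {
      if (depth[cand] < depth[cand - 1L] && committed(cand) &&
            suffix_ok(cand)) { j <- cand; break }
    }
  }
  lab <- rep("horizontal", n)
  lab[1:imax] <- "descending"
  lab[j:n] <- "ascending"
  lab
}

# random plausible dive traces for oracle comparison: jittered descent,
# wiggly bottom, ascent with optional re-descent excursions
random_dive <- function(fs = 10) {
  maxd <- runif(1, 15, 60)
  rate <- runif(1, 0.5, 1.5)
  down <- seq(1.2, maxd, by = rate / fs)
  bottom <- maxd + cumsum(rnorm(round(runif(1, 0, 90) * fs), 0, 0.05))
  bottom <- pmin(bottom, maxd)
  up <- seq(maxd, 1.2, by = -rate / fs)
  if (runif(1) < 0.5) {
    # splice an excursion into the ascent
    exc <- runif(1, 2, 15)
    at <- sample(seq_along(up)[-1], 1)
    dipdown <- seq(up[at], up[at] + exc, by = rate / fs)
    dipup <- seq(up[at] + exc, up[at], by = -rate / fs)
    up <- c(up[1:at], dipdown, dipup, up[at:length(up)])
  }
  d <- c(down, bottom, up) + rnorm(length(down) + length(bottom) + length(up), 0, 0.02)
  pmax(d, 1.05)
}

# linear-scan phase lookup
oracle_phase_of <- function(table, t) {
  for (i in seq_len(nrow(table)))
    if (t >= table$start_s[i] && t < table$end_s[i]) return(table$phase[i])
  "surface"
}

# discretized interval-difference length |a \ b| at 10 Hz
oracle_diff_length <- function(a, b, lo, hi, fs = 10) {
  tt <- seq(lo, hi - 1 / fs, by = 1 / fs) + 0.5 / fs
  ina <- rep(FALSE, length(tt)); inb <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(a))) ina <- ina | (tt >= a[i, 1] & tt < a[i, 2])
  for (i in seq_len(nrow(b))) inb <- inb | (tt >= b[i, 1] & tt < b[i, 2])
  sum(ina & !inb) / fs
}

random_intervals <- function(n, lo, hi, min_len = 2, max_len = 60) {
  s <- sort(runif(n, lo, hi - max_len))
  len <- runif(n, min_len, max_len)
  # enforce disjointness by clipping
  out <- list()
  cursor <- lo
  for (i in seq_len(n)) {
    a <- max(s[i], cursor)
    b <- min(a + len[i], hi)
    if (b > a) { out[[length(out) + 1L]] <- c(a, b); cursor <- b + 0.1 }
  }
  do.call(rbind, out)
}

# Segment-metric tables shaped like the published calf design: 4
# individuals, nursing events spread over phases as in the per-event
# table (1 asc / 1+2 desc+horiz / 2+1 / 1+3), 15 baselines per
# deployment-phase; 116 rows in all.
study_design <- function() {
  des <- list(list(id = "A", ev = c(ascending = 1)),
              list(id = "B", ev = c(descending = 1, horizontal = 2)),
              list(id = "C", ev = c(descending = 2, horizontal = 1)),
              list(id = "D", ev = c(descending = 1, horizontal = 3)))
  do.call(rbind, lapply(des, function(d) {
    ph <- names(d$ev)
    rbind(data.frame(deployment_id = d$id, phase = rep(ph, d$ev),
                     is_nursing = TRUE),
          data.frame(deployment_id = d$id, phase = rep(ph, each = 15),
                     is_nursing = FALSE))
  }))
}

# per-segment response mimicking the pipeline's segment statistics:
# baseline level, modest relative noise, individual offsets, and a
# multiplicative nursing effect
draw_response <- function(design, effect = 1, base = 0.19, rel_sd = 0.15,
                          ind_sd = 0.03) {
  b <- stats::rnorm(4, 0, ind_sd)
  names(b) <- unique(design$deployment_id)
  base * (1 + stats::rnorm(nrow(design), 0, rel_sd)) *
    ifelse(design$is_nursing, effect, 1) + b[design$deployment_id]
}

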