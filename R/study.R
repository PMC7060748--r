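#' Simulate a study with the published deployment structure
#'
#' Generates synthetic deployments mirroring the design of the source
#' study: four calf deployments whose nursing events have the published
#' per-event durations and dive phases (11 events: 1 ascending, 4
#' descending, 6 horizontal, from [fixture_table2()]), plus the two
#' mother deployments paired with the calves that carried three of those
#' events. Every deployment runs over an `n_dives`-dive plan long enough
#' to host fifteen 30 s baseline windows per nursed phase.
#'
#' @param seed Integer master seed; each deployment derives its own
#'   stream from it.
#' @param fs_hi Acceleration sampling rate for the synthetic tags, Hz.
#'   The default simulates at a reduced rate to keep desk-scale runs
#'   fast; the dynamics are band-limited far below either Nyquist.
#' @param n_dives Dives per deployment.
#' @return A list with `deployments` — a named list, each element holding
#'   `record`, `truth`, `role` and (for mothers) `mother_of` — and
#'   `events`, the combined ground-truth nursing [event_log()] on the
#'   calf time bases.
#' @export
simulate_study <- function(seed = 1L, fs_hi = 50, n_dives = 17L) {
  t2 <- fixture_table2()
  calves <- t2[t2$role == "calf", ]
  pairs <- c("mn170613-40" = "mn170613-20", "mn180831-30" = "mn180831-20")
  plan <- default_dive_plan(n_dives)
  dur <- sum(plan$surface_s + plan$max_depth / plan$descent_rate +
               plan$bottom_s + plan$max_depth / plan$ascent_rate) + 120

  deployments <- list()
  all_events <- list()
  k <- 0L
  for (dep in unique(calves$individual)) {
    k <- k + 1L
    rows <- calves[calves$individual == dep, ]
    dep_seed <- seed + k * 101L
    cfg0 <- sim_config(seed = dep_seed, duration_s = dur, fs_hi = fs_hi,
                       dive_plan = plan, deployment_id = dep, role = "calf")
    ds <- simulate_depth_profile(cfg0)
    ph <- sim_phase_intervals(ds)
    ne <- place_events(ph, tolower(rows$phase), rows$duration_s)
    cfg <- sim_config(seed = dep_seed, duration_s = dur, fs_hi = fs_hi,
                      dive_plan = plan, deployment_id = dep, role = "calf",
                      nursing_events = ne)
    out <- simulate_deployment(cfg)
    deployments[[dep]] <- list(record = out$record, truth = out$truth,
                               role = "calf")
    all_events[[dep]] <- out$truth$events

    if (dep %in% names(pairs)) {
      mid <- pairs[[dep]]
      # the mother's tag covers only the events listed under her id in the
      # per-event table (e.g. two of the calf's three for mn170613-20);
      # her nursing timestamps are the calf's for those events
      mrows <- t2[t2$individual == mid, ]
      keep <- mapply(function(ph, du) which(tolower(ne$phase) == tolower(ph) &
                                              ne$duration_s == du)[1L],
                     mrows$phase, mrows$duration_s)
      mne <- ne[sort(keep), , drop = FALSE]
      mcfg <- sim_config(seed = dep_seed + 1000003L, duration_s = dur,
                         fs_hi = fs_hi, dive_plan = plan,
                         deployment_id = mid, role = "mother",
                         nursing_events = mne)
      mout <- simulate_deployment(mcfg)
      deployments[[mid]] <- list(record = mout$record, truth = mout$truth,
                                 role = "mother", mother_of = dep)
      all_events[[mid]] <- mout$truth$events
    }
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  class(events) <- c("event_log", "data.frame")
  list(deployments = deployments, events = events)
}

# drop each event into a distinct ground-truth interval of its phase
place_events <- function(phase_iv, phases, durations) {
  used <- integer(0)
  rows <- lapply(seq_along(phases), function(i) {
    cand <- which(phase_iv$phase == phases[i] &
                    phase_iv$end_s - phase_iv$start_s > durations[i] + 10)
    cand <- setdiff(cand, used)
    if (!length(cand))
      stop(sprintf("no free %s interval can host a %g s event",
                   phases[i], durations[i]), call. = FALSE)
    used <<- c(used, cand[1L])
    data.frame(start_s = phase_iv$start_s[cand[1L]] + 5,
               duration_s = durations[i], phase = phases[i])
  })
  do.call(rbind, rows)
}

#' Run the full nursing-kinematics analysis on a simulated study
#'
#' Processes every deployment to 10 Hz, builds dive-phase tables, draws
#' the phase-matched baseline segments, computes segment metrics and fits
#' the mixed-effects nursing comparisons for the calves (ODBA and FSR).
#'
#' @param study Output of [simulate_study()].
#' @param seed Integer seed for the baseline segment sampler.
#' @param n_calf,n_mother Baseline segments per nursed phase.
#' @return A list: `segments`, `metrics`, `models` (list with `odba` and
#'   `fsr` [fit_nursing_model()] results on the calf segments), and
#'   `processed` (named list of processed records).
#' @export
analyze_study <- function(study, seed = 1L, n_calf = 15L, n_mother = 9L) {
  processed <- lapply(study$deployments, function(d) process_record(d$record))
  deps <- lapply(names(study$deployments), function(id) {
    d <- study$deployments[[id]]
    list(record = processed[[id]], phases = dive_phase_table(processed[[id]]),
         mother_of = d$mother_of)
  })
  segments <- build_segment_table(deps, study$events, n_calf = n_calf,
                                  n_mother = n_mother, seed = seed)
  metrics <- segment_metrics_table(segments, processed)
  calf <- metrics[metrics$role == "calf", ]
  models <- list(odba = fit_nursing_model(calf, "mean_odba"),
                 fsr = fit_nursing_model(calf, "fsr"))
  list(segments = segments, metrics = metrics, models = models,
       processed = processed)
}
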