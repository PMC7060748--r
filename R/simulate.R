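#' Configuration for the synthetic deployment generator
#'
#' Builds the parameter set for simulating one tagged whale: a dive plan, a
#' fluking gait, nursing events with role-specific effect multipliers, and
#' sensor noise. The generator emulates the sensor mix of combined
#' video/motion tags: tri-axial acceleration synthesized at `fs_hi`
#' (default 400 Hz) and a pressure channel effectively sampled at
#' `fs_depth` (default 10 Hz; depth is generated at `fs_hi`, subsampled to
#' `fs_depth` and held, so the stored channel carries 10 Hz information).
#'
#' The gait model is dorsoventral (heave-axis) sinusoidal stroking at
#' `stroke_freq_hz`, interrupted by glides: active and gliding bouts
#' alternate with exponential durations such that the long-run glide
#' fraction equals `glide_fraction`. Baseline defaults (0.25 Hz strokes,
#' 0.3 m/s^2 amplitude, 2% glide-adjusted) put segment mean ODBA near
#' 0.2 m/s^2, the magnitude range observed on free-swimming mother-calf
#' pairs. During nursing events the calf's stroke frequency and amplitude
#' are scaled up (defaults x1.7 FSR, x1.5 ODBA) and the mother's scaled
#' down (x0.3), matching the direction and rough magnitude of published
#' nursing-vs-baseline contrasts.
#'
#' @param seed Integer seed; equal configurations (including seed) produce
#'   bit-identical output.
#' @param duration_s Total record duration in seconds.
#' @param fs_hi Acceleration sampling rate, Hz; must be a multiple of 10
#'   and of `fs_depth`.
#' @param fs_depth Pressure sampling rate, Hz.
#' @param dive_plan `data.frame` with columns `surface_s`, `descent_rate`
#'   (m/s), `max_depth` (m), `bottom_s`, `ascent_rate` (m/s); optional
#'   `excursion_m` and `excursion_frac` add a V-shaped re-descent part-way
#'   up the ascent.
#' @param seafloor_m Maximum permissible planned depth.
#' @param stroke_freq_hz,stroke_amp,glide_fraction Gait: baseline stroke
#'   frequency (Hz), heave amplitude (m/s^2), and long-run glide fraction
#'   in `[0, 1]`.
#' @param glide_bout_mean_s Mean duration of a glide bout, seconds;
#'   active-bout mean duration is derived from it and `glide_fraction`
#'   (glides of tens of seconds are typical of steadily traveling
#'   humpbacks).
#' @param nursing_events `data.frame` with columns `start_s`,
#'   `duration_s` and optionally `phase` (intent label); events must be
#'   non-overlapping and lie within dives.
#' @param calf_fsr_mult,calf_odba_mult Calf nursing multipliers (> 1 for
#'   elevated effort).
#' @param mother_fsr_mult,mother_odba_mult Mother nursing multipliers
#'   (< 1 for suppressed effort).
#' @param noise_sd Gaussian sensor noise, m/s^2 per axis.
#' @param speed_base,speed_ripple Speed channel: base speed (m/s) plus a
#'   stroke-phase-locked ripple of relative amplitude `speed_ripple`.
#' @param role "calf" or "mother"; selects which multipliers apply.
#' @param deployment_id Identifier stamped on the output record.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 1200,
                       fs_hi = 400, fs_depth = 10,
                       dive_plan = default_dive_plan(),
                       seafloor_m = 100,
                       stroke_freq_hz = 0.25,
                       stroke_amp = 0.3,
                       glide_fraction = 0.1,
                       glide_bout_mean_s = 20,
                       nursing_events = NULL,
                       calf_fsr_mult = 1.7, calf_odba_mult = 1.5,
                       mother_fsr_mult = 0.3, mother_odba_mult = 0.3,
                       noise_sd = 0.02,
                       speed_base = 1.5, speed_ripple = 0.1,
                       role = "calf",
                       deployment_id = NULL) {
  role <- match.arg(role, c("calf", "mother"))
  if (fs_hi %% 10 != 0 || fs_hi %% fs_depth != 0)
    stop("fs_hi must be a multiple of 10 and of fs_depth", call. = FALSE)
  mults <- c(calf_fsr_mult, calf_odba_mult, mother_fsr_mult, mother_odba_mult)
  if (any(!is.finite(mults)) || any(mults < 0))
    stop("effect multipliers must be non-negative", call. = FALSE)
  if (glide_fraction < 0 || glide_fraction > 1)
    stop("glide_fraction must lie in [0, 1]", call. = FALSE)
  dp <- as.data.frame(dive_plan)
  need <- c("surface_s", "descent_rate", "max_depth", "bottom_s", "ascent_rate")
  if (!all(need %in% names(dp)))
    stop("dive_plan must have columns surface_s, descent_rate, max_depth, bottom_s, ascent_rate",
         call. = FALSE)
  if (is.null(dp$excursion_m)) dp$excursion_m <- 0
  if (is.null(dp$excursion_frac)) dp$excursion_frac <- 0.5
  if (any(dp$max_depth + dp$excursion_m > seafloor_m))
    stop("dive plan exceeds configured seafloor depth", call. = FALSE)
  if (any(dp$descent_rate <= 0 | dp$ascent_rate <= 0 | dp$max_depth <= 0))
    stop("dive rates and depths must be positive", call. = FALSE)
  ne <- nursing_events
  if (!is.null(ne)) {
    ne <- as.data.frame(ne)
    if (!all(c("start_s", "duration_s") %in% names(ne)))
      stop("nursing_events needs columns start_s and duration_s", call. = FALSE)
    if (is.null(ne$phase)) ne$phase <- NA_character_
    if (any(ne$duration_s <= 0)) stop("nursing durations must be positive", call. = FALSE)
    ne <- ne[order(ne$start_s), , drop = FALSE]
    if (nrow(ne) > 1L &&
        any(ne$start_s[-1L] < (ne$start_s + ne$duration_s)[-nrow(ne)]))
      stop("nursing events may not overlap", call. = FALSE)
  }
  if (is.null(deployment_id))
    deployment_id <- sprintf("sim%04d-%s", seed %% 10000L,
                             if (role == "calf") "40" else "20")
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 fs_hi = fs_hi, fs_depth = fs_depth, dive_plan = dp,
                 seafloor_m = seafloor_m, stroke_freq_hz = stroke_freq_hz,
                 stroke_amp = stroke_amp, glide_fraction = glide_fraction,
                 glide_bout_mean_s = glide_bout_mean_s,
                 nursing_events = ne,
                 calf_fsr_mult = calf_fsr_mult, calf_odba_mult = calf_odba_mult,
                 mother_fsr_mult = mother_fsr_mult, mother_odba_mult = mother_odba_mult,
                 noise_sd = noise_sd, speed_base = speed_base,
                 speed_ripple = speed_ripple, role = role,
                 deployment_id = deployment_id),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_dives Number of dives in the default plan: 60 s surface
#'   intervals, descents/ascents at 1 m/s to depths cycling 35/45/55 m,
#'   bottom times cycling 120/90/150 s.
#' @export
default_dive_plan <- function(n_dives = 3L) {
  idx <- seq_len(n_dives)
  data.frame(surface_s = 60,
             descent_rate = 1.0,
             max_depth = rep_len(c(35, 45, 55), n_dives),
             bottom_s = rep_len(c(120, 90, 150), n_dives),
             ascent_rate = 1.0)[idx, , drop = FALSE]
}

# gravity constant used throughout the generator and orientation math
GRAVITY <- 9.81

#' Simulate a depth profile with ground-truth phase labels
#'
#' Builds a piecewise-linear depth trace at `fs_hi` from the configured dive
#' plan: each dive descends at its planned rate to its maximum depth,
#' optionally holds a flat bottom, then ascends (optionally with a V-shaped
#' re-descent excursion). Remaining time after the plan is spent at the
#' surface.
#'
#' @param config A [sim_config()].
#' @return A list with `t`, `depth` (both at `fs_hi`), per-sample
#'   ground-truth `phase` labels (`surface`/`descending`/`horizontal`/
#'   `ascending`), integer `dive_id` (`NA` at the surface), and `dives`,
#'   a data.frame of planned dive intervals.
#' @export
simulate_depth_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dp <- config$dive_plan
  # breakpoints: (time, depth, phase label of the segment that follows)
  bt <- 0; bd <- 0; lab <- character(); seg_start <- numeric(); seg_end <- numeric()
  dive_start <- numeric(); dive_end <- numeric()
  add <- function(dur, depth_to, phase) {
    if (dur <= 0) return(invisible())
    seg_start <<- c(seg_start, bt[length(bt)])
    bt <<- c(bt, bt[length(bt)] + dur)
    bd <<- c(bd, depth_to)
    seg_end <<- c(seg_end, bt[length(bt)])
    lab <<- c(lab, phase)
    invisible()
  }
  for (i in seq_len(nrow(dp))) {
    add(dp$surface_s[i], 0, "surface")
    t0 <- bt[length(bt)]
    add(dp$max_depth[i] / dp$descent_rate[i], dp$max_depth[i], "descending")
    add(dp$bottom_s[i], dp$max_depth[i], "horizontal")
    exc <- dp$excursion_m[i]
    if (exc > 0) {
      d_turn <- dp$max_depth[i] * (1 - dp$excursion_frac[i])
      add((dp$max_depth[i] - d_turn) / dp$ascent_rate[i], d_turn, "ascending")
      add(exc / dp$ascent_rate[i], d_turn + exc, "ascending")
      add((d_turn + exc) / dp$ascent_rate[i], 0, "ascending")
    } else {
      add(dp$max_depth[i] / dp$ascent_rate[i], 0, "ascending")
    }
    dive_start <- c(dive_start, t0)
    dive_end <- c(dive_end, bt[length(bt)])
  }
  total <- bt[length(bt)]
  if (total > config$duration_s)
    stop(sprintf("dive plan needs %.1f s but duration_s is %.1f s",
                 total, config$duration_s), call. = FALSE)
  add(config$duration_s - total, 0, "surface")
  n <- floor(config$duration_s * config$fs_hi)
  t <- (seq_len(n) - 1L) / config$fs_hi
  depth <- stats::approx(bt, bd, xout = t, rule = 2)$y
  phase <- rep("surface", n)
  dive_id <- rep(NA_integer_, n)
  for (k in seq_along(lab)) {
    sel <- t >= seg_start[k] & t < seg_end[k]
    phase[sel] <- lab[k]
  }
  for (d in seq_along(dive_start))
    dive_id[t >= dive_start[d] & t < dive_end[d]] <- d
  list(t = t, depth = depth, phase = phase, dive_id = dive_id,
       dives = data.frame(dive = seq_along(dive_start),
                          start_s = dive_start, end_s = dive_end,
                          max_depth = dp$max_depth + ifelse(dp$excursion_m > 0, 0, 0)))
}

# Shared synthesis core. Multiplier series scale stroke frequency and
# amplitude per sample; all RNG draws happen in a fixed order under the
# config seed so runs with all-ones multipliers and runs with event-driven
# multipliers agree sample-for-sample outside the events.
synth_record <- function(depth_sim, config, fsr_mult, amp_mult,
                         force_active = NULL) {
  n <- length(depth_sim$t)
  fs <- config$fs_hi
  dt <- 1 / fs
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  # alternating active/glide bouts with exponential durations
  g <- config$glide_fraction
  active <- rep(TRUE, n)
  if (g >= 1) {
    active[] <- FALSE
  } else if (g > 0) {
    mean_glide <- config$glide_bout_mean_s
    mean_active <- mean_glide * (1 - g) / g
    tt <- 0; state <- TRUE
    while (tt < config$duration_s) {
      dur <- stats::rexp(1L, 1 / if (state) mean_active else mean_glide)
      if (!state) {
        i0 <- max(1L, floor(tt * fs) + 1L)
        i1 <- min(n, ceiling((tt + dur) * fs))
        if (i1 >= i0) active[i0:i1] <- FALSE
      }
      tt <- tt + dur
      state <- !state
    }
  }
  # nursing requires station-keeping effort: stroke through event windows
  if (!is.null(force_active)) active[force_active] <- TRUE

  # Stroke phase advances only while actively stroking, and every active
  # bout runs to a completed oscillation (phase a multiple of 2*pi) before
  # the glide starts: the heave signal is exactly zero throughout glides,
  # as a whale finishes its stroke before gliding. This avoids gating
  # transients that a stroke detector would have to disambiguate.
  omega_base <- 2 * pi * config$stroke_freq_hz * fsr_mult
  phi <- numeric(n)
  runs <- rle(active)
  run_end <- cumsum(runs$lengths)
  run_start <- c(1L, utils::head(run_end, -1L) + 1L)
  cur <- 0
  k <- 1L
  while (k <= length(runs$lengths)) {
    a <- run_start[k]; b <- run_end[k]
    if (runs$values[k]) {
      phi[a:b] <- cur + cumsum(omega_base[a:b]) * dt
      cur <- phi[b]
      # run on into the glide until the oscillation completes
      target <- 2 * pi * ceiling(cur / (2 * pi) - 1e-9)
      i <- b
      while (cur < target - 1e-9 && i < n) {
        i <- i + 1L
        cur <- cur + omega_base[i] * dt
        phi[i] <- cur
        active[i] <- TRUE
      }
      # snap the completed oscillation exactly onto the 2*pi grid so the
      # ground-truth wrap lands at the physical completion time
      cur <- max(cur, target)
      if (phi[i] < target && i >= a) phi[i] <- target
      if (i > b && k < length(runs$lengths)) {
        # absorb the overlapped part of the following glide run
        run_start[k + 1L] <- max(run_start[k + 1L], i + 1L)
        if (run_start[k + 1L] > run_end[k + 1L]) k <- k + 1L
      }
    } else {
      if (run_start[k] <= run_end[k]) phi[a:b] <- cur
    }
    k <- k + 1L
  }
  env <- runmean_partial(as.numeric(active), half = max(1L, as.integer(round(2 * fs))))
  dyn_z <- config$stroke_amp * amp_mult * env * sin(phi)
  # ground-truth stroke times: completion of each full oscillation
  k_max <- floor(phi[n] / (2 * pi))
  stroke_times <- if (k_max >= 1) {
    targets <- 2 * pi * seq_len(k_max)
    # last sample with phi strictly below the target (phi nondecreasing and
    # plateaued exactly at completed cycles during glides)
    idx <- findInterval(targets, phi, left.open = TRUE)
    vapply(seq_along(targets), function(j) {
      i <- idx[j]
      if (i >= n) return(depth_sim$t[n])
      if (i < 1L) return(depth_sim$t[1L])
      frac <- (targets[j] - phi[i]) / max(phi[i + 1L] - phi[i], 1e-12)
      depth_sim$t[i] + frac * dt
    }, numeric(1L))
  } else numeric(0)

  speed <- config$speed_base * (1 + config$speed_ripple * sin(phi) * as.numeric(active))
  vz <- c(0, diff(depth_sim$depth)) * fs         # m/s, positive down
  # whales re-orient over many seconds, not samples: smooth the vertical
  # rate so posture changes at dive-plan corners take ~14 s
  vz <- runmean_partial(vz, half = max(1L, as.integer(round(7 * fs))))
  # postural pitch follows the travel speed, not the stroke-locked ripple
  pitch <- asin(pmax(-0.99, pmin(0.99, -vz / max(config$speed_base, 0.1))))
  static <- cbind(GRAVITY * sin(pitch), 0, -GRAVITY * cos(pitch))
  noise <- matrix(stats::rnorm(3L * n, 0, config$noise_sd), ncol = 3L)
  acc <- static + noise
  acc[, 3L] <- acc[, 3L] + dyn_z

  # pressure sensor runs at fs_depth: subsample then hold
  r <- fs / config$fs_depth
  depth_ds <- depth_sim$depth[seq(1L, n, by = r)]
  depth_hold <- rep(depth_ds, each = r)[seq_len(n)]

  rec <- tag_record(deployment_id = config$deployment_id, role = config$role,
                    fs = fs, acc = acc, depth = depth_hold, speed = speed,
                    t = depth_sim$t)
  attr(rec, "sim") <- list(depth_sim = depth_sim, stroke_times = stroke_times,
                           active = active, dyn_z = dyn_z, phi = phi,
                           config = config)
  rec
}

#' Synthesize tag kinematics over a simulated depth profile
#'
#' Generates the tri-axial specific-force, speed and (held 10 Hz) depth
#' channels for a deployment without nursing effects: gravity orientation
#' follows the instantaneous pitch implied by vertical rate and speed,
#' dorsoventral stroking follows the configured gait, and Gaussian sensor
#' noise is added to all axes. Use [embed_nursing()] to impose nursing
#' events on the result.
#'
#' @param depth_sim Output of [simulate_depth_profile()].
#' @param config The same [sim_config()].
#' @return A [tag_record()] carrying simulation ground truth as an
#'   attribute.
#' @export
simulate_kinematics <- function(depth_sim, config) {
  stopifnot(inherits(config, "sim_config"))
  ones <- rep(1, length(depth_sim$t))
  synth_record(depth_sim, config, ones, ones)
}

#' Impose nursing events on a simulated record
#'
#' Re-synthesizes the record with stroke frequency and amplitude scaled
#' inside each configured nursing event by the role's multipliers (calf
#' defaults > 1, mother defaults < 1; the same RNG stream is used, so with
#' unit multipliers the output is identical to the input). Events must lie
#' within dives.
#'
#' @param record Output of [simulate_kinematics()].
#' @param config The same [sim_config()], with `nursing_events` set.
#' @return A list: `record` (the modified [tag_record()]) and `truth`, the
#'   ground truth (event log, per-sample phase labels, true stroke times,
#'   per-event noise-free mean ODBA).
#' @export
embed_nursing <- function(record, config) {
  sim <- attr(record, "sim")
  if (is.null(sim)) stop("record does not carry simulation ground truth", call. = FALSE)
  depth_sim <- sim$depth_sim
  ne <- config$nursing_events
  if (is.null(ne) || nrow(ne) == 0L) {
    truth <- ground_truth(record, config, event_log())
    return(list(record = record, truth = truth))
  }
  # every event must lie within a dive
  for (i in seq_len(nrow(ne))) {
    s <- ne$start_s[i]; e <- s + ne$duration_s[i]
    inside <- any(depth_sim$dives$start_s <= s & depth_sim$dives$end_s >= e)
    if (!inside)
      stop(sprintf("nursing event [%g, %g) lies outside all dives", s, e),
           call. = FALSE)
  }
  if (config$role == "calf") {
    f_m <- config$calf_fsr_mult; a_m <- config$calf_odba_mult
  } else {
    f_m <- config$mother_fsr_mult; a_m <- config$mother_odba_mult
  }
  t <- depth_sim$t
  fsr_mult <- rep(1, length(t)); amp_mult <- rep(1, length(t))
  in_event <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ne))) {
    sel <- t >= ne$start_s[i] & t < ne$start_s[i] + ne$duration_s[i]
    fsr_mult[sel] <- f_m
    amp_mult[sel] <- a_m
    in_event[sel] <- TRUE
  }
  # with unit multipliers nursing leaves the record untouched; otherwise
  # the whale strokes throughout its nursing events
  force_active <- if (f_m != 1 || a_m != 1) in_event else NULL
  rec2 <- synth_record(depth_sim, config, fsr_mult, amp_mult, force_active)
  ev <- event_log(deployment_id = rep(config$deployment_id, nrow(ne)),
                  event_type = "nursing",
                  start_s = ne$start_s, end_s = ne$start_s + ne$duration_s,
                  note = ifelse(is.na(ne$phase), "", ne$phase))
  list(record = rec2, truth = ground_truth(rec2, config, ev))
}

ground_truth <- function(record, config, events) {
  sim <- attr(record, "sim")
  odba_true <- if (nrow(events)) vapply(seq_len(nrow(events)), function(i) {
    sel <- sim$depth_sim$t >= events$start_s[i] & sim$depth_sim$t < events$end_s[i]
    mean(abs(sim$dyn_z[sel]))
  }, numeric(1L)) else numeric(0)
  list(events = events,
       phase = sim$depth_sim$phase,
       dive_id = sim$depth_sim$dive_id,
       dives = sim$depth_sim$dives,
       stroke_times = sim$stroke_times,
       active = sim$active,
       event_mean_odba = odba_true)
}

#' Simulate a full deployment
#'
#' Convenience wrapper: depth profile, kinematics, and nursing embedding in
#' one call.
#'
#' @param config A [sim_config()].
#' @return A list with `record` and `truth` (see [embed_nursing()]).
#' @export
simulate_deployment <- function(config) {
  ds <- simulate_depth_profile(config)
  rec <- simulate_kinematics(ds, config)
  embed_nursing(rec, config)
}

#' Simulate a mother-calf pair
#'
#' Generates a calf deployment and the associated mother deployment over
#' the same dive plan and nursing times, with role-appropriate effect
#' multipliers (calf effort elevated, mother effort suppressed during
#' nursing). The mother's sensor noise stream uses an offset seed.
#'
#' @param config A [sim_config()] describing the calf; the mother inherits
#'   everything but role, id and seed.
#' @return A list with elements `calf` and `mother`, each as returned by
#'   [simulate_deployment()].
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  calf_cfg <- config
  calf_cfg$role <- "calf"
  mother_cfg <- config
  mother_cfg$role <- "mother"
  mother_cfg$seed <- config$seed + 1000003L
  mother_cfg$deployment_id <- sub("-40$", "-20", config$deployment_id)
  if (identical(mother_cfg$deployment_id, config$deployment_id))
    mother_cfg$deployment_id <- paste0(config$deployment_id, "-mother")
  list(calf = simulate_deployment(calf_cfg),
       mother = simulate_deployment(mother_cfg))
}

#' Ground-truth phase intervals of a simulated depth profile
#'
#' Contiguous runs of one plan-based phase label, handy for placing
#' nursing events inside a chosen phase when configuring a simulation.
#'
#' @param depth_sim Output of [simulate_depth_profile()].
#' @return A data.frame with `phase`, `start_s`, `end_s`, `dive_id`.
#' @export
sim_phase_intervals <- function(depth_sim) {
  ph <- depth_sim$phase
  t <- depth_sim$t
  dt <- t[2L] - t[1L]
  runs <- rle(ph)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(phase = runs$values,
             start_s = t[starts],
             end_s = t[ends] + dt,
             dive_id = depth_sim$dive_id[starts])
}
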