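test_that("depth profiles follow the dive plan with closed-form durations", {
  plan <- data.frame(surface_s = 60, descent_rate = 1, max_depth = 30,
                     bottom_s = 120, ascent_rate = 1)
  cfg <- quick_cfg(1, duration_s = 400, dive_plan = plan)
  ds <- simulate_depth_profile(cfg)
  # descent 30 s + bottom 120 s + ascent 30 s
  expect_equal(ds$dives$end_s - ds$dives$start_s, 180)
  expect_equal(max(ds$depth), 30)
  expect_identical(sum(ds$phase == "horizontal") / cfg$fs_hi, 120)

  # V-shaped dive: no horizontal ground truth at all
  vplan <- data.frame(surface_s = 30, descent_rate = 1, max_depth = 20,
                      bottom_s = 0, ascent_rate = 1)
  vds <- simulate_depth_profile(quick_cfg(1, duration_s = 200, dive_plan = vplan))
  expect_identical(sum(vds$phase == "horizontal"), 0L)

  # phase labels partition each dive: nothing inside a dive is unlabeled
  expect_true(all(ds$phase[!is.na(ds$dive_id)] %in%
                    c("descending", "horizontal", "ascending")))
  expect_true(all(ds$phase[is.na(ds$dive_id)] == "surface"))

  expect_error(simulate_depth_profile(
    quick_cfg(1, duration_s = 100, dive_plan = plan)), "duration_s")
  expect_error(sim_config(seed = 1, seafloor_m = 25, dive_plan = plan),
               "seafloor")
})

test_that("the generator is bit-deterministic in its seed", {
  a <- simulate_deployment(quick_cfg(77))
  b <- simulate_deployment(quick_cfg(77))
  expect_identical(a$record$acc, b$record$acc)
  expect_identical(a$record$depth, b$record$depth)
  expect_identical(a$truth$stroke_times, b$truth$stroke_times)
  c_ <- simulate_deployment(quick_cfg(78))
  expect_false(identical(a$record$acc, c_$record$acc))
})

test_that("gait synthesis matches its analytic description", {
  flat <- data.frame(surface_s = 0, descent_rate = 1, max_depth = 8,
                     bottom_s = 160, ascent_rate = 1)
  # continuous stroking at 0.25 Hz: 10 full strokes per 40 s
  cfg <- quick_cfg(5, duration_s = 200, dive_plan = flat, glide_fraction = 0,
                   noise_sd = 0)
  out <- simulate_deployment(cfg)
  tr <- out$truth$stroke_times
  expect_identical(sum(tr >= 40 & tr < 80), 10L)

  # noiseless peak dynamic heave equals the configured amplitude
  sim <- attr(out$record, "sim")
  expect_equal(max(abs(sim$dyn_z)), cfg$stroke_amp, tolerance = 1e-3)

  # permanent glide: zero strokes, dynamic heave identically zero
  cfg1 <- quick_cfg(5, duration_s = 200, dive_plan = flat, glide_fraction = 1,
                    noise_sd = 0)
  out1 <- simulate_deployment(cfg1)
  expect_identical(length(out1$truth$stroke_times), 0L)
  expect_equal(max(abs(attr(out1$record, "sim")$dyn_z)), 0)

  # ground-truth stroke count ~ frequency x active duration, +-1 per bout run
  cfg2 <- quick_cfg(13, duration_s = 600, dive_plan = flat[rep(1, 3), ])
  out2 <- simulate_deployment(cfg2)
  sim2 <- attr(out2$record, "sim")
  active_s <- sum(sim2$active) / cfg2$fs_hi
  expect_lt(abs(length(out2$truth$stroke_times) - 0.25 * active_s), 2)
})

test_that("nursing embedding scales the gait by role and validates placement", {
  pr <- sim_study_pair(31, n_dives = 3)
  calf <- pr$calf; mom <- pr$mother
  ev <- calf$truth$events
  expect_s3_class(ev, "event_log")
  expect_identical(nrow(ev), 2L)

  # unit multipliers leave the record untouched
  cfg <- attr(calf$record, "sim")$config
  cfg$calf_fsr_mult <- 1; cfg$calf_odba_mult <- 1
  ds <- simulate_depth_profile(cfg)
  base <- simulate_kinematics(ds, cfg)
  same <- embed_nursing(base, cfg)
  expect_identical(same$record$acc, base$acc)

  # a zeroed mother stroke multiplier silences strokes during nursing
  mcfg <- attr(mom$record, "sim")$config
  mcfg$mother_fsr_mult <- 0; mcfg$mother_odba_mult <- 0
  mds <- simulate_depth_profile(mcfg)
  m0 <- embed_nursing(simulate_kinematics(mds, mcfg), mcfg)
  for (i in seq_len(nrow(ev)))
    expect_identical(sum(m0$truth$stroke_times >= ev$start_s[i] &
                           m0$truth$stroke_times < ev$end_s[i]), 0L)

  # events must lie within dives
  bad <- attr(calf$record, "sim")$config
  bad$nursing_events <- data.frame(start_s = 1, duration_s = 10, phase = NA)
  bds <- simulate_depth_profile(bad)
  expect_error(embed_nursing(simulate_kinematics(bds, bad), bad),
               "outside all dives")
})
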