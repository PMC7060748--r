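trapezoid <- function(maxd = 30, bottom_s = 60, rate = 1, fs = 10,
                      surface_s = 20) {
  c(rep(0.3, surface_s * fs),
    seq(0.3, maxd, by = rate / fs),
    rep(maxd, bottom_s * fs),
    seq(maxd, 0.3, by = -rate / fs),
    rep(0.3, surface_s * fs))
}

test_that("dive detection finds threshold-crossing excursions of sufficient depth", {
  fs <- 10
  expect_identical(nrow(detect_dives(rep(0.4, 1000), fs)), 0L)
  # shallow wiggle below the minimum dive depth is not a dive
  shallow <- c(rep(0.3, 100), seq(0.3, 3, by = 0.1), seq(3, 0.3, by = -0.1),
               rep(0.3, 100))
  expect_identical(nrow(detect_dives(shallow, fs)), 0L)

  d <- trapezoid()
  dv <- detect_dives(d, fs)
  expect_identical(nrow(dv), 1L)
  expect_equal(dv$max_depth_m, 30)
  # crossings: depth passes 1 m at 0.7 s into the descent leg
  expect_equal(dv$start_s, 20 + 0.8, tolerance = 0.11)
  expect_equal(dv$end_s, 20 + 29.7 + 60 + 29, tolerance = 0.2)

  # simulator ground truth: as many dives detected as planned
  cfg <- quick_cfg(12, duration_s = 1300, dive_plan = default_dive_plan(4))
  out <- simulate_deployment(cfg)
  pr <- decimate_record(out$record, 10)
  expect_identical(nrow(detect_dives(pr$depth, 10, pr$t)), 4L)
})

test_that("phase classification matches the published three-phase rules", {
  fs <- 10
  # V-shaped dive (single-sample maximum): descending + ascending only
  v <- c(seq(1.2, 30, by = 0.1), seq(29.9, 1.2, by = -0.1))
  ph <- classify_phases(v, fs)
  expect_identical(ph$phase, c("descending", "ascending"))
  expect_equal(ph$end_s[1], length(seq(1.2, 30, by = 0.1)) / fs)

  # U-shaped dive with a 60 s flat bottom: all three phases, horizontal
  # within a few samples (ascent-commitment tolerance) of 60 s
  u <- trapezoid()[201:1100]
  phu <- classify_phases(u, fs)
  expect_identical(phu$phase, c("descending", "horizontal", "ascending"))
  hz <- phu[phu$phase == "horizontal", ]
  expect_lt(abs((hz$end_s - hz$start_s) - 60), 0.5)

  # a 12 m re-descent interrupts the ascent: everything through the
  # excursion is horizontal; ascending starts after it
  exc <- c(seq(1.2, 30, by = 0.1), rep(30, 100),
           seq(30, 15, by = -0.1), seq(15, 27, by = 0.1),
           seq(27, 1.2, by = -0.1))
  phe <- classify_phases(exc, fs)
  expect_identical(phe$phase, c("descending", "horizontal", "ascending"))
  asc_start <- phe$start_s[phe$phase == "ascending"]
  t_excursion_peak <- (length(seq(1.2, 30, by = 0.1)) + 100 +
                         length(seq(30, 15, by = -0.1)) +
                         length(seq(15, 27, by = 0.1)) - 1) / fs
  expect_equal(asc_start, t_excursion_peak, tolerance = 0.2)

  # an 8 m re-descent is tolerated inside the ascent: horizontal stays
  # confined to the 10 s flat bottom
  exc8 <- c(seq(1.2, 30, by = 0.1), rep(30, 100),
            seq(30, 15, by = -0.1), seq(15, 23, by = 0.1),
            seq(23, 1.2, by = -0.1))
  ph8 <- classify_phases(exc8, fs)
  hz8 <- ph8[ph8$phase == "horizontal", ]
  expect_lt(hz8$end_s - hz8$start_s, 12)

  expect_error(classify_phases(c(3, NA, 2), fs), "degenerate")
  expect_error(classify_phases(3, fs), "too short")
})

test_that("phase classification agrees with a sample-by-sample rule oracle", {
  set.seed(303)
  fs <- 10
  for (i in 1:40) {
    d <- random_dive(fs)
    t <- (seq_along(d) - 1) / fs
    ph <- classify_phases(d, fs, t)
    lab <- oracle_phases(d)
    got <- phase_of(structure(cbind(ph, dive = 1, max_depth_m = max(d)),
                              class = c("dive_phase_table", "data.frame")), t)
    expect_identical(got, lab)
    # partition: contiguous, ordered, covering the dive exactly
    expect_identical(ph$start_s[1], t[1])
    expect_equal(ph$end_s[nrow(ph)], t[length(t)] + 1 / fs)
    expect_true(all(ph$start_s[-1] == ph$end_s[-nrow(ph)]))
    # monotone guarantee inside the returned ascent
    asc <- d[t >= ph$start_s[nrow(ph)]]
    expect_true(all(asc - cummin(asc) <= 10 + 1e-9))
  }
})

test_that("phase lookup matches a linear-scan oracle and labels surface time", {
  cfg <- quick_cfg(14, duration_s = 1000, dive_plan = default_dive_plan(3))
  out <- simulate_deployment(cfg)
  pr <- decimate_record(out$record, 10)
  tab <- dive_phase_table(pr)
  expect_identical(phase_of(tab, tab$start_s[1] + 0.5), "descending")
  expect_identical(phase_of(tab, 1), "surface")
  set.seed(5)
  tt <- runif(10000, 0, 1000)
  got <- phase_of(tab, tt)
  ora <- vapply(tt, function(x) oracle_phase_of(tab, x), character(1))
  expect_identical(got, ora)
})
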