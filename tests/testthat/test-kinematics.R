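make_rec <- function(acc, fs = 400, depth = NULL, ...) {
  n <- nrow(acc)
  tag_record("kin-40", "calf", fs = fs, acc = acc,
             depth = if (is.null(depth)) rep(5, n) else depth, ...)
}

test_that("decimation preserves constants and in-band amplitudes", {
  n <- 400 * 60
  const <- make_rec(matrix(rep(c(10, 10, 10), each = n), ncol = 3))
  dec <- decimate_record(const, 10)
  expect_equal(dec$fs, 10)
  expect_identical(length(dec$t), as.integer(n %/% 40))
  expect_lt(max(abs(dec$acc - 10)), 1e-9)

  # a 0.2 Hz unit sine survives 400 -> 10 Hz within 1% amplitude
  t <- (seq_len(n) - 1) / 400
  s <- sin(2 * pi * 0.2 * t)
  rec <- make_rec(cbind(s, 0 * s, -9.81 + 0 * s))
  dec <- decimate_record(rec, 10)
  ref <- sin(2 * pi * 0.2 * dec$t)
  mid <- dec$t > 5 & dec$t < 55
  expect_lt(max(abs(dec$acc[mid, 1] - ref[mid])), 0.01)

  expect_error(decimate_record(make_rec(matrix(0, 100, 3), fs = 25), 10),
               "integer multiple")
})

test_that("whale-frame correction recovers the mounting rotation and is an isometry", {
  set.seed(20)
  n <- 2000
  level <- cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05), -9.81 + rnorm(n, 0, 0.05))
  rec <- make_rec(level, fs = 10)

  # already aligned: rotation ~ identity
  fixed <- correct_to_whale_frame(rec, c(0, 200))
  expect_lt(max(abs(attr(fixed, "rotation") - diag(3))), 1e-3)

  # tag pitched 30 degrees off the body axis
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  tilted <- make_rec(level %*% t(R), fs = 10)
  corr <- correct_to_whale_frame(tilted, c(0, 200))
  ang <- acos((sum(diag(attr(corr, "rotation"))) - 1) / 2)
  expect_lt(abs(ang - th), 0.5 * pi / 180)
  expect_equal(colMeans(corr$acc), c(x = 0, y = 0, z = -9.81), tolerance = 0.01)
  # isometry: per-sample norms preserved
  expect_lt(max(abs(sqrt(rowSums(corr$acc^2)) - sqrt(rowSums(tilted$acc^2)))),
            1e-9)

  # a window where mean specific force is far from g is rejected
  accel <- make_rec(cbind(0 * level[, 1], 0 * level[, 1], -5 + 0 * level[, 1]),
                    fs = 10)
  expect_error(correct_to_whale_frame(accel, c(0, 200)), "differs from gravity")
})

test_that("static/dynamic separation is exact and recovers in-band strokes", {
  n <- 10 * 120
  t <- (seq_len(n) - 1) / 10
  s <- 0.3 * sin(2 * pi * 0.25 * t)
  rec <- make_rec(cbind(1.5 + 0 * t, 0 * t, -9.6 + s), fs = 10)
  sd_ <- split_static_dynamic(rec, window_s = 8)  # two stroke periods
  expect_lt(max(abs(sd_$static + sd_$dynamic - rec$acc)), 1e-9)
  mid <- t > 10 & t < 110
  expect_lt(max(abs(sd_$dynamic[mid, 3] - s[mid])), 0.05 * 0.3)
  expect_lt(max(abs(sd_$dynamic[mid, 1])), 1e-9)

  const <- make_rec(matrix(rep(c(0, 0, -9.81), each = 50), ncol = 3), fs = 10)
  expect_equal(max(abs(split_static_dynamic(const, 5)$dynamic)), 0)
  expect_error(split_static_dynamic(const, 0.1), "at least 3 samples")
})

test_that("ODBA is the L1 norm of dynamic acceleration and bounds its L2 norm", {
  expect_identical(compute_odba(matrix(0, 5, 3)), rep(0, 5))
  expect_equal(compute_odba(matrix(c(0.1, 0.2, 0.3), 1)), 0.6)
  set.seed(4)
  dyn <- matrix(rnorm(300), ncol = 3)
  odba <- compute_odba(dyn)
  expect_true(all(odba >= sqrt(rowSums(dyn^2)) - 1e-12))
  expect_true(all(odba >= 0))
  expect_error(compute_odba(matrix(c(1, NA, 0), 1)), "finite")
})

test_that("orientation angles invert the gravity construction", {
  ori <- compute_orientation(matrix(c(0, 0, -9.81), 1))
  expect_equal(ori$pitch, 0)
  expect_equal(ori$roll, 0)

  up30 <- matrix(9.81 * c(sin(pi / 6), 0, -cos(pi / 6)), 1)
  ori30 <- compute_orientation(up30)
  expect_equal(ori30$pitch, 0.5236, tolerance = 1e-4)
  expect_equal(ori30$roll, 0)

  set.seed(2)
  p <- runif(1000, -pi / 2 + 0.01, pi / 2 - 0.01)
  r <- runif(1000, -pi + 0.01, pi)
  g <- 9.81
  static <- cbind(g * sin(p), g * cos(p) * sin(r), -g * cos(p) * cos(r))
  ori2 <- compute_orientation(static)
  expect_lt(max(abs(ori2$pitch - p)), 1e-6)
  expect_lt(max(abs(ori2$roll - r)), 1e-6)
  expect_false(any(ori2$undefined))

  weak <- compute_orientation(matrix(c(0.1, 0, -0.2), 1))
  expect_true(weak$undefined)
})

test_that("stroke detection counts full oscillations and ignores offsets and noise", {
  fs <- 10
  t <- (0:(40 * fs - 1)) / fs
  # start mid-stroke so all ten oscillations complete inside the series
  s <- 0.3 * sin(2 * pi * 0.25 * t + pi)
  st <- detect_fluke_strokes(s, fs)
  expect_identical(length(st), 10L)
  expect_equal(length(st) / 40, 0.25)

  # constant offsets do not shift detections
  st2 <- detect_fluke_strokes(s + 5, fs)
  expect_equal(st, st2)

  # sub-threshold noise yields nothing
  set.seed(9)
  expect_identical(length(detect_fluke_strokes(rnorm(400, 0, 0.01), fs)), 0L)

  expect_error(detect_fluke_strokes(s, fs, band = c(0.6, 0.1)), "band")
  expect_error(detect_fluke_strokes(s, fs, band = c(0.1, 6)), "band")
})

test_that("the processing chain recovers a configured segment mean ODBA", {
  # flat continuous-gait deployment whose heave amplitude targets a mean
  # ODBA of 0.25 m/s^2 (mean |A sin| = 2A/pi)
  target <- 0.25
  flat <- data.frame(surface_s = 0, descent_rate = 1, max_depth = 8,
                     bottom_s = 400, ascent_rate = 1)
  cfg <- quick_cfg(6, duration_s = 450, dive_plan = flat, glide_fraction = 0,
                   stroke_amp = pi * target / 2)
  out <- simulate_deployment(cfg)
  pr <- process_record(out$record, window_s = 8)
  mid <- pr$t > 60 & pr$t < 360
  expect_lt(abs(mean(pr$odba[mid]) - target) / target, 0.15)
})
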