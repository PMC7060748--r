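#' Decimate a tag record to a lower sampling rate
#'
#' Anti-alias low-pass filters every channel (zero-phase Butterworth with
#' cutoff at 80% of the target Nyquist) and subsamples. Raw-rate
#' accelerometer streams are decimated to a common 10 Hz analysis rate
#' before orientation, ODBA and stroke metrics are computed.
#'
#' @param record A [tag_record()].
#' @param target_fs Target rate in Hz; `record$fs` must be an integer
#'   multiple of it.
#' @return A [tag_record()] at `target_fs`.
#' @export
decimate_record <- function(record, target_fs = 10) {
  stopifnot(inherits(record, "tag_record"))
  r <- record$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("record fs must be an integer multiple of target_fs", call. = FALSE)
  r <- as.integer(round(r))
  if (r == 1L) return(record)
  idx <- seq(1L, length(record$t), by = r)
  dec1 <- function(x) antialias_lowpass(x, record$fs, target_fs)[idx]
  dec3 <- function(m) if (is.null(m)) NULL else apply(m, 2L, dec1)
  out <- record
  out$fs <- target_fs
  out$t <- record$t[idx]
  out$acc <- as_triaxial(dec3(record$acc), "acc")
  out$depth <- dec1(record$depth)
  out$speed <- if (is.null(record$speed)) NULL else dec1(record$speed)
  out$mag <- dec3(record$mag)
  out$gyro <- dec3(record$gyro)
  attr(out, "sim") <- attr(record, "sim")
  out
}

# Zero-phase Butterworth low-pass with reflective padding; the mean is
# removed before filtering so constant signals pass through exactly.
antialias_lowpass <- function(x, fs, target_fs) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  bf <- signal::butter(4L, 0.8 * target_fs / fs, type = "low")
  npad <- min(n - 1L, as.integer(round(2 * fs / target_fs * 10)))
  if (npad > 0L) {
    xp <- c(2 * xc[1L] - xc[(npad + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - npad)])
    y <- signal::filtfilt(bf, xp)[(npad + 1L):(npad + n)]
  } else {
    y <- signal::filtfilt(bf, xc)
  }
  y + mu
}

#' Rotate a tag record into the whale frame
#'
#' Suction-cup tags sit on the animal at an arbitrary orientation. Using a
#' calibration window in which the whale is assumed level and unaccelerated
#' (typically a quiet surface interval), a fixed rotation is estimated that
#' maps the window-mean specific force onto (0, 0, -g), and that rotation
#' is applied to all tri-axial channels.
#'
#' @param record A [tag_record()].
#' @param calib_window Numeric length-2 vector `c(start_s, end_s)`.
#' @param g Gravity, m/s^2.
#' @return The rotated [tag_record()], with the 3x3 rotation matrix
#'   attached as attribute `"rotation"`.
#' @export
correct_to_whale_frame <- function(record, calib_window, g = GRAVITY) {
  stopifnot(inherits(record, "tag_record"), length(calib_window) == 2L)
  sel <- record$t >= calib_window[1L] & record$t < calib_window[2L]
  if (sum(sel) < 2L) stop("calibration window contains no data", call. = FALSE)
  m <- colMeans(record$acc[sel, , drop = FALSE])
  nm <- sqrt(sum(m^2))
  if (abs(nm - g) > 0.2 * g)
    stop(sprintf(paste0("calibration window mean specific force (%.2f m/s^2) ",
                        "differs from gravity by more than 20%%"), nm),
         call. = FALSE)
  R <- rotation_between(m / nm, c(0, 0, -1))
  out <- record
  out$acc <- record$acc %*% t(R)
  colnames(out$acc) <- c("x", "y", "z")
  for (ch in c("mag", "gyro")) if (!is.null(record[[ch]])) {
    out[[ch]] <- record[[ch]] %*% t(R)
    colnames(out[[ch]]) <- c("x", "y", "z")
  }
  attr(out, "rotation") <- R
  attr(out, "sim") <- attr(record, "sim")
  out
}

# Rodrigues rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3L))
    # antiparallel: rotate half-turn about any axis orthogonal to a
    ax <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3L))
  }
  K <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + K + K %*% K * ((1 - c_) / s^2)
}

#' Split specific force into static and dynamic components
#'
#' The static (gravitational/postural) component is a centered running mean
#' of each axis over `window_s`; the dynamic component is the remainder, so
#' `static + dynamic == acc` exactly. The window should exceed twice the
#' dominant stroke period (default 5 s against a ~4 s humpback stroke).
#' Edges use shrinking (partial) windows.
#'
#' @param record A [tag_record()].
#' @param window_s Running-mean window in seconds.
#' @return A list with n x 3 matrices `static` and `dynamic`.
#' @export
split_static_dynamic <- function(record, window_s = 5) {
  stopifnot(inherits(record, "tag_record"))
  w <- round(window_s * record$fs)
  if (w < 3) stop("running-mean window must span at least 3 samples", call. = FALSE)
  half <- floor(w / 2)
  static <- apply(record$acc, 2L, runmean_partial, half = half)
  colnames(static) <- c("x", "y", "z")
  list(static = static, dynamic = record$acc - static)
}

# centered running mean with shrinking windows at the edges
runmean_partial <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Overall dynamic body acceleration
#'
#' ODBA is the sum of the absolute dynamic acceleration over the three
#' axes, a standard proxy for movement effort in accelerometry.
#'
#' @param dynamic_acc n x 3 matrix of dynamic acceleration, m/s^2.
#' @return Numeric vector, m/s^2, non-negative.
#' @export
compute_odba <- function(dynamic_acc) {
  dynamic_acc <- as_triaxial(dynamic_acc, "dynamic_acc")
  if (any(!is.finite(dynamic_acc)))
    stop("dynamic acceleration must be finite", call. = FALSE)
  rowSums(abs(dynamic_acc))
}

#' Pitch and roll from static acceleration
#'
#' With the whale-frame convention (x surge forward, y sway left, z heave
#' up; specific force (0, 0, -g) at rest), pitch is
#' `asin(x / |static|)` (nose-up positive) and roll is `atan2(y, -z)`.
#' Samples whose static magnitude is implausibly far from gravity are
#' flagged undefined.
#'
#' @param static_acc n x 3 static acceleration matrix.
#' @param g Gravity, m/s^2.
#' @return A list: `pitch` (radians, `[-pi/2, pi/2]`), `roll` (radians,
#'   `(-pi, pi]`), and logical `undefined`.
#' @export
compute_orientation <- function(static_acc, g = GRAVITY) {
  static_acc <- as_triaxial(static_acc, "static_acc")
  nrm <- sqrt(rowSums(static_acc^2))
  undefined <- nrm < 0.5 * g | nrm > 1.5 * g
  pitch <- unname(asin(pmax(-1, pmin(1, static_acc[, 1L] / pmax(nrm, 1e-12)))))
  roll <- unname(atan2(static_acc[, 2L], -static_acc[, 3L]))
  pitch[nrm < 1e-9] <- NA_real_
  roll[nrm < 1e-9] <- NA_real_
  list(pitch = pitch, roll = roll, undefined = undefined)
}

#' Detect fluke strokes by hysteresis zero crossing
#'
#' Band-pass filters the input (dorsoventral dynamic acceleration, or
#' pitch) to the fluking band and counts one stroke per full oscillation: a
#' stroke is registered at each positive-going zero crossing, provided the
#' signal dipped below `-amp_threshold` since the previous stroke
#' (hysteresis). This is robust to the amplitude modulation seen during
#' nursing, and sub-threshold noise produces no strokes. Crossing times are
#' linearly interpolated.
#'
#' @param series Numeric series at a uniform rate.
#' @param fs Sampling rate, Hz.
#' @param amp_threshold Hysteresis threshold in the units of `series`
#'   (default 0.05 m/s^2 for dynamic heave).
#' @param band Length-2 pass band in Hz, within `(0, fs/2)`; default
#'   0.1-0.6 Hz brackets humpback fluking.
#' @return Numeric vector of stroke times, seconds.
#' @export
detect_fluke_strokes <- function(series, fs, amp_threshold = 0.05,
                                 band = c(0.1, 0.6)) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
      band[2L] >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  n <- length(series)
  if (n < 8L) return(numeric(0))
  mu <- mean(series)
  bf <- signal::butter(2L, band / (fs / 2), type = "pass")
  npad <- min(n - 1L, as.integer(round(fs / band[1L])))
  xc <- series - mu
  xp <- c(2 * xc[1L] - xc[(npad + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - npad)])
  y <- signal::filtfilt(bf, xp)[(npad + 1L):(npad + n)]
  # full-oscillation state machine: arm below -thr, take the time of the
  # next positive-going zero crossing, confirm when the signal then
  # reaches +thr (a re-dip below -thr first cancels the candidate, so
  # sub-threshold wobbles during glides never count)
  armed <- FALSE
  pending <- NA_real_
  times <- numeric(0)
  for (i in seq_len(n - 1L)) {
    if (y[i] < -amp_threshold) {
      pending <- NA_real_
      armed <- TRUE
    } else if (!is.na(pending) && y[i] > amp_threshold) {
      times <- c(times, pending)
      pending <- NA_real_
    }
    if (armed && y[i] < 0 && y[i + 1L] >= 0) {
      frac <- -y[i] / (y[i + 1L] - y[i])
      pending <- (i - 1L + frac) / fs
      armed <- FALSE
    }
  }
  if (!is.na(pending) && y[n] > amp_threshold) times <- c(times, pending)
  times
}

#' Process a raw tag record into a 10 Hz analysis record
#'
#' Runs the standard chain: decimation to `target_fs`, optional whale-frame
#' correction, static/dynamic separation, ODBA, orientation angles and
#' fluke-stroke detection.
#'
#' @param record A raw [tag_record()].
#' @param target_fs Analysis rate, Hz.
#' @param calib_window Optional `c(start_s, end_s)` level calibration
#'   window passed to [correct_to_whale_frame()]; `NULL` skips frame
#'   correction (e.g. for simulator output already in the whale frame).
#' @param window_s Static/dynamic running-mean window, seconds.
#' @param amp_threshold,band Stroke-detection settings, see
#'   [detect_fluke_strokes()].
#' @param stroke_source Signal used for stroke detection: dorsoventral
#'   dynamic acceleration (`"heave"`, default) or `"pitch"`.
#' @return A `processed_record`: the decimated [tag_record()] plus
#'   `static_acc`, `dynamic_acc`, `odba`, `pitch`, `roll`,
#'   `orientation_undefined` and `stroke_times`.
#' @export
process_record <- function(record, target_fs = 10, calib_window = NULL,
                           window_s = 5, amp_threshold = 0.05,
                           band = c(0.1, 0.6),
                           stroke_source = c("heave", "pitch")) {
  stroke_source <- match.arg(stroke_source)
  rec <- decimate_record(record, target_fs)
  if (!is.null(calib_window)) rec <- correct_to_whale_frame(rec, calib_window)
  sd_ <- split_static_dynamic(rec, window_s)
  ori <- compute_orientation(sd_$static)
  series <- if (stroke_source == "heave") sd_$dynamic[, 3L] else ori$pitch
  thr <- if (stroke_source == "heave") amp_threshold else amp_threshold
  strokes <- detect_fluke_strokes(series, rec$fs, thr, band)
  rec$static_acc <- sd_$static
  rec$dynamic_acc <- sd_$dynamic
  rec$odba <- compute_odba(sd_$dynamic)
  rec$pitch <- ori$pitch
  rec$roll <- ori$roll
  rec$orientation_undefined <- ori$undefined
  rec$stroke_times <- strokes
  class(rec) <- c("processed_record", class(rec))
  rec
}

#' @export
print.processed_record <- function(x, ...) {
  NextMethod()
  cat(sprintf("  processed: odba, pitch/roll, %d fluke strokes\n",
              length(x$stroke_times)))
  invisible(x)
}
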