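#' Construct a tag record
#'
#' A tag record holds the uniformly sampled multichannel sensor streams of
#' one suction-cup tag deployment: tri-axial specific force, depth, and
#' optionally speed, magnetometer and gyroscope channels, all on a common
#' time base in seconds since tag-on.
#'
#' Axis convention: x is surge (+forward), y is sway (+left), z is heave
#' (+up). The accelerometer reports specific force in m/s^2, so a level,
#' unaccelerated animal reads approximately (0, 0, -9.81).
#'
#' @param deployment_id Character deployment identifier, e.g. "mn170613-40".
#' @param role Either "mother" or "calf".
#' @param fs Sampling rate in Hz.
#' @param acc n x 3 numeric matrix of specific force (surge, sway, heave),
#'   m/s^2.
#' @param depth Numeric vector of depth in meters, positive down. Small
#'   negative sensor offsets down to -0.5 m are tolerated.
#' @param speed Optional numeric vector of speed in m/s.
#' @param mag,gyro Optional n x 3 numeric matrices.
#' @param t Optional time vector (seconds since deployment start). Defaults
#'   to `(0:(n-1))/fs`; if supplied it must be uniform at step `1/fs`.
#' @param tag_on_time Optional wall-clock tag-on time, stored as metadata
#'   only (all analysis runs on the seconds-since-start time base).
#'
#' @return An object of class `tag_record`.
#' @export
tag_record <- function(deployment_id, role, fs, acc, depth,
                       speed = NULL, mag = NULL, gyro = NULL,
                       t = NULL, tag_on_time = NA_character_) {
  role <- match.arg(role, c("mother", "calf"))
  acc <- as_triaxial(acc, "acc")
  n <- nrow(acc)
  if (n < 1L) stop("tag record must contain at least one sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  depth <- as.numeric(depth)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  check_uniform_time(t, fs)
  if (length(t) != n || length(depth) != n)
    stop("all channels must have equal length", call. = FALSE)
  if (!all(is.finite(acc)))
    stop("acceleration must be finite", call. = FALSE)
  if (any(!is.finite(depth)) || any(depth < -0.5))
    stop("depth must be finite and >= -0.5 m", call. = FALSE)
  if (!is.null(speed)) {
    speed <- as.numeric(speed)
    if (length(speed) != n) stop("all channels must have equal length", call. = FALSE)
  }
  if (!is.null(mag)) { mag <- as_triaxial(mag, "mag"); if (nrow(mag) != n) stop("all channels must have equal length", call. = FALSE) }
  if (!is.null(gyro)) { gyro <- as_triaxial(gyro, "gyro"); if (nrow(gyro) != n) stop("all channels must have equal length", call. = FALSE) }
  structure(list(deployment_id = as.character(deployment_id), role = role,
                 fs = fs, t = t, acc = acc, depth = depth, speed = speed,
                 mag = mag, gyro = gyro, tag_on_time = tag_on_time),
            class = "tag_record")
}

as_triaxial <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop(sprintf("%s must have 3 columns (x, y, z)", what), call. = FALSE)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

check_uniform_time <- function(t, fs) {
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6 / fs)
      stop("timestamps must be strictly increasing with constant step 1/fs",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.tag_record <- function(x, ...) {
  cat(sprintf("<tag_record> %s (%s), fs = %g Hz, %d samples (%.1f s)\n",
              x$deployment_id, x$role, x$fs, length(x$t),
              length(x$t) / x$fs))
  opt <- c(speed = !is.null(x$speed), mag = !is.null(x$mag),
           gyro = !is.null(x$gyro))
  cat("  channels: acc, depth",
      if (any(opt)) paste0(", ", paste(names(opt)[opt], collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

record_duration <- function(record) length(record$t) / record$fs

#' Write a tag record to a delimited text file
#'
#' The format is plain tab-separated text with a commented header block of
#' `# key: value` lines (deployment_id, role, fs, units, tag-on time)
#' followed by one column per channel. It round-trips through
#' [read_tag_record()] with at least 9 significant digits.
#'
#' @param record A [tag_record()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tag_record <- function(record, path) {
  stopifnot(inherits(record, "tag_record"))
  if (length(record$t) == 0L)
    stop("refusing to write a record with zero-length channels", call. = FALSE)
  cols <- list(t = record$t,
               acc_x = record$acc[, 1L], acc_y = record$acc[, 2L],
               acc_z = record$acc[, 3L], depth = record$depth)
  if (!is.null(record$speed)) cols$speed <- record$speed
  for (ch in c("mag", "gyro")) if (!is.null(record[[ch]]))
    for (ax in c("x", "y", "z"))
      cols[[paste0(ch, "_", ax)]] <- record[[ch]][, ax]
  df <- data.table::setDT(cols)
  hdr <- c(sprintf("# deployment_id: %s", record$deployment_id),
           sprintf("# role: %s", record$role),
           sprintf("# fs: %.10g", record$fs),
           sprintf("# tag_on_time: %s", record$tag_on_time),
           "# units: t=s acc=m/s2 depth=m speed=m/s mag=uT gyro=deg/s")
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) NULL)
  if (is.null(con))
    stop(sprintf("cannot open '%s' for writing", path), call. = FALSE)
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a tag record from a delimited text file
#'
#' Reads files written by [write_tag_record()]: a commented `# key: value`
#' header declaring deployment metadata and the sampling rate, followed by
#' tab-separated channel columns. Optional channels absent from the file are
#' left absent (`NULL`), never zero-filled.
#'
#' @param path File path.
#' @return A validated [tag_record()].
#' @export
read_tag_record <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, n = 50L)
  hdr_n <- 0L
  meta <- list()
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    hdr_n <- hdr_n + 1L
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0)
      meta[[trimws(substr(kv, 1L, pos - 1L))]] <- trimws(substr(kv, pos + 1L, nchar(kv)))
  }
  for (key in c("deployment_id", "role", "fs"))
    if (is.null(meta[[key]]))
      stop(sprintf("malformed header: missing '%s'", key), call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (!is.finite(fs) || fs <= 0)
    stop("malformed header: fs is not a positive number", call. = FALSE)
  df <- data.table::fread(path, sep = "\t", skip = hdr_n, header = TRUE,
                          data.table = TRUE)
  need <- c("t", "acc_x", "acc_y", "acc_z", "depth")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed header: missing columns %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  for (cn in names(df)) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric value in column '%s' at data row %d", cn,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  grab3 <- function(prefix) {
    cols <- paste0(prefix, "_", c("x", "y", "z"))
    if (all(cols %in% names(df))) as.matrix(df[, cols, with = FALSE]) else NULL
  }
  tag_record(deployment_id = meta$deployment_id, role = meta$role, fs = fs,
             acc = grab3("acc"), depth = df$depth,
             speed = if ("speed" %in% names(df)) df$speed else NULL,
             mag = grab3("mag"), gyro = grab3("gyro"),
             t = df$t,
             tag_on_time = if (is.null(meta$tag_on_time)) NA_character_ else meta$tag_on_time)
}
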