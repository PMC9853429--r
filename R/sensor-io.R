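#' Read one lap's raw sensor files
#'
#' Loads and validates the IMU (low-g, high-g, gyro), plantar-pressure and
#' GPS/heart-rate files of a lap directory written by [generate_study()] (or
#' any export following the same dialect). Duplicate timestamps are dropped
#' with a warning; non-monotone timestamps are an error; sampling rates must
#' be within 1 % of nominal.
#'
#' @param dir Lap directory.
#' @param manifest_entry The lap's entry from the study manifest (carries the
#'   foot side, sensor specs, and file names).
#' @return List with `imu` (`imu_recording`), `pressure`
#'   (`pressure_recording`), `gps` (`gps_hr_recording`).
#' @export
read_lap <- function(dir, manifest_entry) {
  need <- c("imu_low.csv", "imu_high.csv", "gyro.csv", "pressure.csv",
            "track.gpx")
  paths <- file.path(dir, need)
  miss <- need[!file.exists(paths)]
  if (length(miss))
    stop("missing lap files in ", dir, ": ", paste(miss, collapse = ", "))

  sens <- manifest_entry$sensors
  low <- read_imu_csv(file.path(dir, "imu_low.csv"), c("ax", "ay", "az"),
                      sens$low_g$rate_hz)
  high <- read_imu_csv(file.path(dir, "imu_high.csv"), c("ax", "ay", "az"),
                       sens$high_g$rate_hz)
  gy <- read_imu_csv(file.path(dir, "gyro.csv"), c("gx", "gy", "gz"),
                     sens$gyro$rate_hz)
  if (nrow(gy$m) != nrow(low$m))
    stop("gyro and low-g accelerometer must share a time base")

  g <- if (!is.null(manifest_entry$gravity)) manifest_entry$gravity else 9.81
  imu <- structure(list(
    t_low = low$t, accel_low = low$m,
    t_high = high$t, accel_high = high$m,
    gyro = gy$m,
    rate_low = sens$low_g$rate_hz, rate_high = sens$high_g$rate_hz,
    axes = c(anterior = 1L, mediolateral = 2L, vertical = 3L),
    frontal_gyro_axis = 1L,
    side = manifest_entry$foot_side,
    range_low_g = sens$low_g$range_g,
    bits_low = sens$low_g$bits,
    gravity = g
  ), class = "imu_recording")
  eps <- 2 * imu$range_low_g * g / 2^imu$bits_low
  if (max(abs(imu$accel_low)) > imu$range_low_g * g + eps)
    stop("low-g samples exceed the +/-", imu$range_low_g, " g range")

  pr <- data.table::fread(file.path(dir, "pressure.csv"))
  pt <- pr[[1]]
  pm <- as.matrix(pr[, -1])
  pressure <- structure(list(
    t = pt, frames = pm,
    rows = sens$pressure$rows, cols = sens$pressure$cols,
    rate = sens$pressure$rate_hz,
    sensel_area_cm2 = sens$pressure$sensel_area_cm2
  ), class = "pressure_recording")
  if (ncol(pm) != sens$pressure$rows * sens$pressure$cols)
    stop("pressure grid shape mismatch")
  check_rate(pt, sens$pressure$rate_hz, "pressure")

  gps <- read_gpx(file.path(dir, "track.gpx"))

  list(imu = imu, pressure = pressure, gps = gps)
}

read_imu_csv <- function(path, cols, nominal_rate) {
  d <- data.table::fread(path)
  if (!all(c("t_unix", cols) %in% names(d)))
    stop("unexpected columns in ", basename(path))
  t <- d$t_unix
  if (anyDuplicated(t)) {
    keep <- !duplicated(t)
    warning(sum(!keep), " duplicated timestamp(s) removed from ",
            basename(path))
    d <- d[keep]; t <- t[keep]
  }
  if (any(diff(t) <= 0))
    stop("non-monotone timestamps in ", basename(path))
  check_rate(t, nominal_rate, basename(path))
  list(t = t, m = as.matrix(d[, cols, with = FALSE]))
}

check_rate <- function(t, nominal, what) {
  rate <- (length(t) - 1) / (t[length(t)] - t[1])  # jitter-robust mean interval
  if (abs(rate - nominal) > 0.01 * nominal)
    stop(sprintf("%s: sampling rate %.1f Hz deviates >1%% from nominal %s Hz",
                 what, rate, nominal))
  invisible(rate)
}

#' Fuse the dual-range accelerometer streams
#'
#' Interpolates the high-g stream linearly onto the low-g UNIX timestamps and
#' substitutes the interpolated high-g value wherever the low-g sample is
#' saturated, per sample and per axis. Saturation is `|low-g| >= range - LSB/2`
#' so rail-limited quantized codes are caught.
#'
#' @param rec An `imu_recording`.
#' @param saturation_threshold_g Saturation rail in g units.
#' @return A list of class `fused_accel`: `t` (low-g timestamps), `accel`
#'   (n x 3, m/s^2), `substituted` (n x 3 logical mask), plus the axis map
#'   carried over from `rec`.
#' @export
fuse_accelerometers <- function(rec, saturation_threshold_g = NULL) {
  if (is.null(saturation_threshold_g)) saturation_threshold_g <- rec$range_low_g
  g <- rec$gravity
  if (max(rec$t_high) < min(rec$t_low) || min(rec$t_high) > max(rec$t_low))
    stop("low-g and high-g streams do not overlap in time")
  lsb <- 2 * rec$range_low_g * g / 2^rec$bits_low
  thr <- saturation_threshold_g * g - lsb / 2
  mask <- abs(rec$accel_low) >= thr
  accel <- rec$accel_low
  if (any(mask)) {
    for (ax in 1:3) {
      idx <- which(mask[, ax])
      if (!length(idx)) next
      hi <- stats::approx(rec$t_high, rec$accel_high[, ax],
                          xout = rec$t_low[idx], rule = 2)$y
      accel[idx, ax] <- hi
    }
  }
  structure(list(
    t = rec$t_low, accel = accel, substituted = mask,
    axes = rec$axes, frontal_gyro_axis = rec$frontal_gyro_axis,
    side = rec$side, gravity = g
  ), class = "fused_accel")
}

#' Read / write a GPX 1.1 track with heart-rate extension
#'
#' @param path GPX file path.
#' @param gps A `gps_hr_recording`.
#' @return `read_gpx` returns a `gps_hr_recording` (`t` in seconds from the
#'   first point); `write_gpx` returns `path` invisibly.
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- xml2::xml_find_all(doc, ".//*[local-name()='trkpt']")
  if (!length(pts)) stop("no track points in ", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(pts, "./*[local-name()='ele']")))
  tim <- xml2::xml_text(
    xml2::xml_find_first(pts, "./*[local-name()='time']"))
  hr <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(pts, ".//*[local-name()='hr']")))
  tt <- as.numeric(as.POSIXct(tim, format = "%Y-%m-%dT%H:%M:%OSZ",
                              tz = "UTC"))
  if (any(!is.finite(tt))) stop("unparseable timestamps in ", path)
  if (any(hr < 30 | hr > 230, na.rm = TRUE))
    warning("heart-rate samples outside [30, 230] bpm")
  structure(list(
    t = tt - tt[1], t_unix = tt, lat = lat, lon = lon, ele = ele,
    heart_rate = hr
  ), class = "gps_hr_recording")
}

#' @rdname read_gpx
#' @export
write_gpx <- function(gps, path) {
  tstr <- format(as.POSIXct(gps$t_unix, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%OS2Z")
  pts <- sprintf(paste0(
    '    <trkpt lat="%.7f" lon="%.7f"><ele>%.1f</ele><time>%s</time>',
    '<extensions><gpxtpx:TrackPointExtension><gpxtpx:hr>%d</gpxtpx:hr>',
    '</gpxtpx:TrackPointExtension></extensions></trkpt>'),
    gps$lat, gps$lon, gps$ele, tstr, as.integer(round(gps$heart_rate)))
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<gpx version="1.1" creator="trailgait" ',
           'xmlns="http://www.topografix.com/GPX/1/1" ',
           'xmlns:gpxtpx="http://www.garmin.com/xmlschemas/TrackPointExtension/v1">'),
    '  <trk><name>lap</name><trkseg>', pts, '  </trkseg></trk>', '</gpx>')
  writeLines(xml, path)
  invisible(path)
}
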