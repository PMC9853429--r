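#' Trail course geometry and GPS-based section assignment
#'
#' A `trail_course` is the GPS-side description of the loop: ordered boundary
#' waypoints forming a closed triangle of three legs labelled uphill, top and
#' downhill, plus nominal lengths and mean slopes. Samples of a recorded track
#' are assigned to the leg they lie closest to, which partitions every lap
#' into the three sections used by the statistical models.
#'
#' @name course
NULL

# Local planar (equirectangular) projection helpers. Adequate at loop scale
# (<2 km): projection error is far below consumer-GPS noise.
EARTH_R <- 6371000

latlon_to_xy <- function(lat, lon, lat0, lon0) {
  x <- (lon - lon0) * pi / 180 * EARTH_R * cos(lat0 * pi / 180)
  y <- (lat - lat0) * pi / 180 * EARTH_R
  cbind(x = x, y = y)
}

xy_to_latlon <- function(x, y, lat0, lon0) {
  lat <- lat0 + (y / EARTH_R) * 180 / pi
  lon <- lon0 + (x / (EARTH_R * cos(lat0 * pi / 180))) * 180 / pi
  cbind(lat = lat, lon = lon)
}

#' Default trail course
#'
#' Constructs the packaged synthetic loop: a closed triangle with leg lengths
#' 580 m (uphill, +4 deg), 520 m (top, +2 deg) and 470 m (downhill, -6 deg),
#' anchored near Morrison, Colorado. Vertices are solved planimetrically from
#' the three leg lengths and converted to latitude/longitude.
#'
#' @param lap_scale Multiplier applied to the leg lengths.
#' @param lat0,lon0 Anchor coordinate of the course start.
#' @return A list of class `trail_course` with `waypoints` (data.frame of
#'   lat/lon vertices), `sections`, `lengths_m`, `slopes_deg`.
#' @export
default_course <- function(lap_scale = 1, lat0 = 39.6536, lon0 = -105.1932) {
  a <- 580 * lap_scale  # uphill  P0 -> P1
  b <- 520 * lap_scale  # top     P1 -> P2
  c <- 470 * lap_scale  # downhill P2 -> P0
  # interior angle at P1 between legs a and b
  ang1 <- acos((a^2 + b^2 - c^2) / (2 * a * b))
  p0 <- c(0, 0)
  p1 <- c(0, a)                       # uphill heads due north
  h2 <- pi - ang1                     # heading of top leg (from north, cw)
  p2 <- p1 + b * c(sin(h2), cos(h2))
  xy <- rbind(p0, p1, p2)
  ll <- xy_to_latlon(xy[, 1], xy[, 2], lat0, lon0)
  course <- list(
    waypoints = data.frame(lat = ll[, "lat"], lon = ll[, "lon"],
                           label = c("start", "uphill_end", "top_end"),
                           stringsAsFactors = FALSE),
    sections = c("uphill", "top", "downhill"),
    lengths_m = c(uphill = a, top = b, downhill = c),
    slopes_deg = c(uphill = 4, top = 2, downhill = -6)
  )
  class(course) <- "trail_course"
  course
}

#' Write / read a course definition YAML
#'
#' @param course A `trail_course`.
#' @param path File path of the YAML course definition.
#' @return `load_course` returns a `trail_course`; `write_course` the path,
#'   invisibly.
#' @export
write_course <- function(course, path) {
  obj <- list(
    waypoints = lapply(seq_len(nrow(course$waypoints)), function(i)
      as.list(course$waypoints[i, ])),
    sections = as.list(course$sections),
    lengths_m = as.list(course$lengths_m),
    slopes_deg = as.list(course$slopes_deg)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_course
#' @export
load_course <- function(path) {
  obj <- yaml::read_yaml(path)
  wp <- do.call(rbind, lapply(obj$waypoints, function(w)
    data.frame(lat = w$lat, lon = w$lon, label = w$label,
               stringsAsFactors = FALSE)))
  course <- list(
    waypoints = wp,
    sections = unlist(obj$sections),
    lengths_m = unlist(obj$lengths_m),
    slopes_deg = unlist(obj$slopes_deg)
  )
  class(course) <- "trail_course"
  course
}

# squared distance from points (n x 2) to segment p->q
point_segment_dist2 <- function(pts, p, q) {
  v <- q - p
  len2 <- sum(v^2)
  t <- ((pts[, 1] - p[1]) * v[1] + (pts[, 2] - p[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- pts[, 1] - (p[1] + t * v[1])
  dy <- pts[, 2] - (p[2] + t * v[2])
  dx^2 + dy^2
}

#' Assign GPS samples to trail sections
#'
#' Labels every track sample with the course section whose leg (segment
#' between consecutive boundary waypoints) it lies nearest to, then computes
#' per-section path lengths by summing haversine distances between
#' consecutive samples sharing a label.
#'
#' @param track A `gps_hr_recording` (see [read_gpx()]), or any list with
#'   numeric `lat`, `lon`.
#' @param course A `trail_course`.
#' @param max_start_dist_m Error if the track never comes within this distance
#'   of any course leg.
#' @return A list with `labels` (character per sample) and `path_lengths_m`
#'   (named numeric, one per section).
#' @export
assign_sections <- function(track, course, max_start_dist_m = 200) {
  stopifnot(length(track$lat) == length(track$lon))
  wp <- course$waypoints
  lat0 <- wp$lat[1]; lon0 <- wp$lon[1]
  vert <- latlon_to_xy(wp$lat, wp$lon, lat0, lon0)
  pts <- latlon_to_xy(track$lat, track$lon, lat0, lon0)
  nleg <- nrow(vert)
  d2 <- sapply(seq_len(nleg), function(i) {
    p <- vert[i, ]; q <- vert[if (i == nleg) 1 else i + 1, ]
    point_segment_dist2(pts, p, q)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  mind <- sqrt(apply(d2, 1, min))
  if (min(mind) > max_start_dist_m)
    stop("track never approaches a course boundary (min distance ",
         round(min(mind)), " m)")
  labels <- course$sections[apply(d2, 1, which.min)]
  lens <- vapply(course$sections, function(s) {
    idx <- which(labels == s)
    if (length(idx) < 2) return(0)
    # consecutive samples within the section
    runs <- idx[which(diff(idx) == 1)]
    if (!length(runs)) return(0)
    sum(geosphere::distHaversine(
      cbind(track$lon[runs], track$lat[runs]),
      cbind(track$lon[runs + 1], track$lat[runs + 1]), r = EARTH_R))
  }, numeric(1))
  empty <- course$sections[!(course$sections %in% labels)]
  if (length(empty))
    warning("sections with no GPS samples: ", paste(empty, collapse = ", "))
  list(labels = labels, path_lengths_m = lens)
}

#' Mean heart rate per section
#'
#' @param track A `gps_hr_recording` with a `heart_rate` field.
#' @param labels Per-sample section labels from [assign_sections()].
#' @return Named numeric: arithmetic mean heart rate per section (NA for an
#'   empty section).
#' @export
section_heart_rate <- function(track, labels) {
  secs <- unique(c("uphill", "top", "downhill", labels))
  out <- vapply(secs, function(s) {
    hr <- track$heart_rate[labels == s]
    if (!length(hr)) NA_real_ else mean(hr)
  }, numeric(1))
  out[c("uphill", "top", "downhill")]
}

#' Lap-time quality control
#'
#' A subject is excluded when the range of their condition-lap durations
#' exceeds 60 s (strictly greater than); a range of exactly 60 s is retained.
#'
#' @param lap_durations_s Numeric vector of one subject's lap durations in
#'   seconds (>= 2 laps).
#' @param max_range_s Exclusion threshold in seconds.
#' @return Logical: `TRUE` to retain the subject, `FALSE` to exclude.
#' @export
lap_qc <- function(lap_durations_s, max_range_s = 60) {
  if (any(is.na(lap_durations_s)))
    stop("missing lap durations")
  if (length(lap_durations_s) < 2)
    stop("lap QC needs at least two laps")
  diff(range(lap_durations_s)) <= max_range_s
}

#' Align the IMU and GPS time lines
#'
#' The GPS watch is started right after the third synchronization hop, so
#' GPS time zero maps onto the IMU `run_start` sample. Each stride or step
#' then inherits the section label of the GPS sample covering its
#' foot-contact time.
#'
#' @param contact_times_s Foot-contact times (seconds, on the recording
#'   clock) of strides or steps.
#' @param run_start_time_s Recording-clock time of the detected run start.
#' @param track A `gps_hr_recording` whose `t` starts at 0 at run start.
#' @param labels Section labels per GPS sample.
#' @return Character vector of section labels (NA where no GPS sample covers
#'   the contact).
#' @export
align_streams <- function(contact_times_s, run_start_time_s, track, labels) {
  if (!length(track$t) || !length(labels))
    return(rep(NA_character_, length(contact_times_s)))
  rel <- contact_times_s - run_start_time_s
  if (length(track$t) > 1 && max(rel, -Inf) > max(track$t) + 5)
    warning("contacts extend beyond the GPS track")
  idx <- findInterval(rel, track$t)
  out <- rep(NA_character_, length(rel))
  ok <- idx >= 1 & idx <= length(labels)
  out[ok] <- labels[idx[ok]]
  out
}
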