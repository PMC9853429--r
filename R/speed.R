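#' Per-stride running speed by ZUPT double integration
#'
#' Running speed is stride length divided by stride time. Stride length is
#' obtained by rotating the fused acceleration into a gravity-aligned world
#' frame, double-integrating it between consecutive midstance instants, and
#' removing integration drift with a linear de-drift anchored on zero
#' velocity at both midstances (the foot is quasi-static at foot-flat).
#'
#' @name speed
NULL

# Midstance sample of each stride: minimum of the (smoothed) gyro magnitude
# within the central 25-75 % of the contact-to-contact interval. The
# accelerometer's deviation from gravity is added as a secondary quiescence
# term so the anchor stays in the foot-flat window even when the gyro is
# degenerate (near-zero throughout the stride).
find_midstances <- function(strides, gyro_dps, accel = NULL,
                            gravity = 9.81, smooth_n = 11L) {
  score <- sqrt(rowSums(gyro_dps^2))
  if (!is.null(accel))
    score <- score + abs(sqrt(rowSums(accel^2)) - gravity)
  kern <- rep(1 / smooth_n, smooth_n)
  score <- as.numeric(stats::filter(score, kern, sides = 2))
  score[is.na(score)] <- Inf
  vapply(seq_len(nrow(strides)), function(i) {
    a <- strides$start[i]; b <- strides$end[i]
    lo <- as.integer(a + floor(0.25 * (b - a)))
    hi <- as.integer(a + floor(0.75 * (b - a)))
    lo + which.min(score[lo:hi]) - 1L
  }, integer(1))
}

#' Rotate a stride's fused acceleration into the world frame
#'
#' Orientation is initialized at a quasi-static anchor sample from the
#' accelerometer gravity direction (minimal rotation taking the measured
#' gravity onto world vertical), propagated across the window by gyroscope
#' integration, and gravity is subtracted in the aligned frame.
#'
#' @param accel n x 3 fused acceleration (m/s^2, body frame).
#' @param gyro_dps n x 3 gyroscope (deg/s), same time base.
#' @param anchor Sample index (within the window) of the quasi-static
#'   initialization instant.
#' @param rate_hz Sampling rate.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param init_halfwin_s Half-width of the averaging window for the gravity
#'   direction at the anchor.
#' @return n x 3 matrix of world-frame linear acceleration (gravity
#'   removed); attribute `"tilt_deg"` carries the initial tilt.
#' @export
world_frame_acceleration <- function(accel, gyro_dps, anchor, rate_hz,
                                     gravity = 9.81,
                                     init_halfwin_s = 0.01) {
  n <- nrow(accel)
  if (anchor < 1 || anchor > n) stop("anchor outside the window")
  hw <- max(1L, round(init_halfwin_s * rate_hz))
  sel <- max(1L, anchor - hw):min(n, anchor + hw)
  ghat <- colMeans(accel[sel, , drop = FALSE])
  nrm <- sqrt(sum(ghat^2))
  if (nrm < 1e-6) stop("no usable gravity vector at the anchor")
  ghat <- ghat / nrm
  R0 <- rotation_between(ghat, c(0, 0, 1))

  gy <- gyro_dps * pi / 180
  # propagate backward and forward from the anchor
  fwd <- rotate_to_world(gy[anchor:n, , drop = FALSE],
                         accel[anchor:n, , drop = FALSE], 1 / rate_hz, R0)
  out <- matrix(0, n, 3)
  out[anchor:n, ] <- fwd
  if (anchor > 1) {
    idx <- anchor:1
    bwd <- rotate_to_world(-gy[idx, , drop = FALSE],
                           accel[idx, , drop = FALSE], 1 / rate_hz, R0)
    out[idx, ] <- bwd
  }
  out[, 3] <- out[, 3] - gravity
  attr(out, "tilt_deg") <- acos(min(1, max(-1, ghat[3]))) * 180 / pi
  out
}

# minimal rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) return(diag(c(1, -1, -1)))  # antipodal: flip
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Speed of one stride from world-frame acceleration
#'
#' Integrates world acceleration over a midstance-to-midstance window,
#' subtracts the linear velocity ramp that makes velocity exactly zero at
#' both zero-velocity-update anchors, integrates the corrected velocity to
#' displacement, and reports the horizontal displacement norm divided by the
#' contact-to-contact stride time.
#'
#' @param world_accel m x 3 world-frame linear acceleration spanning
#'   midstance to midstance (first and last rows are the ZUPT anchors).
#' @param stride_time_s Contact-to-contact stride time, seconds.
#' @param rate_hz Sampling rate.
#' @return List: `speed` (m/s), `stride_length` (m), `stride_time` (s),
#'   `drift_correction` (m/s, norm of the removed terminal velocity).
#' @export
stride_speed <- function(world_accel, stride_time_s, rate_hz) {
  m <- nrow(world_accel)
  if (m < 4) stop("window too short for integration")
  dt <- 1 / rate_hz
  v <- apply(world_accel, 2, cumtrapz, dt = dt)
  ramp <- (seq_len(m) - 1) / (m - 1)
  vc <- v - outer(ramp, v[m, ])
  disp <- apply(vc, 2, trapz, dt = dt)
  len <- sqrt(disp[1]^2 + disp[2]^2)
  list(speed = len / stride_time_s, stride_length = len,
       stride_time = stride_time_s,
       drift_correction = sqrt(sum(v[m, ]^2)))
}

# Per-stride speeds for a whole lap: strides from segment_strides(), fused
# 50 Hz-filtered accel + gyro. The last stride has no following midstance
# anchor and gets NA.
lap_stride_speeds <- function(strides, fused50, gyro50_dps, rate_hz,
                              gravity = 9.81) {
  ns <- nrow(strides)
  out <- data.frame(speed = rep(NA_real_, ns),
                    stride_length = NA_real_,
                    drift_correction = NA_real_)
  if (ns < 2) return(out)
  mids <- find_midstances(strides, gyro50_dps, fused50, gravity)
  for (i in seq_len(ns - 1L)) {
    a <- mids[i]; b <- mids[i + 1L]
    if (b - a < 4) next
    win <- a:b
    wa <- world_frame_acceleration(fused50[win, , drop = FALSE],
                                   gyro50_dps[win, , drop = FALSE],
                                   1L, rate_hz, gravity)
    ss <- stride_speed(wa, strides$stride_time[i], rate_hz)
    out$speed[i] <- ss$speed
    out$stride_length[i] <- ss$stride_length
    out$drift_correction[i] <- ss$drift_correction
  }
  out
}
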