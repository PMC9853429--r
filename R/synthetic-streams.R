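#' Synthesize raw sensor streams from ground truth
#'
#' Renders one lap of ground-truth kinematics into the raw signals the
#' pipeline consumes: dual-range accelerometer and gyroscope streams on their
#' own UNIX-timestamp grids, plantar-pressure frames, and a GPS/heart-rate
#' track.
#'
#' The per-stride template is built so that the assumptions the pipeline
#' exploits hold by construction:
#' * the foot is stationary (zero velocity, zero rotation) in a foot-flat
#'   window between contact and swing, providing the zero-velocity-update
#'   anchor;
#' * the swing-phase anterior velocity is a raised-cosine-squared bump whose
#'   integral equals the true stride length exactly;
#' * the frontal-plane gyroscope carries a biphasic eversion/inversion pulse
#'   peaking at the true eversion velocity inside the first 20 % of the
#'   stride (amplitude pre-compensated for the 30 Hz measurement filter);
#' * the landing impact is a raised-cosine transient on the vertical axis
#'   whose amplitude and width are solved so the 50 Hz-filtered peak
#'   acceleration norm and peak jerk norm match the drawn truth;
#' * emitted accelerometer samples are the world-frame specific force rotated
#'   through the orientation implied by the emitted gyroscope (single-axis,
#'   time-disjoint roll and pitch rotations, so the rotation is closed-form).
#'
#' The low-g stream is clipped at +/-16 g and quantized to 16 bits; the
#' high-g stream is quantized to 13 bits over +/-200 g and never clipped.
#'
#' @param truth A `ground_truth` from [generate_subject_kinematics()].
#' @param lap Lap number within `truth`.
#' @param config The [study_config()] used to generate `truth`.
#' @param course Optional `trail_course`; defaults to the configured
#'   geometry.
#' @param t_unix0 UNIX time of the recording start.
#' @param self_check If `TRUE`, double-integrate the emitted noise-free
#'   template for a mid-lap stride and error if the displacement misses the
#'   true stride length by more than 1 %.
#' @return List with elements `imu` (`imu_recording`), `pressure`
#'   (`pressure_recording`), and `gps` (`gps_hr_recording`).
#' @export
synthesize_sensor_streams <- function(truth, lap, config, course = NULL,
                                      t_unix0 = NULL, self_check = FALSE) {
  lt <- truth$laps[[lap]]
  if (is.null(course)) course <- default_course(config$lap_scale)
  if (is.null(t_unix0))
    t_unix0 <- 1665000000 + truth$subject_id * 86400 + lap * 3600
  set.seed(lt$seed)
  g <- config$gravity
  wf <- config$waveform
  side_sign <- if (truth$foot_side == "right") -1 else 1

  st <- lt$strides
  n_str <- nrow(st)
  rate_lo <- config$sensors$low_g$rate_hz
  rate_hi <- config$sensors$high_g$rate_hz
  dur <- lt$duration_s

  # ---- per-stride template parameters -------------------------------------
  prm <- stride_template_params(st, config)

  t_lo <- seq(0, dur, by = 1 / rate_lo)
  t_hi <- seq(0, dur, by = 1 / rate_hi)

  tmpl_lo <- eval_imu_template(t_lo, st, prm, lt, config, side_sign)
  tmpl_hi <- eval_imu_template(t_hi, st, prm, lt, config, side_sign)

  if (self_check) {
    k <- max(1L, n_str %/% 2L)
    tk <- st$t_start[k]; Tk <- st$stride_time[k]
    idx <- which(t_lo >= tk + 0.25 * Tk & t_lo <= tk + Tk + 0.25 * Tk)
    ax <- tmpl_lo$a_world[idx, 1]
    v <- cumtrapz(ax, 1 / rate_lo)
    d <- trapz(v, 1 / rate_lo)
    if (abs(d - st$stride_length[k]) > 0.01 * st$stride_length[k] + 1e-6)
      stop(sprintf(
        "generator self-check: template displacement %.3f m vs truth %.3f m",
        d, st$stride_length[k]))
  }

  nz_lo <- matrix(rnorm(length(t_lo) * 3, 0, wf$accel_noise_sd), ncol = 3)
  nz_hi <- matrix(rnorm(length(t_hi) * 3, 0, wf$accel_noise_sd), ncol = 3)
  f_lo <- tmpl_lo$f + nz_lo
  f_hi <- tmpl_hi$f + nz_hi

  lsb_lo <- 2 * config$sensors$low_g$range_g * g / 2^config$sensors$low_g$bits
  lsb_hi <- 2 * config$sensors$high_g$range_g * g / 2^config$sensors$high_g$bits
  clip_lo <- config$sensors$low_g$range_g * g
  accel_low <- round(pmin(pmax(f_lo, -clip_lo), clip_lo) / lsb_lo) * lsb_lo
  accel_high <- round(f_hi / lsb_hi) * lsb_hi

  gy_noise <- cbind(rnorm(length(t_lo), 0, wf$gyro_noise_sd),
                    rnorm(length(t_lo), 0, wf$gyro_cross_noise_sd),
                    rnorm(length(t_lo), 0, wf$gyro_cross_noise_sd))
  lsb_gy <- 2 * config$sensors$gyro$range_dps / 2^config$sensors$gyro$bits
  gyro <- round((tmpl_lo$gyro + gy_noise) / lsb_gy) * lsb_gy

  imu <- structure(list(
    t_low = t_unix0 + t_lo, accel_low = accel_low,
    t_high = t_unix0 + t_hi, accel_high = accel_high,
    gyro = gyro,
    rate_low = rate_lo, rate_high = rate_hi,
    axes = c(anterior = 1L, mediolateral = 2L, vertical = 3L),
    frontal_gyro_axis = 1L,
    side = truth$foot_side,
    range_low_g = config$sensors$low_g$range_g,
    bits_low = config$sensors$low_g$bits,
    gravity = g
  ), class = "imu_recording")

  pressure <- synthesize_pressure(lt, config, t_unix0)
  gps <- synthesize_gps(lt, config, course, t_unix0)

  list(imu = imu, pressure = pressure, gps = gps)
}

# Solve per-stride waveform parameters, including the impact shape
# (raised-cosine width, ringing amplitude, overall scale) against the 50 Hz
# measurement filter and the eversion-pulse amplitude against the 30 Hz
# filter.
stride_template_params <- function(st, config) {
  g <- config$gravity
  wf <- config$waveform
  rate <- config$sensors$low_g$rate_hz
  resp <- impact_filter_response(rate, 50)
  ratio_req <- st$peak_jerk / pmax(st$peak_acc - g, 1)
  # filtered jerk/acc ratio is monotone along the shape family; clamp at the
  # family edges
  d_imp <- stats::approx(resp$ratio, resp$d, xout = ratio_req, rule = 2)$y
  r_imp <- stats::approx(resp$ratio, resp$r, xout = ratio_req, rule = 2)$y
  alpha <- stats::approx(resp$ratio, resp$alpha, xout = ratio_req, rule = 2)$y
  A_imp <- pmax(st$peak_acc - g, 0.5) / alpha

  w_ev <- wf$ev_halfwidth_frac * st$stride_time
  ev_att <- eversion_filter_attenuation(stats::median(w_ev), rate, 30)
  P_ev <- st$eversion_vel / ev_att

  D <- (wf$swing_end_frac - wf$swing_start_frac) * st$stride_time
  list(A_imp = A_imp, d_imp = d_imp, r_imp = r_imp, P_ev = P_ev, w_ev = w_ev,
       B_ml = st$ml_range / ml_shape_range(), D = D,
       V = 2 * st$stride_length / D)
}

# ML acceleration shape: second derivative of the compactly supported
# displacement profile h(u) = sin(2*pi*u) * sin^2(pi*u), u in [0, 1].
# h and h' vanish at both ends, so the ML channel contributes exactly zero
# net velocity and displacement over the swing and is continuous at the
# swing boundaries (no spurious jerk step).
ml_shape <- function(u) {
  -2 * pi^2 * sin(2 * pi * u) + 4 * pi^2 * sin(4 * pi * u)
}

ml_shape_range <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      g <- ml_shape(seq(0, 1, length.out = 4001))
      val <<- max(g) - min(g)
    }
    val
  }
})

# Impact shape: raised-cosine bump of full width d plus an r-scaled ringing
# rider (45 Hz sine under a raised-cosine envelope). Landing transients of
# running feet carry near-cutoff oscillatory content; the rider reproduces
# the jerk/acceleration ratios seen through a 50 Hz filter, which a smooth
# bump alone cannot reach.
RIDER_HZ <- 45
RIDER_LEN_S <- 0.044

impact_shape <- function(tau, d, r) {
  bump <- ifelse(tau >= 0 & tau < d, 0.5 * (1 - cos(2 * pi * tau / d)), 0)
  env <- ifelse(tau >= 0 & tau < RIDER_LEN_S,
                0.5 * (1 - cos(2 * pi * tau / RIDER_LEN_S)), 0)
  bump + r * sin(2 * pi * RIDER_HZ * tau) * env
}

# raised-cosine bump of unit amplitude, half-width w, centered at c
cosbump <- function(tau, c, w) {
  ifelse(abs(tau - c) < w, 0.5 * (1 + cos(pi * (tau - c) / w)), 0)
}

# integral of cosbump from (c - w) to tau, clamped to the support
cosbump_int <- function(tau, c, w) {
  x <- pmin(pmax(tau, c - w), c + w)
  0.5 * ((x - c + w) + (w / pi) * sin(pi * (x - c) / w))
}

# Filtered peak acceleration (alpha) and peak jerk (beta) of the unit
# impact-shape family through the two-pass 50 Hz filter. The family spans
# low jerk/acc ratios with wide smooth bumps (r = 0) and high ratios with a
# 20 ms bump plus increasing ringing amplitude.
impact_filter_response <- local({
  cache <- new.env(parent = emptyenv())
  function(rate, cutoff) {
    key <- paste0(rate, "_", cutoff)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fam <- rbind(
      data.frame(d = seq(0.060, 0.020, by = -0.004), r = 0),
      data.frame(d = 0.020, r = seq(0.2, 4.0, by = 0.2)))
    pad <- round(0.25 * rate)
    tau <- seq(0, 0.12, by = 1 / rate)
    out <- lapply(seq_len(nrow(fam)), function(i) {
      x <- c(rep(0, pad), impact_shape(tau, fam$d[i], fam$r[i]), rep(0, pad))
      y <- zero_phase_lowpass(x, cutoff, rate)
      jerk <- central_diff(y) * rate
      c(alpha = max(y), beta = max(abs(jerk)))
    })
    m <- do.call(rbind, out)
    res <- data.frame(d = fam$d, r = fam$r, alpha = m[, "alpha"],
                      beta = m[, "beta"], ratio = m[, "beta"] / m[, "alpha"])
    res <- res[order(res$ratio), ]
    # keep a strictly increasing ratio path for interpolation
    keep <- !duplicated(round(res$ratio, 6))
    res <- res[keep, ]
    cache[[key]] <- res
    res
  }
})

# Peak attenuation of the biphasic eversion pulse through the 30 Hz filter.
eversion_filter_attenuation <- local({
  cache <- new.env(parent = emptyenv())
  function(w, rate, cutoff) {
    key <- paste0(round(w * 1e4), "_", rate, "_", cutoff)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pad <- round(0.3 * rate)
    tau <- seq(0, 6 * w, by = 1 / rate)
    x <- cosbump(tau, 1.6 * w, w) - cosbump(tau, 4.6 * w, w)
    y <- zero_phase_lowpass(c(rep(0, pad), x, rep(0, pad)), cutoff, rate)
    att <- max(y)
    cache[[key]] <- att
    att
  }
})

# Evaluate the deterministic IMU template at arbitrary times.
# Returns the emitted specific force f (sensor frame), the gyro (deg/s) and
# the world-frame linear acceleration (for self-checks/oracles).
eval_imu_template <- function(t, st, prm, lt, config, side_sign) {
  g <- config$gravity
  wf <- config$waveform
  n <- length(t)
  a_w <- matrix(0, n, 3)
  gyro <- matrix(0, n, 3)
  roll <- numeric(n)
  pitch <- numeric(n)

  # synchronization hops: world-vertical raised-cosine bursts
  for (h in lt$hop_times_s)
    a_w[, 3] <- a_w[, 3] + wf$hop_amp_ms2 * cosbump(t, h, wf$hop_halfwidth_s)

  bounds <- c(st$t_start, st$t_start[nrow(st)] + st$stride_time[nrow(st)])
  idx_stride <- findInterval(t, bounds)

  for (k in seq_len(nrow(st))) {
    sel <- which(idx_stride == k)
    if (!length(sel)) next
    tau <- t[sel] - st$t_start[k]
    Tk <- st$stride_time[k]

    # landing impact (world vertical)
    a_w[sel, 3] <- a_w[sel, 3] +
      prm$A_imp[k] * impact_shape(tau, prm$d_imp[k], prm$r_imp[k])

    # frontal-plane eversion pulse (deg/s) and roll angle (rad)
    c1 <- wf$ev_center1_frac * Tk; c2 <- wf$ev_center2_frac * Tk
    w <- prm$w_ev[k]
    ev <- prm$P_ev[k] * (cosbump(tau, c1, w) - cosbump(tau, c2, w))
    gyro[sel, 1] <- side_sign * ev
    roll[sel] <- side_sign * (pi / 180) * prm$P_ev[k] *
      (cosbump_int(tau, c1, w) - cosbump_int(tau, c2, w))

    # swing: anterior translation, ML oscillation, sagittal pitch
    s0 <- wf$swing_start_frac * Tk
    D <- prm$D[k]
    taus <- tau - s0
    insw <- taus >= 0 & taus <= D
    ph <- 2 * pi * taus / D
    a_w[sel, 1] <- ifelse(insw, prm$V[k] * (pi / D) * sin(ph), 0)
    a_w[sel, 2] <- ifelse(insw, prm$B_ml[k] * ml_shape(taus / D), 0)
    gyro[sel, 2] <- ifelse(insw, wf$pitch_amp_dps * sin(ph), 0)
    pitch[sel] <- ifelse(insw,
      (pi / 180) * wf$pitch_amp_dps * (D / (2 * pi)) * (1 - cos(ph)), 0)
  }

  # final landing impact at the end of the last stride
  k <- nrow(st)
  t_end <- st$t_start[k] + st$stride_time[k]
  a_w[, 3] <- a_w[, 3] + prm$A_imp[k] *
    impact_shape(t - t_end, prm$d_imp[k], prm$r_imp[k])

  # sensor-frame specific force: f = Ry(pitch)^T Rx(roll)^T (a_w + g e_z);
  # roll and pitch windows are time-disjoint, so the order is immaterial.
  u1 <- a_w[, 1]; u2 <- a_w[, 2]; u3 <- a_w[, 3] + g
  cr <- cos(roll); sr <- sin(roll)
  f2 <- cr * u2 + sr * u3
  f3 <- -sr * u2 + cr * u3
  cp <- cos(pitch); sp <- sin(pitch)
  f1 <- cp * u1 - sp * f3
  f3 <- sp * u1 + cp * f3

  list(f = cbind(f1, f2, f3), gyro = gyro, a_world = a_w)
}

# ---- plantar pressure ------------------------------------------------------

synthesize_pressure <- function(lt, config, t_unix0) {
  ps <- config$sensors$pressure
  wf <- config$waveform
  rate <- ps$rate_hz
  rows <- ps$rows; cols <- ps$cols
  ns <- rows * cols
  nt <- floor(lt$duration_s * rate) + 1L
  tt <- (seq_len(nt) - 1L) / rate
  frames <- matrix(0, nt, ns)

  nh <- ceiling(0.2 * rows)
  heel_idx <- which(rep(seq_len(rows), each = cols) > rows - nh)
  toe_idx <- which(rep(seq_len(rows), each = cols) <= nh)
  mid_idx <- setdiff(seq_len(ns), c(heel_idx, toe_idx))

  # synchronization hop spikes (gated out downstream by run_start)
  for (h in lt$hop_times_s) {
    fi <- which(abs(tt - h) <= 0.05)
    if (length(fi)) frames[fi, mid_idx] <- 150
  }

  st <- lt$strides
  base <- wf$pressure_base_kpa
  for (k in seq_len(nrow(st))) {
    f0 <- floor(st$t_start[k] * rate) + 1L
    f1 <- floor((st$t_start[k] + wf$stance_frac * st$stride_time[k]) * rate)
    if (f1 < f0 || f0 > nt) next
    f1 <- min(f1, nt)
    fr <- f0:f1
    prog <- seq(0.1, 0.9, length.out = length(fr))
    shape <- sin(pi * prog)

    n_heel_on <- round(st$heel_area[k] / 100 * length(heel_idx))
    n_toe_on <- round(st$toe_area[k] / 100 * length(toe_idx))
    heel_on <- if (n_heel_on > 0) sample(heel_idx, n_heel_on) else integer(0)
    toe_on <- if (n_toe_on > 0) sample(toe_idx, n_toe_on) else integer(0)
    mid_on <- sample(mid_idx, round(wf$mid_force_frac * length(mid_idx)))

    if (length(heel_on)) {
      wgt <- c(1, runif(length(heel_on) - 1L, 0.3, 0.8))
      frames[fr, heel_on] <- pmax(base, outer(shape, wgt) * st$heel_peak[k])
    }
    if (length(toe_on)) {
      wgt <- c(1, runif(length(toe_on) - 1L, 0.3, 0.8))
      frames[fr, toe_on] <- pmax(base, outer(shape, wgt) * st$toe_peak[k])
    }
    frames[fr, mid_on] <- pmax(base, shape * 80)
  }

  frames <- frames + matrix(rnorm(length(frames), 0, wf$pressure_frame_noise_kpa),
                            nrow = nt)
  frames[frames < 0] <- 0

  structure(list(
    t = t_unix0 + tt, frames = frames, rows = rows, cols = cols,
    rate = rate, sensel_area_cm2 = ps$sensel_area_cm2
  ), class = "pressure_recording")
}

# ---- GPS + heart rate ------------------------------------------------------

#' Synthesize a GPS/heart-rate track for one lap
#'
#' Walks the configured course at the true per-stride speeds (GPS time zero at
#' run start), adds slowly drifting AR(1) position noise, and renders heart
#' rate as the per-section truth plus AR(1) noise.
#'
#' @inheritParams synthesize_sensor_streams
#' @param lt One element of `ground_truth$laps`.
#' @return A `gps_hr_recording`.
#' @export
synthesize_gps <- function(lt, config, course = NULL, t_unix0 = 0) {
  if (is.null(course)) course <- default_course(config$lap_scale)
  gp <- config$sensors$gps
  st <- lt$strides
  t_rel <- seq(0, lt$duration_s - lt$run_start_s, by = 1 / gp$rate_hz)
  # cumulative distance along the course at each GPS second
  move_start <- st$t_start[1] - lt$run_start_s
  s_of_t <- stats::approx(c(-1e9, move_start, move_start + cumsum(st$stride_time)),
                          c(0, 0, cumsum(st$stride_length)),
                          xout = t_rel, rule = 2)$y

  wp <- course$waypoints
  vert <- latlon_to_xy(wp$lat, wp$lon, wp$lat[1], wp$lon[1])
  vert <- rbind(vert, vert[1, ])
  leg_len <- course$lengths_m
  cum_len <- c(0, cumsum(leg_len))
  s_mod <- pmin(s_of_t, cum_len[length(cum_len)] - 1e-9)
  leg <- findInterval(s_mod, cum_len, rightmost.closed = TRUE)
  leg[leg < 1] <- 1; leg[leg > 3] <- 3
  frac <- (s_mod - cum_len[leg]) / leg_len[leg]
  x <- vert[leg, 1] + frac * (vert[leg + 1, 1] - vert[leg, 1])
  y <- vert[leg, 2] + frac * (vert[leg + 1, 2] - vert[leg, 2])

  rho <- gp$noise_rho
  innov_sd <- gp$noise_sd_m * sqrt(1 - rho^2)
  ar1 <- function(n, sd0, rho, innov) {
    e <- rnorm(n, 0, innov)
    as.numeric(stats::filter(e, rho, method = "recursive",
                             init = rnorm(1, 0, sd0)))
  }
  nx <- ar1(length(x), gp$noise_sd_m, rho, innov_sd)
  ny <- ar1(length(y), gp$noise_sd_m, rho, innov_sd)
  ll <- xy_to_latlon(x + nx, y + ny, wp$lat[1], wp$lon[1])

  slope <- course$slopes_deg[course$sections][leg] * pi / 180
  ele_gain <- cumsum(c(0, diff(s_mod)) * sin(slope))
  ele <- 1740 + ele_gain + rnorm(length(x), 0, 0.5)

  hrp <- config$sensors$hr
  sec_of_leg <- course$sections[leg]
  hr_base <- lt$heart_rate[sec_of_leg]
  hr <- hr_base + as.numeric(stats::filter(rnorm(length(x), 0, hrp$innovation_sd),
                                           hrp$ar_rho, method = "recursive"))
  hr <- clamp(hr, 30, 230)

  structure(list(
    t = t_rel, t_unix = t_unix0 + lt$run_start_s + t_rel,
    lat = unname(ll[, "lat"]), lon = unname(ll[, "lon"]),
    ele = unname(ele), heart_rate = unname(hr)
  ), class = "gps_hr_recording")
}

# trapezoidal helpers shared with tests' oracles
cumtrapz <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((x[-1] + x[-n]) / 2 * dt))
}

trapz <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] + x[-n]) / 2 * dt)
}

central_diff <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, central_diff))
  n <- length(x)
  if (n < 3) return(rep(0, n))
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}
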