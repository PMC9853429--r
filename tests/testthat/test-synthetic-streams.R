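test_that("double-integrated template displacement equals stride length", {
  # independent trapezoid oracle on the emitted waveform: with rotations and
  # noise disabled, the anterior channel is world-frame swing acceleration
  cfg <- clean_config()
  tr <- generate_subject_kinematics(cfg, 1)
  st <- tr$laps[[1]]$strides
  recs <- synthesize_sensor_streams(tr, 1, cfg)
  t_rel <- recs$imu$t_low - recs$imu$t_low[1]
  rate <- recs$imu$rate_low
  for (k in c(3L, 10L, nrow(st) %/% 2L)) {
    # integrate midstance-to-midstance (0.3T after contact to 0.3T after
    # the next contact)
    t0 <- st$t_start[k] + 0.3 * st$stride_time[k]
    t1 <- st$t_start[k + 1] + 0.3 * st$stride_time[k + 1]
    idx <- which(t_rel >= t0 & t_rel <= t1)
    ax <- recs$imu$accel_low[idx, 1]
    v <- oracle_cumtrapz(ax, 1 / rate)
    d <- oracle_trapz(v, 1 / rate)
    expect_lt(abs(d - st$stride_length[k]), 0.01 * st$stride_length[k])
  }
})

test_that("low-g is clipped at the rail; high-g agrees when unclipped", {
  tl <- tiny_lap()
  imu <- tl$recs$imu
  g <- tl$cfg$gravity
  expect_lte(max(abs(imu$accel_low)), 16 * g)
  # where low-g is far from the rail, the interpolated high-g stream agrees
  # within its quantization + interpolation error
  hi <- stats::approx(imu$t_high, imu$accel_high[, 3], xout = imu$t_low)$y
  ok <- abs(imu$accel_low[, 3]) < 10 * g & is.finite(hi)
  err <- abs(hi[ok] - imu$accel_low[ok, 3])
  lsb_hi <- 2 * 200 * g / 2^13
  # bound: high-g LSB + both sensors' noise + linear-interp curvature error
  expect_lt(stats::quantile(err, 0.99),
            lsb_hi + 6 * tl$cfg$waveform$accel_noise_sd)
})

test_that("saturated heel truth loads every heel sensel each stance frame", {
  cfg <- flat_config()
  cfg$means$heel_area[, ] <- 100
  cfg$waveform$pressure_frame_noise_kpa <- 0
  tr <- generate_subject_kinematics(cfg, 1)
  recs <- synthesize_sensor_streams(tr, 1, cfg)
  pr <- recs$pressure
  masks <- region_masks(c(pr$rows, pr$cols))
  iv <- detect_stance(total_force(pr))
  tt <- pr$t - pr$t[1]
  iv <- iv[tt[iv[, "contact"]] > tr$laps[[1]]$run_start_s, , drop = FALSE]
  heel_cols <- which(as.vector(t(masks$heel)))
  for (i in seq_len(min(5, nrow(iv)))) {
    fr <- pr$frames[iv[i, 1]:(iv[i, 2] - 1L), heel_cols]
    expect_true(all(fr > 2.5))
  }
})

test_that("sensor synthesis is deterministic under the lap seed", {
  cfg <- tiny_config()
  tr <- generate_subject_kinematics(cfg, 1)
  a <- synthesize_sensor_streams(tr, 1, cfg)
  b <- synthesize_sensor_streams(tr, 1, cfg)
  expect_identical(a$imu$accel_low, b$imu$accel_low)
  expect_identical(a$pressure$frames, b$pressure$frames)
  expect_identical(a$gps$lat, b$gps$lat)
})

test_that("GPS noise stays at the configured scale", {
  tl <- tiny_lap()
  gps <- tl$recs$gps
  course <- tl$course
  # every sample lies within a few noise SDs of some course leg
  sec <- assign_sections(gps, course)
  expect_true(all(sec$labels %in% course$sections))
  expect_equal(length(sec$labels), length(gps$lat))
  expect_true(all(gps$heart_rate >= 30 & gps$heart_rate <= 230))
})
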