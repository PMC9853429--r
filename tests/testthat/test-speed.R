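test_that("gravity cancels for a stationary window", {
  g <- 9.81
  n <- 1200
  set.seed(4)
  accel <- cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05), rnorm(n, g, 0.05))
  gyro <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  wa <- world_frame_acceleration(accel, gyro, n %/% 2L, 1125, g)
  expect_lt(sqrt(mean(rowSums(wa^2))), 0.1)
  # noiseless: identically zero
  wa0 <- world_frame_acceleration(matrix(c(0, 0, g), 4000, 3, byrow = TRUE),
                                  matrix(0, 4000, 3), 2000L, 1125, g)
  expect_lt(max(abs(wa0)), 1e-9)
})

test_that("the initial gravity direction is recovered from a tilted sensor", {
  g <- 9.81
  tilt <- 14 * pi / 180
  n <- 1000
  accel <- matrix(rep(c(g * sin(tilt), 0, g * cos(tilt)), each = n), n, 3)
  wa <- world_frame_acceleration(accel, matrix(0, n, 3), 500L, 1125, g)
  expect_lt(max(abs(wa)), 1e-9)           # gravity removed despite tilt
  expect_lt(abs(attr(wa, "tilt_deg") - 14), 2)
})

test_that("ZUPT de-drifting zeroes velocity at both anchors exactly", {
  set.seed(8)
  m <- 900
  wa <- matrix(rnorm(3 * m, 0, 5), m, 3)
  dt <- 1 / 1125
  v <- apply(wa, 2, oracle_cumtrapz, dt = dt)
  ramp <- (seq_len(m) - 1) / (m - 1)
  vc <- v - outer(ramp, v[m, ])
  expect_equal(max(abs(vc[1, ])), 0)
  expect_lt(max(abs(vc[m, ])), 1e-12)
  ss <- stride_speed(wa, 0.8, 1125)
  expect_gte(ss$speed, 0)
  # invariance to a constant world-frame bias (absorbed by the de-drift)
  ss_b <- stride_speed(wa + matrix(rep(c(1.3, -0.7, 2.1), each = m), m, 3),
                       0.8, 1125)
  expect_equal(ss_b$speed, ss$speed, tolerance = 1e-10)
})

test_that("a zero-motion window yields zero speed", {
  wa <- matrix(0, 500, 3)
  expect_equal(stride_speed(wa, 0.8, 1125)$speed, 0)
})

test_that("noise-free synthetic strides recover true speed within 1%", {
  fl <- flat_lap()
  pl <- process_lap(fl$recs, fl$course)
  st <- fl$truth$laps[[1]]$strides
  i <- match_truth(pl$strides, st)
  ok <- is.finite(pl$strides$speed)
  rel <- abs(pl$strides$speed[ok] - st$speed[i][ok]) / st$speed[i][ok]
  expect_lt(stats::median(rel), 0.005)
  expect_lt(mean(rel), 0.01)
  # spec-level example: ~3 m/s strides recovered within 0.03 m/s
  dh <- st$section[i] == "downhill" & ok
  expect_lt(max(abs(pl$strides$speed[dh] - st$speed[i][dh])), 0.05)
})

test_that("doubling stride length at fixed stride time doubles speed", {
  cfg1 <- clean_config()
  cfg2 <- clean_config()
  cfg2$means$speed[, ] <- cfg1$means$speed * 2
  sp <- lapply(list(cfg1, cfg2), function(cfg) {
    tr <- generate_subject_kinematics(cfg, 1)
    recs <- synthesize_sensor_streams(tr, 1, cfg)
    pl <- process_lap(recs, default_course(cfg$lap_scale))
    st <- tr$laps[[1]]$strides
    i <- match_truth(pl$strides, st)
    up <- st$section[i] == "uphill" & is.finite(pl$strides$speed)
    mean(pl$strides$speed[up])
  })
  expect_equal(sp[[2]] / sp[[1]], 2, tolerance = 0.02)
})
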