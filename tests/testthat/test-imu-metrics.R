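still_fused <- function(n = 2000, g = 9.81) {
  matrix(rep(c(0, 0, g), each = n), n, 3)
}

test_that("a quiet stance segment gives peak_acc = g and near-zero jerk", {
  f <- still_fused()
  s <- list(start = 10L, end = 1990L)
  pj <- peak_acc_jerk(s, f, 1125)
  expect_equal(pj$peak_acc, 9.81)
  expect_lt(pj$peak_jerk, 1e-9)
  expect_equal(ml_acceleration_range(s, f,
                                     c(anterior = 1, mediolateral = 2,
                                       vertical = 3)), 0)
})

test_that("peak metrics equal an exhaustive per-sample scan", {
  tp <- tiny_processed()
  fused <- fuse_accelerometers(tp$recs$imu)
  rate <- tp$recs$imu$rate_low
  f50 <- zero_phase_lowpass(fused$accel, 50, rate)
  s <- tp$pl$strides[4, ]
  pj <- peak_acc_jerk(s, f50, rate)
  idx <- s$start:(s$end - 1L)
  # oracle: brute-force loop over samples
  best_a <- 0
  for (k in idx) best_a <- max(best_a, sqrt(sum(f50[k, ]^2)))
  expect_equal(pj$peak_acc, best_a)
  seg <- f50[idx, ]
  n <- nrow(seg)
  jer <- rbind(seg[2, ] - seg[1, ],
               (seg[3:n, ] - seg[1:(n - 2), ]) / 2,
               seg[n, ] - seg[n - 1, ]) * rate
  best_j <- 0
  for (k in seq_len(n)) best_j <- max(best_j, sqrt(sum(jer[k, ]^2)))
  expect_equal(pj$peak_jerk, best_j)
  # max - min scan for the ML range
  expect_equal(ml_acceleration_range(s, f50, tp$recs$imu$axes),
               max(f50[idx, 2]) - min(f50[idx, 2]))
})

test_that("an ML sine of amplitude A has range 2A after filtering", {
  rate <- 1125
  n <- 4000
  t <- (0:(n - 1)) / rate
  f <- cbind(0, 40 * sin(2 * pi * 3 * t), 9.81)
  f50 <- zero_phase_lowpass(f, 50, rate)
  s <- list(start = 400L, end = 3600L)
  expect_equal(ml_acceleration_range(s, f50,
                                     c(anterior = 1, mediolateral = 2,
                                       vertical = 3)),
               80, tolerance = 0.01 * 80)
  expect_error(ml_acceleration_range(s, f50, c(anterior = 1, vertical = 3)),
               "axis")
})

test_that("eversion peak honors the first-20% window and the side convention", {
  rate <- 1125
  n <- round(0.8 * rate)  # one 0.8 s stride
  g30 <- matrix(0, 2 * n, 3)
  t <- (seq_len(2 * n) - 1) / rate
  pulse <- function(c0) 400 * exp(-((t - c0) / 0.03)^2)
  s <- list(start = 1L, end = n + 1L, contact = 1L)
  # right foot: eversion is negative frontal-channel rate
  g30a <- g30; g30a[, 1] <- -pulse(0.08 * 0.8)
  v_in <- peak_eversion_velocity(s, zero_phase_lowpass(g30a, 30, rate),
                                 1L, "right")
  expect_equal(v_in, 400, tolerance = 0.02 * 400)
  # same pulse at 30% of the stride falls outside the window
  g30b <- g30; g30b[, 1] <- -pulse(0.30 * 0.8)
  v_out <- peak_eversion_velocity(s, zero_phase_lowpass(g30b, 30, rate),
                                  1L, "right")
  expect_lt(v_out, 0.1 * 400)
  # left foot mirrors the sign
  g30c <- g30; g30c[, 1] <- pulse(0.08 * 0.8)
  v_left <- peak_eversion_velocity(s, zero_phase_lowpass(g30c, 30, rate),
                                   1L, "left")
  expect_equal(v_left, v_in)
  expect_error(peak_eversion_velocity(s, g30a, 1L, NULL), "side")
})

test_that("time reversal preserves peak_acc but not the eversion window", {
  tp <- tiny_processed()
  fused <- fuse_accelerometers(tp$recs$imu)
  rate <- tp$recs$imu$rate_low
  f50 <- zero_phase_lowpass(fused$accel, 50, rate)
  g30 <- zero_phase_lowpass(tp$recs$imu$gyro, 30, rate)
  s <- tp$pl$strides[5, ]
  idx <- s$start:(s$end - 1L)
  srev <- list(start = 1L, end = length(idx) + 1L, contact = 1L)
  pj_f <- peak_acc_jerk(s, f50, rate)
  pj_r <- peak_acc_jerk(srev, f50[rev(idx), , drop = FALSE], rate)
  expect_equal(pj_r$peak_acc, pj_f$peak_acc)
  ev_f <- peak_eversion_velocity(s, g30, 1L, "right")
  ev_r <- peak_eversion_velocity(srev, g30[rev(idx), , drop = FALSE],
                                 1L, "right")
  expect_false(isTRUE(all.equal(ev_f, ev_r)))
})

test_that("metrics are computed only on strides after the hop gate", {
  tp <- tiny_processed()
  rs_time <- tp$pl$run_start_time_s
  expect_true(all(tp$pl$strides$contact_time >= rs_time))
  expect_equal(nrow(tp$pl$strides), nrow(tp$truth$laps[[1]]$strides))
})
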