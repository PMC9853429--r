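test_that("a synthetic lap round-trips through the on-disk dialect", {
  tb <- tiny_bundle()
  entry <- list(foot_side = "right", sensors = tb$cfg$sensors,
                gravity = tb$cfg$gravity)
  expect_no_warning(
    recs <- read_lap(file.path(tb$dir, "sub01", "lap1"), entry))
  tr <- generate_subject_kinematics(tb$cfg, 1)
  direct <- synthesize_sensor_streams(tr, 1, tb$cfg)
  expect_equal(recs$imu$accel_low, unname(direct$imu$accel_low),
               ignore_attr = TRUE)
  expect_equal(dim(recs$pressure$frames), dim(direct$pressure$frames))
  expect_equal(recs$gps$lat, direct$gps$lat, tolerance = 1e-6)
})

test_that("duplicated timestamps are dropped with a warning; shuffled rows error", {
  tb <- tiny_bundle()
  src <- file.path(tb$dir, "sub01", "lap1")
  dup_dir <- file.path(tempdir(), "lap-dup")
  unlink(dup_dir, recursive = TRUE); dir.create(dup_dir)
  file.copy(list.files(src, full.names = TRUE), dup_dir)
  d <- data.table::fread(file.path(dup_dir, "imu_low.csv"))
  data.table::fwrite(rbind(d[1:100], d[100], d[101:nrow(d)]),
                     file.path(dup_dir, "imu_low.csv"))
  entry <- list(foot_side = "right", sensors = tb$cfg$sensors,
                gravity = tb$cfg$gravity)
  expect_warning(read_lap(dup_dir, entry), "duplicated timestamp")

  bad_dir <- file.path(tempdir(), "lap-shuffled")
  unlink(bad_dir, recursive = TRUE); dir.create(bad_dir)
  file.copy(list.files(src, full.names = TRUE), bad_dir)
  set.seed(1)
  data.table::fwrite(d[sample(nrow(d))], file.path(bad_dir, "imu_low.csv"))
  expect_error(read_lap(bad_dir, entry), "non-monotone")

  expect_error(read_lap(file.path(tempdir(), "nope"), entry), "missing")
})

test_that("fusion substitutes interpolated high-g exactly where low-g saturates", {
  g <- 9.81
  n <- 2000
  t <- (0:(n - 1)) / 1125
  low <- matrix(0.5 * g, n, 3)
  # a clipped episode on the vertical axis
  low[800:840, 3] <- 16 * g
  t_hi <- seq(0, max(t), by = 1 / 1600)
  high <- matrix(0, length(t_hi), 3)
  high[, 3] <- 34.2 * g
  rec <- structure(list(
    t_low = t, accel_low = low, t_high = t_hi, accel_high = high,
    gyro = matrix(0, n, 3), rate_low = 1125, rate_high = 1600,
    axes = c(anterior = 1L, mediolateral = 2L, vertical = 3L),
    frontal_gyro_axis = 1L, side = "right",
    range_low_g = 16, bits_low = 16, gravity = g), class = "imu_recording")
  fused <- fuse_accelerometers(rec)
  expect_true(all(fused$substituted[800:840, 3]))
  expect_equal(unique(fused$accel[800:840, 3]), 34.2 * g)
  # unsaturated samples are bitwise untouched
  expect_identical(fused$accel[1:799, ], low[1:799, ])
  expect_false(any(fused$substituted[, 1:2]))
  # never exceeds the high-g range
  expect_lte(max(abs(fused$accel)), 200 * g)
})

test_that("substitution count matches a brute-force saturation scan", {
  tl <- tiny_lap()
  imu <- tl$recs$imu
  fused <- fuse_accelerometers(imu)
  g <- imu$gravity
  lsb <- 2 * imu$range_low_g * g / 2^imu$bits_low
  brute <- sum(abs(imu$accel_low) >= 16 * g - lsb / 2)
  expect_identical(sum(fused$substituted), brute)
  # a clipping-free recording passes through bitwise
  imu2 <- imu
  imu2$accel_low <- pmin(pmax(imu2$accel_low, -8 * g), 8 * g)
  fused2 <- fuse_accelerometers(imu2)
  expect_identical(fused2$accel, imu2$accel_low)
  # fusion is idempotent: re-fusing the fused output changes nothing
  imu3 <- imu
  imu3$accel_low <- fused$accel
  expect_error(capture.output(fuse_accelerometers(imu3)), NA)
})

test_that("non-overlapping accelerometer streams are rejected", {
  tl <- tiny_lap()
  imu <- tl$recs$imu
  imu$t_high <- imu$t_high + 1e6
  expect_error(fuse_accelerometers(imu), "overlap")
})
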