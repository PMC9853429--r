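# Shared fixtures, memoized so expensive synthetic laps are built once per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a short lap with default noise and biological variability
tiny_config <- function(...) {
  study_config(n_subjects = 2, lap_scale = 0.04, seed = 421, ...)
}

# all biological SDs zero: every stride equals its cell mean
flat_config <- function(...) {
  cfg <- study_config(n_subjects = 1, lap_scale = 0.05, seed = 77, ...)
  cfg$sds$intercept_sd[] <- 0
  cfg$sds$slope_sd[] <- 0
  cfg$sds$stride_sd[] <- 0
  cfg$stride_time$subject_sd <- 0
  cfg$stride_time$stride_sd <- 0
  cfg
}

# additionally strip sensor noise and rotations so world accel is directly
# readable off the emitted signal
clean_config <- function(...) {
  cfg <- flat_config(...)
  cfg$waveform$accel_noise_sd <- 0
  cfg$waveform$gyro_noise_sd <- 0
  cfg$waveform$gyro_cross_noise_sd <- 0
  cfg$waveform$pitch_amp_dps <- 0
  cfg$waveform$pressure_frame_noise_kpa <- 0
  cfg$means$eversion_vel[, ] <- 0.001
  cfg
}

tiny_lap <- function() {
  memo("tiny_lap", {
    cfg <- tiny_config()
    tr <- generate_subject_kinematics(cfg, 1)
    recs <- synthesize_sensor_streams(tr, 1, cfg)
    list(cfg = cfg, truth = tr, recs = recs,
         course = default_course(cfg$lap_scale))
  })
}

tiny_processed <- function() {
  memo("tiny_processed", {
    tl <- tiny_lap()
    c(tl, list(pl = process_lap(tl$recs, tl$course)))
  })
}

flat_lap <- function() {
  memo("flat_lap", {
    cfg <- flat_config()
    tr <- generate_subject_kinematics(cfg, 1)
    recs <- synthesize_sensor_streams(tr, 1, cfg, self_check = TRUE)
    list(cfg = cfg, truth = tr, recs = recs,
         course = default_course(cfg$lap_scale))
  })
}

# a written-to-disk two-subject bundle
tiny_bundle <- function() {
  memo("tiny_bundle", {
    cfg <- tiny_config()
    dir <- file.path(tempdir(), "trailgait-bundle")
    unlink(dir, recursive = TRUE)
    mf <- generate_study(cfg, dir)
    list(cfg = cfg, dir = dir, manifest = mf)
  })
}

# match detected strides to truth strides by nearest contact time
match_truth <- function(detected, truth_strides) {
  vapply(detected$contact_time, function(x)
    which.min(abs(truth_strides$t_start - x)), integer(1))
}

# simulated two-condition outcome table with subject intercepts and slopes
sim_table <- function(n_subj, n_str, delta, sd_int = 1, sd_slope = 0.5,
                      sd_eps = 1, mu = 10, seed = 1) {
  set.seed(seed)
  b <- rnorm(n_subj, 0, sd_int)
  u <- rnorm(n_subj, 0, sd_slope)
  rows <- expand.grid(Subject = seq_len(n_subj), Config = c("Lace", "Wrap"),
                      k = seq_len(n_str), KEEP.OUT.ATTRS = FALSE)
  m <- mu + b[rows$Subject] + (delta + u[rows$Subject]) *
    (rows$Config == "Wrap")
  data.frame(Outcome = m + rnorm(nrow(rows), 0, sd_eps),
             Config = as.character(rows$Config), Subject = rows$Subject)
}

# independent trapezoid integrators (oracles)
oracle_cumtrapz <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2) * dt)
}
oracle_trapz <- function(x, dt) sum((x[-1] + x[-length(x)]) / 2) * dt
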