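#' Study configuration
#'
#' Builds the configuration object that drives the synthetic-study generator
#' and documents the conditions of the footwear comparison it emulates: a
#' three-section trail loop (uphill / technical top / downhill) run four times
#' per subject in an A-B-B-A counterbalanced order contrasting a Wrap and a
#' Lace closure of the same shoe.
#'
#' Population means per metric are parameterized per trail section and shoe
#' configuration. Between-subject variation enters through a random intercept
#' (one per subject per metric) and a random condition slope (the
#' subject-specific response to switching closures); stride-to-stride variation
#' through a residual SD. All three SDs are per metric.
#'
#' @param n_subjects Number of subjects in the simulated cohort.
#' @param laps_per_subject Laps per subject; must be even (A-B-B-A pairs). The
#'   condition run first is randomized per subject.
#' @param lap_scale Multiplier on the section lengths. 1 is the full 1.57 km
#'   loop; smaller values generate geometrically similar but shorter laps
#'   (same speeds, slopes, and effect structure) for desk-scale runs.
#' @param seed Integer seed from which every random draw in the study derives.
#' @param qc_outlier If `TRUE`, the last subject runs one lap slowed so that
#'   their lap-time range is ~143 s, exercising the one-minute lap-QC rule.
#' @param gravity Gravitational acceleration in m/s^2.
#' @param ... Named overrides for any top-level configuration element
#'   (`sections`, `means`, `sds`, `stride_time`, `sensors`, `waveform`,
#'   `questionnaire`, `hops`).
#'
#' @return A list of class `trail_config`.
#' @export
study_config <- function(n_subjects = 29L,
                         laps_per_subject = 4L,
                         lap_scale = 1,
                         seed = 20230106L,
                         qc_outlier = FALSE,
                         gravity = 9.81,
                         ...) {
  sections <- data.frame(
    section   = c("uphill", "top", "downhill"),
    length_m  = c(580, 520, 470) * lap_scale,
    slope_deg = c(4, 2, -6),
    stringsAsFactors = FALSE
  )

  cell <- function(uw, ul, tw, tl, dw, dl) {
    m <- matrix(c(uw, ul, tw, tl, dw, dl), nrow = 3, byrow = TRUE,
                dimnames = list(c("uphill", "top", "downhill"),
                                c("Wrap", "Lace")))
    m
  }

  # Population cell means (section x configuration) for every outcome.
  means <- list(
    speed        = cell(2.71, 2.68, 2.54, 2.51, 3.32, 3.29),
    peak_acc     = cell(124.7, 124.1, 135.9, 135.4, 185.9, 182.0),
    peak_jerk    = cell(24660, 24657, 27836, 27912, 40343, 39819),
    eversion_vel = cell(328.1, 343.8, 324.6, 341.2, 466.7, 490.2),
    ml_range     = cell(93.0, 95.2, 105.0, 107.2, 165.0, 167.4),
    heel_area    = cell(61.7, 59.3, 62.8, 60.5, 67.4, 65.4),
    toe_area     = cell(70.0, 69.8, 70.9, 70.7, 69.2, 69.0),
    heel_peak    = cell(180.1, 175.5, 207.1, 205.4, 382.3, 372.9),
    toe_peak     = cell(513.1, 509.7, 527.3, 523.9, 511.0, 516.8),
    heart_rate   = cell(160, 159, 171, 171, 162, 161)
  )

  # intercept_sd: between-subject SD of a subject's overall level (shared
  # across sections); slope_sd: between-subject SD of the condition response;
  # stride_sd: stride-to-stride (or step/lap) residual SD.
  sds <- data.frame(
    metric       = c("speed", "peak_acc", "peak_jerk", "eversion_vel",
                     "ml_range", "heel_area", "toe_area", "heel_peak",
                     "toe_peak", "heart_rate"),
    intercept_sd = c(0.40, 21, 6000, 75, 29, 9, 5, 72, 96, 11),
    slope_sd     = c(0.008, 3, 900, 6, 4, 0.8, 0.8, 10, 14, 1),
    stride_sd    = c(0.10, 18, 5000, 40, 16, 5, 3, 40, 50, 1.5),
    stringsAsFactors = FALSE
  )

  # Lower clamps keep draws physically meaningful in small-SD tails.
  clamp_lo <- c(speed = 0.5, peak_acc = 60, peak_jerk = 8000,
                eversion_vel = 50, ml_range = 10, heel_area = 5,
                toe_area = 5, heel_peak = 20, toe_peak = 20,
                heart_rate = 60)
  clamp_hi <- c(speed = 8, peak_acc = 1900, peak_jerk = 3e5,
                eversion_vel = 1900, ml_range = 300, heel_area = 100,
                toe_area = 100, heel_peak = 1200, toe_peak = 1200,
                heart_rate = 220)

  stride_time <- list(mean = 0.78, subject_sd = 0.04, stride_sd = 0.02,
                      min = 0.5, max = 1.2)

  sensors <- list(
    low_g    = list(rate_hz = 1125, range_g = 16,  bits = 16),
    high_g   = list(rate_hz = 1600, range_g = 200, bits = 13),
    gyro     = list(rate_hz = 1125, range_dps = 2000, bits = 16),
    pressure = list(rate_hz = 100, rows = 25L, cols = 9L,
                    sensel_area_cm2 = 1.0),
    gps      = list(rate_hz = 1, noise_sd_m = 2, noise_rho = 0.99),
    hr       = list(rate_hz = 1, ar_rho = 0.8, innovation_sd = 1.0)
  )

  # Stride waveform template phases (fractions of stride time) and noise.
  waveform <- list(
    stance_frac      = 0.35,   # stance duration for the insole
    flat_end_frac    = 0.40,   # foot stationary from contact to here
    swing_start_frac = 0.40,
    swing_end_frac   = 0.98,   # foot again stationary just before landing
    ev_center1_frac  = 0.08,   # eversion lobe (within first 20 %)
    ev_center2_frac  = 0.23,   # inversion return lobe
    ev_halfwidth_frac = 0.05,
    pitch_amp_dps    = 250,    # sagittal swing rotation amplitude
    accel_noise_sd   = 0.4,    # m/s^2, per axis, both accelerometers
    gyro_noise_sd    = 2,      # deg/s on the frontal channel
    gyro_cross_noise_sd = 0.5, # deg/s on the other channels
    hop_amp_ms2      = 6 * gravity,
    hop_halfwidth_s  = 0.075,
    pressure_base_kpa = 10,    # floor pressure of a loaded sensel
    pressure_frame_noise_kpa = 0.3,
    mid_force_frac   = 0.35    # midfoot share of loaded sensels
  )

  questionnaire <- data.frame(
    item      = c("uphill", "level", "downhill", "confidence", "overall_fit",
                  "forefoot_fit", "midfoot_fit", "heel_fit"),
    wrap_mean = c(8.3, 8.4, 8.4, 8.8, 8.0, 6.2, 5.3, 5.1),
    wrap_sd   = c(1.1, 1.2, 1.5, 1.0, 1.5, 1.5, 0.6, 0.7),
    lace_mean = c(7.3, 7.5, 6.3, 6.8, 6.5, 5.5, 5.1, 4.5),
    lace_sd   = c(1.1, 1.3, 1.5, 1.5, 1.4, 2.1, 1.5, 1.4),
    stringsAsFactors = FALSE
  )

  hops <- list(n = 3L, times_s = c(2.0, 2.8, 3.6), settle_s = 0.2,
               quiet_after_s = 1.2, tail_s = 1.0)

  cfg <- list(
    n_subjects = as.integer(n_subjects),
    laps_per_subject = as.integer(laps_per_subject),
    lap_scale = lap_scale,
    seed = as.integer(seed),
    qc_outlier = isTRUE(qc_outlier),
    qc_outlier_extra_s = 143,
    gravity = gravity,
    sections = sections,
    means = means,
    sds = sds,
    clamp_lo = clamp_lo,
    clamp_hi = clamp_hi,
    stride_time = stride_time,
    sensors = sensors,
    waveform = waveform,
    questionnaire = questionnaire,
    hops = hops
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "trail_config"
  validate_config(cfg)
  cfg
}

#' Validate a trail_config
#'
#' Checks the structural invariants of a study configuration: non-negative
#' SDs, positive section lengths, an even lap count, and sensor rates.
#'
#' @param cfg A `trail_config`.
#' @return `cfg`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "trail_config"))
  if (cfg$n_subjects < 1L)
    stop("configuration error: n_subjects must be >= 1")
  if (cfg$laps_per_subject %% 2L != 0L)
    stop("configuration error: laps_per_subject must be even (A-B-B-A pairs)")
  if (any(cfg$sections$length_m <= 0))
    stop("configuration error: section lengths must be positive")
  sdcols <- c("intercept_sd", "slope_sd", "stride_sd")
  if (any(as.matrix(cfg$sds[, sdcols]) < 0))
    stop("configuration error: all SDs must be >= 0")
  if (cfg$stride_time$mean <= 0 || cfg$stride_time$min <= 0)
    stop("configuration error: stride times must be positive")
  for (s in c("low_g", "high_g", "gyro", "pressure", "gps")) {
    if (cfg$sensors[[s]]$rate_hz <= 0)
      stop("configuration error: sensor rates must be positive")
  }
  if (cfg$sensors$pressure$rows < 5L)
    stop("configuration error: pressure grid needs >= 5 rows")
  invisible(cfg)
}

#' @export
print.trail_config <- function(x, ...) {
  cat("<trail_config>\n")
  cat(sprintf("  subjects: %d, laps each: %d (A-B-B-A), seed: %d\n",
              x$n_subjects, x$laps_per_subject, x$seed))
  cat(sprintf("  sections: %s\n",
              paste(sprintf("%s %.0f m @ %+.0f deg", x$sections$section,
                            x$sections$length_m, x$sections$slope_deg),
                    collapse = ", ")))
  cat(sprintf("  IMU %d Hz (low-g +/-%d g, high-g +/-%d g @ %d Hz), pressure %d Hz (%dx%d),\n",
              x$sensors$low_g$rate_hz, x$sensors$low_g$range_g,
              x$sensors$high_g$range_g, x$sensors$high_g$rate_hz,
              x$sensors$pressure$rate_hz, x$sensors$pressure$rows,
              x$sensors$pressure$cols))
  cat(sprintf("  GPS/HR %d Hz\n", x$sensors$gps$rate_hz))
  invisible(x)
}

# Deterministic per-subject / per-lap seed streams, kept below 2^31.
subject_seed <- function(cfg, subject_id) {
  as.integer((as.numeric(cfg$seed) + subject_id * 10007) %% 2147483629)
}

lap_seed <- function(cfg, subject_id, lap) {
  as.integer((as.numeric(cfg$seed) + subject_id * 97003 + lap * 641) %%
               2147483629)
}

metric_names <- function() {
  c("speed", "peak_acc", "peak_jerk", "eversion_vel", "ml_range",
    "heel_area", "toe_area", "heel_peak", "toe_peak")
}

sd_row <- function(cfg, metric) {
  i <- match(metric, cfg$sds$metric)
  if (is.na(i)) stop("unknown metric: ", metric)
  cfg$sds[i, ]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
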