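#' Process one lap's recordings into per-stride and per-step outcomes
#'
#' Runs the full per-lap chain: accelerometer fusion, hop gating, stride
#' segmentation, zero-phase filtering (50 Hz accelerometer/gyro for
#' orientation and stride metrics, 30 Hz gyro for eversion), ZUPT speed
#' estimation, IMU stride metrics, insole stance detection and regional
#' metrics, GPS section assignment, and per-section heart rate.
#'
#' @param recs List with `imu`, `pressure`, `gps` as returned by
#'   [read_lap()] or [synthesize_sensor_streams()].
#' @param course A `trail_course`.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return List: `strides` (per-stride metrics + section labels), `steps`
#'   (per-step pressure metrics + sections), `hr` (per-section means),
#'   `lap_duration_s`, `run_start_time_s`.
#' @export
process_lap <- function(recs, course, gravity = 9.81) {
  imu <- recs$imu
  rate <- imu$rate_low
  fused <- fuse_accelerometers(imu)
  run_start <- detect_hops(fused, gravity = gravity)
  run_start_time <- fused$t[run_start] - fused$t[1]

  strides <- segment_strides(fused, run_start = run_start)
  fused50 <- zero_phase_lowpass(fused$accel, 50, rate)
  gyro50 <- zero_phase_lowpass(imu$gyro, 50, rate)
  gyro30 <- zero_phase_lowpass(imu$gyro, 30, rate)

  sec <- assign_sections(recs$gps, course)
  hr <- section_heart_rate(recs$gps, sec$labels)

  if (nrow(strides)) {
    sp <- lap_stride_speeds(strides, fused50, gyro50, rate, gravity)
    im <- lap_imu_metrics(strides, fused50, gyro30, imu$axes,
                          imu$frontal_gyro_axis, imu$side, rate)
    contact_t <- fused$t[strides$contact] - fused$t[1]
    labels <- align_streams(contact_t, run_start_time, recs$gps, sec$labels)
    strides <- cbind(strides, sp, im,
                     data.frame(Section = labels,
                                contact_time = contact_t))
  } else {
    strides <- cbind(strides,
                     data.frame(speed = numeric(0),
                                stride_length = numeric(0),
                                drift_correction = numeric(0),
                                peak_acc = numeric(0),
                                peak_jerk = numeric(0),
                                ml_range = numeric(0),
                                eversion_vel = numeric(0),
                                Section = character(0),
                                contact_time = numeric(0)))
  }

  masks <- region_masks(c(recs$pressure$rows, recs$pressure$cols))
  steps <- lap_pressure_metrics(recs$pressure, run_start_time, masks)
  if (nrow(steps)) {
    steps$Section <- align_streams(steps$contact_time, run_start_time,
                                   recs$gps, sec$labels)
  } else {
    steps$Section <- character(0)
  }

  list(strides = strides, steps = steps, hr = hr,
       section_path_lengths_m = sec$path_lengths_m,
       lap_duration_s = max(recs$gps$t) - min(recs$gps$t),
       run_start_time_s = run_start_time)
}

#' Generate and process a synthetic study in memory
#'
#' Generates every subject's ground truth and raw sensor streams lap by lap
#' and runs [process_lap()] on each, without touching disk. This is the
#' round-trip entry point: the returned tables come from the measurement
#' pipeline, while `$truth` holds the generating values for comparison.
#'
#' @param config A [study_config()].
#' @param progress Print one line per subject.
#' @return A `processed_study`: `strides`, `steps`, `hr` (long data.frames
#'   with `Subject`, `Lap`, `Config`, `Section` columns), `lap_times`,
#'   `qc` (`retained`/`excluded` subject ids), `questionnaire`, `truth`
#'   (list of `ground_truth`), `config`.
#' @export
process_study <- function(config, progress = FALSE) {
  validate_config(config)
  course <- default_course(config$lap_scale)
  all_str <- list(); all_steps <- list(); all_hr <- list()
  lap_rows <- list(); truths <- list(); quest <- list()
  for (sid in seq_len(config$n_subjects)) {
    truth <- generate_subject_kinematics(config, sid)
    truths[[sid]] <- truth
    for (lap in seq_len(config$laps_per_subject)) {
      recs <- synthesize_sensor_streams(truth, lap, config, course)
      pl <- process_lap(recs, course, gravity = config$gravity)
      cond <- truth$laps[[lap]]$config
      key <- paste(sid, lap)
      if (nrow(pl$strides))
        all_str[[key]] <- data.frame(Subject = sid, Lap = lap,
                                     Config = cond, pl$strides)
      if (nrow(pl$steps))
        all_steps[[key]] <- data.frame(Subject = sid, Lap = lap,
                                       Config = cond, pl$steps)
      all_hr[[key]] <- data.frame(Subject = sid, Lap = lap, Config = cond,
                                  Section = names(pl$hr), hr = unname(pl$hr))
      lap_rows[[key]] <- data.frame(Subject = sid, Lap = lap, Config = cond,
                                    duration_s = pl$lap_duration_s)
    }
    q <- truth$questionnaire
    quest[[sid]] <- data.frame(Subject = sid, item = q$item,
                               config = q$config, response = q$response)
    if (progress)
      message(sprintf("subject %d/%d processed", sid, config$n_subjects))
  }
  lap_times <- do.call(rbind, lap_rows)
  qc <- study_lap_qc(lap_times)
  out <- list(
    strides = do.call(rbind, all_str),
    steps = do.call(rbind, all_steps),
    hr = do.call(rbind, all_hr),
    lap_times = lap_times,
    qc = qc,
    questionnaire = do.call(rbind, quest),
    truth = truths,
    config = config
  )
  rownames(out$strides) <- rownames(out$steps) <- rownames(out$hr) <- NULL
  class(out) <- "processed_study"
  out
}

# Apply the lap-time QC rule per subject.
study_lap_qc <- function(lap_times) {
  subs <- unique(lap_times$Subject)
  keep <- vapply(subs, function(s)
    lap_qc(lap_times$duration_s[lap_times$Subject == s]), logical(1))
  list(retained = subs[keep], excluded = subs[!keep])
}

#' @export
print.processed_study <- function(x, ...) {
  cat(sprintf(
    "<processed_study> %d subjects, %d strides, %d steps, %d retained\n",
    length(unique(x$lap_times$Subject)), nrow(x$strides), nrow(x$steps),
    length(x$qc$retained)))
  invisible(x)
}

#' Write a synthetic study bundle to disk
#'
#' Generates all subjects and laps of a study and writes the on-disk bundle
#' consumed by [run_pipeline()]: a JSON manifest, per-lap CSV files (low-g,
#' high-g, gyro, pressure frames), a GPX 1.1 track with heart rate, a
#' course-definition YAML, and a separate ground-truth JSON archive.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
generate_study <- function(config, dir) {
  validate_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  course <- default_course(config$lap_scale)
  write_course(course, file.path(dir, "course.yaml"))

  subjects <- list()
  truth_arch <- list()
  for (sid in seq_len(config$n_subjects)) {
    truth <- generate_subject_kinematics(config, sid)
    laps <- list()
    for (lap in seq_len(config$laps_per_subject)) {
      lap_dir <- file.path(dir, sprintf("sub%02d", sid),
                           sprintf("lap%d", lap))
      dir.create(lap_dir, recursive = TRUE, showWarnings = FALSE)
      recs <- synthesize_sensor_streams(truth, lap, config, course,
                                        self_check = (sid == 1 && lap == 1))
      write_lap(recs, lap_dir)
      laps[[lap]] <- list(lap = lap, config = truth$laps[[lap]]$config,
                          dir = file.path(sprintf("sub%02d", sid),
                                          sprintf("lap%d", lap)))
    }
    subjects[[sid]] <- list(
      id = sid, foot_side = truth$foot_side,
      condition_order = truth$condition_order, laps = laps,
      questionnaire = truth$questionnaire)
    truth_arch[[sid]] <- list(
      subject = sid,
      laps = lapply(truth$laps, function(l)
        list(lap = l$lap, config = l$config, run_start_s = l$run_start_s,
             duration_s = l$duration_s, heart_rate = as.list(l$heart_rate),
             strides = l$strides))
    )
  }
  manifest <- list(
    study = "trailgait synthetic study",
    seed = config$seed, n_subjects = config$n_subjects,
    laps_per_subject = config$laps_per_subject,
    lap_scale = config$lap_scale,
    gravity = config$gravity,
    sensors = config$sensors,
    subjects = subjects
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(truth_arch, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

write_lap <- function(recs, lap_dir) {
  imu <- recs$imu
  data.table::fwrite(data.table::data.table(
    t_unix = imu$t_low, ax = imu$accel_low[, 1], ay = imu$accel_low[, 2],
    az = imu$accel_low[, 3]), file.path(lap_dir, "imu_low.csv"))
  data.table::fwrite(data.table::data.table(
    t_unix = imu$t_high, ax = imu$accel_high[, 1],
    ay = imu$accel_high[, 2], az = imu$accel_high[, 3]),
    file.path(lap_dir, "imu_high.csv"))
  data.table::fwrite(data.table::data.table(
    t_unix = imu$t_low, gx = imu$gyro[, 1], gy = imu$gyro[, 2],
    gz = imu$gyro[, 3]), file.path(lap_dir, "gyro.csv"))
  pr <- recs$pressure
  pm <- data.table::as.data.table(pr$frames)
  data.table::setnames(pm, paste0("p_r",
    rep(seq_len(pr$rows), each = pr$cols), "_c",
    rep(seq_len(pr$cols), pr$rows)))
  data.table::fwrite(cbind(data.table::data.table(t_unix = pr$t), pm),
                     file.path(lap_dir, "pressure.csv"))
  write_gpx(recs$gps, file.path(lap_dir, "track.gpx"))
  invisible(lap_dir)
}

#' Run the processing pipeline over an on-disk study bundle
#'
#' Reads the manifest, processes every lap (failures are isolated per lap
#' and recorded in the run manifest), applies lap-time QC, and returns the
#' same `processed_study` structure as [process_study()] plus a run
#' manifest with per-lap statuses.
#'
#' @param study_dir Directory written by [generate_study()].
#' @param out_dir Optional directory for tidy per-stride/per-step CSV
#'   outputs and the run manifest JSON.
#' @return A `processed_study` with an extra `run_manifest` element.
#' @export
run_pipeline <- function(study_dir, out_dir = NULL) {
  mf_path <- file.path(study_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", study_dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (!length(manifest$subjects)) stop("empty study: no subjects")
  course <- load_course(file.path(study_dir, "course.yaml"))
  gravity <- manifest$gravity %||% 9.81

  all_str <- list(); all_steps <- list(); all_hr <- list()
  lap_rows <- list(); statuses <- list(); quest <- list()
  for (su in manifest$subjects) {
    sid <- su$id
    for (lp in su$laps) {
      key <- paste(sid, lp$lap)
      entry <- list(foot_side = su$foot_side, sensors = manifest$sensors,
                    gravity = gravity)
      res <- tryCatch({
        recs <- read_lap(file.path(study_dir, lp$dir), entry)
        pl <- process_lap(recs, course, gravity = gravity)
        if (nrow(pl$strides))
          all_str[[key]] <- data.frame(Subject = sid, Lap = lp$lap,
                                       Config = lp$config, pl$strides)
        if (nrow(pl$steps))
          all_steps[[key]] <- data.frame(Subject = sid, Lap = lp$lap,
                                         Config = lp$config, pl$steps)
        all_hr[[key]] <- data.frame(Subject = sid, Lap = lp$lap,
                                    Config = lp$config,
                                    Section = names(pl$hr),
                                    hr = unname(pl$hr))
        lap_rows[[key]] <- data.frame(Subject = sid, Lap = lp$lap,
                                      Config = lp$config,
                                      duration_s = pl$lap_duration_s)
        "ok"
      }, error = function(e) paste("failed:", conditionMessage(e)))
      statuses[[key]] <- list(subject = sid, lap = lp$lap, status = res)
    }
    if (length(su$questionnaire)) {
      # manifest JSON stores the questionnaire row-wise
      qdf <- do.call(rbind, lapply(su$questionnaire, function(r)
        data.frame(item = r$item, config = r$config,
                   response = as.numeric(r$response),
                   stringsAsFactors = FALSE)))
      quest[[as.character(sid)]] <- data.frame(Subject = sid, qdf)
    }
  }
  if (!length(lap_rows)) stop("no lap processed successfully")
  lap_times <- do.call(rbind, lap_rows)
  qc_ok <- vapply(unique(lap_times$Subject), function(s)
    sum(lap_times$Subject == s) >= 2, logical(1))
  qc <- study_lap_qc(lap_times[lap_times$Subject %in%
                                 unique(lap_times$Subject)[qc_ok], ])

  out <- list(
    strides = do.call(rbind, all_str),
    steps = do.call(rbind, all_steps),
    hr = do.call(rbind, all_hr),
    lap_times = lap_times,
    qc = qc,
    questionnaire = do.call(rbind, quest),
    truth = NULL,
    config = NULL,
    run_manifest = list(seed = manifest$seed, laps = unname(statuses))
  )
  rownames(out$strides) <- rownames(out$hr) <- NULL
  class(out) <- "processed_study"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(out$strides, file.path(out_dir, "strides.csv"))
    data.table::fwrite(out$steps, file.path(out_dir, "steps.csv"))
    data.table::fwrite(out$hr, file.path(out_dir, "heart_rate.csv"))
    jsonlite::write_json(out$run_manifest,
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
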