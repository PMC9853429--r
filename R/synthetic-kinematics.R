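#' Generate per-subject ground-truth kinematics
#'
#' Draws the stride-level biomechanical truth for one subject across all of
#' their laps: per-stride running speed, stride time and length, peak
#' acceleration and jerk, medial-lateral acceleration range, peak eversion
#' velocity, per-step heel/toe contact areas and peak pressures, per-section
#' heart rate, lap condition labels (A-B-B-A with the first condition
#' randomized), and questionnaire responses.
#'
#' The generative model per metric is
#' `value = cell_mean(section, config) + intercept_s + slope_s * I(Wrap) + noise`
#' with `intercept_s ~ N(0, intercept_sd)`, `slope_s ~ N(0, slope_sd)` and
#' stride noise `~ N(0, stride_sd)`. The condition effect is carried by the
#' difference of the configured cell means; the subject slope is the
#' subject-specific deviation from it. With all SDs zero every stride equals
#' its cell mean exactly.
#'
#' @param config A [study_config()].
#' @param subject_id Integer in `1..n_subjects`.
#' @return A list of class `ground_truth` with elements `subject_id`,
#'   `foot_side`, `condition_order`, `laps` (list; each lap has a `strides`
#'   data.frame, hop times, `run_start_s`, `duration_s`, per-section heart
#'   rate) and `questionnaire`.
#' @export
generate_subject_kinematics <- function(config, subject_id) {
  validate_config(config)
  if (subject_id < 1 || subject_id > config$n_subjects)
    stop("subject_id out of range")
  set.seed(subject_seed(config, subject_id))

  mets <- c(metric_names(), "heart_rate")
  intercepts <- vapply(mets, function(m) rnorm(1, 0, sd_row(config, m)$intercept_sd),
                       numeric(1))
  slopes <- vapply(mets, function(m) rnorm(1, 0, sd_row(config, m)$slope_sd),
                   numeric(1))
  t_subj <- clamp(rnorm(1, config$stride_time$mean, config$stride_time$subject_sd),
                  0.65, 0.95)

  first <- sample(c("Wrap", "Lace"), 1)
  other <- setdiff(c("Wrap", "Lace"), first)
  npairs <- config$laps_per_subject / 2L
  condition_order <- rep(c(first, other, other, first),
                         length.out = config$laps_per_subject)
  if (npairs > 2L)  # extend A-B-B-A blocks if more than 4 laps requested
    condition_order <- rep(c(first, other, other, first),
                           length.out = config$laps_per_subject)

  qc_scale <- rep(1, config$laps_per_subject)
  if (config$qc_outlier && subject_id == config$n_subjects) {
    # slow one lap so that this subject's lap-time range is
    # ~qc_outlier_extra_s, accounting for their own speed intercept
    v_sec <- pmax(rowMeans(config$means$speed)[config$sections$section] +
                    intercepts[["speed"]], 0.5)
    nominal <- sum(config$sections$length_m / v_sec)
    qc_scale[2] <- nominal / (nominal + config$qc_outlier_extra_s)
  }

  laps <- vector("list", config$laps_per_subject)
  for (lap in seq_len(config$laps_per_subject)) {
    cond <- condition_order[lap]
    strides <- list()
    for (si in seq_len(nrow(config$sections))) {
      sec <- config$sections$section[si]
      len <- config$sections$length_m[si]
      rows <- list()
      covered <- 0
      while (covered < len) {
        ti <- clamp(rnorm(1, t_subj, config$stride_time$stride_sd),
                    config$stride_time$min, config$stride_time$max)
        draw <- function(m) {
          clamp(config$means[[m]][sec, cond] + intercepts[[m]] +
                  slopes[[m]] * (cond == "Wrap") +
                  rnorm(1, 0, sd_row(config, m)$stride_sd),
                config$clamp_lo[[m]], config$clamp_hi[[m]])
        }
        vi <- draw("speed") * qc_scale[lap]
        rows[[length(rows) + 1L]] <- data.frame(
          section = sec, stride_time = ti, speed = vi,
          stride_length = vi * ti,
          peak_acc = draw("peak_acc"), peak_jerk = draw("peak_jerk"),
          eversion_vel = draw("eversion_vel"), ml_range = draw("ml_range"),
          heel_area = draw("heel_area"), toe_area = draw("toe_area"),
          heel_peak = draw("heel_peak"), toe_peak = draw("toe_peak"),
          stringsAsFactors = FALSE)
        covered <- covered + vi * ti
      }
      strides[[si]] <- do.call(rbind, rows)
    }
    strides <- do.call(rbind, strides)
    run_start <- config$hops$times_s[config$hops$n] + config$hops$settle_s
    t0 <- run_start + config$hops$quiet_after_s
    strides$t_start <- t0 + c(0, cumsum(strides$stride_time))[seq_len(nrow(strides))]
    hr <- vapply(config$sections$section, function(sec)
      clamp(config$means$heart_rate[sec, cond] + intercepts[["heart_rate"]] +
              slopes[["heart_rate"]] * (cond == "Wrap") +
              rnorm(1, 0, sd_row(config, "heart_rate")$stride_sd),
            config$clamp_lo[["heart_rate"]], config$clamp_hi[["heart_rate"]]),
      numeric(1))
    laps[[lap]] <- list(
      lap = lap, config = cond,
      strides = strides,
      hop_times_s = config$hops$times_s,
      run_start_s = run_start,
      run_duration_s = config$hops$quiet_after_s + sum(strides$stride_time),
      duration_s = run_start + config$hops$quiet_after_s +
        sum(strides$stride_time) + config$hops$tail_s,
      heart_rate = hr,
      rpe = round(clamp(rnorm(1, 5 - 0.1 * (cond == "Wrap"), 1.2), 0, 10)),
      seed = lap_seed(config, subject_id, lap)
    )
  }

  q <- config$questionnaire
  questionnaire <- do.call(rbind, lapply(seq_len(nrow(q)), function(i) {
    data.frame(
      item = q$item[i],
      config = c("Wrap", "Lace"),
      response = round(clamp(c(rnorm(1, q$wrap_mean[i], q$wrap_sd[i]),
                               rnorm(1, q$lace_mean[i], q$lace_sd[i])), 0, 10)),
      stringsAsFactors = FALSE)
  }))

  out <- list(subject_id = subject_id, foot_side = "right",
              condition_order = condition_order, laps = laps,
              questionnaire = questionnaire)
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  ns <- vapply(x$laps, function(l) nrow(l$strides), integer(1))
  cat(sprintf("<ground_truth> subject %d (%s foot), laps %s, strides %s\n",
              x$subject_id, x$foot_side,
              paste(x$condition_order, collapse = "-"),
              paste(ns, collapse = "/")))
  invisible(x)
}
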