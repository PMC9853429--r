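#' Per-stride IMU metrics
#'
#' Peak acceleration magnitude, peak jerk magnitude, medial-lateral
#' acceleration range (from the 50 Hz zero-phase-filtered fused signal) and
#' peak eversion angular velocity (from the raw gyroscope filtered at 30 Hz,
#' within the first 20 % of the stride).
#'
#' @name imu_metrics
NULL

#' Peak acceleration and jerk of one stride
#'
#' @param stride One row of a `stride_table` (list or data.frame row with
#'   `start`, `end`).
#' @param fused50 n x 3 fused acceleration filtered at 50 Hz (m/s^2), full
#'   lap.
#' @param rate_hz Sampling rate.
#' @return List: `peak_acc` (max vector norm, m/s^2), `peak_jerk` (max norm
#'   of the central-difference derivative, m/s^3). NA for strides shorter
#'   than 3 samples.
#' @export
peak_acc_jerk <- function(stride, fused50, rate_hz) {
  idx <- stride$start:(stride$end - 1L)
  if (length(idx) < 3)
    return(list(peak_acc = NA_real_, peak_jerk = NA_real_))
  seg <- fused50[idx, , drop = FALSE]
  peak_acc <- max(sqrt(rowSums(seg^2)))
  jerk <- central_diff(seg) * rate_hz
  list(peak_acc = peak_acc, peak_jerk = max(sqrt(rowSums(jerk^2))))
}

#' Medial-lateral acceleration range of one stride
#'
#' @inheritParams peak_acc_jerk
#' @param axes Named axis map of the recording (`anterior`, `mediolateral`,
#'   `vertical` column indices).
#' @return max - min of the mediolateral filtered acceleration, m/s^2.
#' @export
ml_acceleration_range <- function(stride, fused50, axes) {
  if (!("mediolateral" %in% names(axes)))
    stop("unknown axis convention: no mediolateral axis in the axis map")
  ml <- fused50[stride$start:(stride$end - 1L), axes[["mediolateral"]]]
  max(ml) - min(ml)
}

#' Peak eversion angular velocity of one stride
#'
#' The raw gyroscope is filtered with a second-order zero-phase 30 Hz
#' Butterworth; the signed maximum toward eversion is taken within
#' `[contact, contact + window_frac * stride duration)`. The sign convention
#' (eversion positive) is resolved from the foot side: for a right foot with
#' the frontal-plane channel as roll about the anterior axis, eversion is a
#' negative roll rate, mirrored for the left foot.
#'
#' @param stride One row of a `stride_table`.
#' @param gyro30 n x 3 gyroscope filtered at 30 Hz (deg/s), full lap.
#' @param frontal_axis Column index of the frontal-plane channel.
#' @param side `"left"` or `"right"`.
#' @param window_frac Fraction of the stride after contact to search.
#' @return Peak eversion velocity, deg/s (signed maximum toward eversion).
#' @export
peak_eversion_velocity <- function(stride, gyro30, frontal_axis, side,
                                   window_frac = 0.20) {
  if (is.null(side) || !side %in% c("left", "right"))
    stop("foot side missing: cannot resolve the eversion sign")
  n_str <- stride$end - stride$start
  if (n_str < 10) return(NA_real_)
  wend <- stride$start + max(1L, floor(window_frac * n_str)) - 1L
  seg <- gyro30[stride$start:wend, frontal_axis]
  sgn <- if (side == "right") -1 else 1
  max(sgn * seg)
}

# All IMU metrics for every stride of a lap.
lap_imu_metrics <- function(strides, fused50, gyro30, axes, frontal_axis,
                            side, rate_hz) {
  ns <- nrow(strides)
  out <- data.frame(peak_acc = rep(NA_real_, ns), peak_jerk = NA_real_,
                    ml_range = NA_real_, eversion_vel = NA_real_)
  for (i in seq_len(ns)) {
    s <- strides[i, ]
    pj <- peak_acc_jerk(s, fused50, rate_hz)
    out$peak_acc[i] <- pj$peak_acc
    out$peak_jerk[i] <- pj$peak_jerk
    out$ml_range[i] <- ml_acceleration_range(s, fused50, axes)
    out$eversion_vel[i] <- peak_eversion_velocity(s, gyro30, frontal_axis,
                                                  side)
  }
  out
}
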