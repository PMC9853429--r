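#' Zero-phase low-pass Butterworth filter
#'
#' Second-order (by default) low-pass Butterworth applied forward and
#' backward, so the net phase response is zero at every frequency and the
#' squared magnitude response is applied twice (gain 0.5 at the cutoff).
#' The signal is reflection-padded at both ends before filtering to suppress
#' edge transients.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param rate_hz Sampling rate in Hz.
#' @param order Filter order for each pass.
#' @return Filtered signal, same shape as `x`.
#' @export
zero_phase_lowpass <- function(x, cutoff_hz, rate_hz, order = 2) {
  if (cutoff_hz >= rate_hz / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         rate_hz / 2, " Hz)")
  if (is.matrix(x))
    return(apply(x, 2, zero_phase_lowpass, cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz, order = order))
  n <- length(x)
  if (n <= 3 * order)
    stop("signal too short for the filter (length ", n, ")")
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(n - 1L, max(3L * order, ceiling(3 * rate_hz / cutoff_hz)))
  # odd reflection about the end points
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

#' Detect the three synchronization hops
#'
#' Each lap begins with three vertical hops marking the start of the run.
#' Bursts are found as peaks of the deviation of the acceleration norm from
#' gravity exceeding a threshold, separated by a refractory gap; the run
#' start is placed a fixed settle time after the third hop's landing burst.
#'
#' @param fused A `fused_accel` (see [fuse_accelerometers()]) or any list
#'   with `t` (seconds) and `accel` (n x 3 matrix, m/s^2).
#' @param n_hops Number of hops to find.
#' @param search_s Search window from the start of the recording, seconds.
#' @param threshold_ms2 Burst threshold on |norm - g|, m/s^2.
#' @param refractory_s Minimum spacing between hop bursts.
#' @param settle_s Gap between the detected third burst and the returned run
#'   start.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return Integer sample index (on the low-g time base) of the first sample
#'   of the run.
#' @export
detect_hops <- function(fused, n_hops = 3, search_s = 30,
                        threshold_ms2 = 3 * 9.81, refractory_s = 0.3,
                        settle_s = 0.2, gravity = 9.81) {
  t <- fused$t
  rate <- (length(t) - 1) / (t[length(t)] - t[1])  # jitter-robust mean interval
  win <- which(t - t[1] <= search_s)
  dev <- abs(sqrt(rowSums(fused$accel[win, , drop = FALSE]^2)) - gravity)
  above <- which(dev > threshold_ms2)
  if (!length(above))
    stop("no synchronization hops found in the first ", search_s, " s")
  peaks <- integer(0)
  refr <- round(refractory_s * rate)
  i <- 1L
  while (i <= length(above) && length(peaks) < n_hops) {
    j <- above[i]
    grp <- above[above >= j & above <= j + refr]
    peaks <- c(peaks, grp[which.max(dev[grp])])
    i <- match(TRUE, above > j + refr)
    if (is.na(i)) break
  }
  if (length(peaks) < n_hops)
    stop("only ", length(peaks), " of ", n_hops,
         " synchronization hops found")
  min(length(t), peaks[n_hops] + round(settle_s * rate))
}

#' Segment running strides from the jerk-squared magnitude
#'
#' Foot contacts are impact transients in the fused acceleration. The
#' detector differentiates the (unfiltered) fused signal, sums the squared
#' jerk over axes, smooths it with a short moving average, and picks peaks
#' exceeding an adaptive threshold (`k_mult` times the rolling median) with a
#' refractory period. Strides span contact to next contact of the same foot;
#' stride times outside the physiological QC band are flagged.
#'
#' @param fused A `fused_accel`.
#' @param run_start First sample to consider (from [detect_hops()]).
#' @param k_mult Threshold multiplier on the rolling median.
#' @param refractory_s Minimum time between contacts, seconds.
#' @param median_win_s Rolling-median window, seconds.
#' @param smooth_n Moving-average length (samples) for the jerk-squared
#'   series.
#' @param qc_range_s Stride-time QC band `(min, max)` in seconds.
#' @return A data.frame of class `stride_table`: `start`, `end` (half-open
#'   sample span), `contact` (= start), `stride_time`, `first`, `last`,
#'   `qc_pass`. Zero rows when no strides are detected.
#' @export
segment_strides <- function(fused, run_start = 1L, k_mult = 10,
                            refractory_s = 0.4, median_win_s = 1.0,
                            smooth_n = 9L, qc_range_s = c(0.4, 2.0)) {
  t <- fused$t
  rate <- (length(t) - 1) / (t[length(t)] - t[1])  # jitter-robust mean interval
  acc <- fused$accel[run_start:nrow(fused$accel), , drop = FALSE]
  n <- nrow(acc)
  empty <- data.frame(start = integer(0), end = integer(0),
                      contact = integer(0), stride_time = numeric(0),
                      first = logical(0), last = logical(0),
                      qc_pass = logical(0))
  class(empty) <- c("stride_table", "data.frame")
  if (n < smooth_n + 3) return(empty)

  jerk <- apply(acc, 2, function(col) c(diff(col), 0)) * rate
  j2 <- rowSums(jerk^2)
  kern <- rep(1 / smooth_n, smooth_n)
  j2s <- as.numeric(stats::filter(j2, kern, sides = 2))
  j2s[is.na(j2s)] <- 0
  mw <- round(median_win_s * rate)
  if (mw %% 2 == 0) mw <- mw + 1L
  mw <- min(mw, if (n %% 2 == 0) n - 1L else n)
  med <- stats::runmed(j2s, mw, endrule = "constant")
  thr <- k_mult * pmax(med, 1e-12)

  cand <- which(j2s > thr)
  if (!length(cand)) return(empty)
  refr <- round(refractory_s * rate)
  contacts <- integer(0)
  i <- 1L
  while (i <= length(cand)) {
    j <- cand[i]
    grp <- cand[cand >= j & cand <= j + refr]
    contacts <- c(contacts, grp[which.max(j2s[grp])])
    nxt <- match(TRUE, cand > contacts[length(contacts)] + refr)
    if (is.na(nxt)) break
    i <- nxt
  }
  if (length(contacts) < 2) return(empty)

  contacts <- contacts + run_start - 1L
  ns <- length(contacts) - 1L
  stride_time <- diff(contacts) / rate
  out <- data.frame(
    start = contacts[seq_len(ns)],
    end = contacts[seq_len(ns) + 1L],
    contact = contacts[seq_len(ns)],
    stride_time = stride_time,
    first = seq_len(ns) == 1L,
    last = seq_len(ns) == ns,
    qc_pass = stride_time >= qc_range_s[1] & stride_time <= qc_range_s[2]
  )
  class(out) <- c("stride_table", "data.frame")
  out
}
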