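#' Stance detection and regional plantar-pressure metrics
#'
#' Stance phases are found on the total insole force (sum of sensel
#' pressures times sensel area): candidate events are threshold crossings at
#' a fraction of the per-lap median peak force, and each event is refined by
#' descending the force curve from the adjacent steepest-gradient frame to
#' the local baseline. Heel and toe regions are the rear and front 20 % of
#' the sensor rows; contact area is the fraction of a region's sensels
#' loaded above a threshold, averaged over stance frames.
#'
#' @name pressure_metrics
NULL

#' Total insole force per frame
#'
#' @param rec A `pressure_recording` (pressures in kPa).
#' @return Numeric vector of force in newtons
#'   (kPa * cm^2 = 0.1 N).
#' @export
total_force <- function(rec) {
  rowSums(rec$frames) * rec$sensel_area_cm2 * 0.1
}

#' Detect stance phases on the total-force curve
#'
#' @param force Total force per frame (any consistent unit).
#' @param threshold_frac Candidate threshold as a fraction of the median
#'   peak force of the lap.
#' @param min_stance_frames,max_stance_frames Duration bounds for a stance.
#' @return Integer matrix with columns `contact`, `toe_off`: half-open frame
#'   intervals, non-overlapping and ordered. Zero rows for an all-zero
#'   force.
#' @export
detect_stance <- function(force, threshold_frac = 0.05,
                          min_stance_frames = 5L, max_stance_frames = 200L) {
  n <- length(force)
  none <- matrix(integer(0), ncol = 2,
                 dimnames = list(NULL, c("contact", "toe_off")))
  if (!any(force > 0)) return(none)
  above0 <- force > max(force) * 0.02
  # median peak: median of per-burst maxima at a coarse split
  r <- rle(above0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bursts <- which(r$values)
  if (!length(bursts)) return(none)
  peaks <- vapply(bursts, function(b) max(force[starts[b]:ends[b]]),
                  numeric(1))
  thr <- threshold_frac * stats::median(peaks)

  grad <- c(0, diff(force))
  eps <- thr / 10
  out <- list()
  for (b in bursts) {
    s <- starts[b]; e <- ends[b]
    if (max(force[s:e]) < thr) next
    lo <- max(1L, s - 3L); hi <- min(n, e + 3L)
    gseg <- grad[lo:hi]
    # contact: descend the force curve backward from the steepest rising
    # gradient until it stops falling (local baseline); contact is the first
    # rising frame after the baseline
    up <- lo + which.max(gseg) - 1L
    c0 <- up
    while (c0 > 1L && force[c0 - 1L] < force[c0] - eps) c0 <- c0 - 1L
    contact <- min(c0 + 1L, up)
    # toe-off: descend forward from the steepest falling gradient to the
    # local baseline; the baseline frame is the exclusive bound
    dn <- lo + which.min(gseg) - 1L
    t0 <- dn
    while (t0 < n && force[t0 + 1L] < force[t0] - eps) t0 <- t0 + 1L
    if (t0 - contact >= min_stance_frames &&
        t0 - contact <= max_stance_frames)
      out[[length(out) + 1L]] <- c(contact, t0)
  }
  if (!length(out)) return(none)
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1) {
    keep <- c(TRUE, m[-1, 1] > m[-nrow(m), 2] - 1L & diff(m[, 1]) > 0)
    m <- m[keep, , drop = FALSE]
  }
  colnames(m) <- c("contact", "toe_off")
  m
}

#' Heel and toe region masks
#'
#' Heel = rear `ceiling(heel_frac * rows)` rows; toe = front
#' `ceiling(toe_frac * rows)` rows (row 1 is the front of the sensor).
#'
#' @param grid_shape Integer `c(rows, cols)`.
#' @param heel_frac,toe_frac Region fractions of the sensor length.
#' @return List with logical matrices `heel` and `toe` of shape
#'   `grid_shape`; always disjoint.
#' @export
region_masks <- function(grid_shape, heel_frac = 0.20, toe_frac = 0.20) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (rows < 5) stop("pressure grid needs at least 5 rows")
  if (heel_frac + toe_frac > 1) stop("region fractions sum above 1")
  nh <- ceiling(heel_frac * rows)
  nt <- ceiling(toe_frac * rows)
  if (nh + nt > rows) stop("region fractions overlap on this grid")
  heel <- matrix(FALSE, rows, cols)
  toe <- matrix(FALSE, rows, cols)
  heel[(rows - nh + 1L):rows, ] <- TRUE
  toe[1:nt, ] <- TRUE
  list(heel = heel, toe = toe)
}

#' Regional contact area and peak pressure for one step
#'
#' Per stance frame, a region's contact area is 100 x (loaded sensels) /
#' (region sensels), a sensel being loaded when its pressure exceeds
#' `load_threshold_kpa`; the reported area is the mean over stance frames.
#' The regional peak pressure is the maximum sensel pressure in the region
#' over the stance.
#'
#' @param rec A `pressure_recording`.
#' @param interval Integer `c(contact, toe_off)` half-open frame interval.
#' @param masks Region masks from [region_masks()].
#' @param load_threshold_kpa Loaded-sensel threshold, kPa.
#' @return List: `heel_contact_area`, `toe_contact_area` (percent),
#'   `peak_heel_pressure`, `peak_toe_pressure` (kPa), `contact`, `toe_off`.
#' @export
step_metrics <- function(rec, interval, masks, load_threshold_kpa = 2.5) {
  c0 <- interval[1]; t0 <- interval[2]
  if (t0 <= c0 || c0 < 1 || t0 > nrow(rec$frames) + 1L)
    stop("empty or out-of-range stance interval")
  fr <- rec$frames[c0:(t0 - 1L), , drop = FALSE]
  heel_cols <- which(as.vector(t(masks$heel)))
  toe_cols <- which(as.vector(t(masks$toe)))
  # frames store sensels row-major (r1c1, r1c2, ...): mask vectorized by row
  area <- function(cols) {
    sub <- fr[, cols, drop = FALSE]
    100 * mean(rowMeans(sub > load_threshold_kpa))
  }
  list(
    heel_contact_area = area(heel_cols),
    toe_contact_area = area(toe_cols),
    peak_heel_pressure = max(fr[, heel_cols]),
    peak_toe_pressure = max(fr[, toe_cols]),
    contact = c0, toe_off = t0
  )
}

# All steps of a lap, gated at run_start (seconds on the recording clock).
lap_pressure_metrics <- function(rec, run_start_time, masks,
                                 load_threshold_kpa = 2.5) {
  force <- total_force(rec)
  iv <- detect_stance(force)
  if (!nrow(iv)) {
    return(data.frame(contact_time = numeric(0), heel_area = numeric(0),
                      toe_area = numeric(0), heel_peak = numeric(0),
                      toe_peak = numeric(0)))
  }
  tt <- rec$t - rec$t[1]
  keep <- tt[iv[, "contact"]] >= run_start_time
  iv <- iv[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    sm <- step_metrics(rec, iv[i, ], masks, load_threshold_kpa)
    data.frame(contact_time = tt[iv[i, "contact"]],
               heel_area = sm$heel_contact_area,
               toe_area = sm$toe_contact_area,
               heel_peak = sm$peak_heel_pressure,
               toe_peak = sm$peak_toe_pressure)
  })
  do.call(rbind, rows)
}
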