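make_rec <- function(frames, rows, cols, rate = 100) {
  structure(list(t = (seq_len(nrow(frames)) - 1) / rate, frames = frames,
                 rows = rows, cols = cols, rate = rate,
                 sensel_area_cm2 = 1),
            class = "pressure_recording")
}

test_that("region masks take the front and rear 20% of rows, disjoint", {
  m <- region_masks(c(30, 9))
  heel_rows <- which(apply(m$heel, 1, any))
  toe_rows <- which(apply(m$toe, 1, any))
  expect_equal(heel_rows, 25:30)   # last ceiling(0.2*30) = 6 rows
  expect_equal(toe_rows, 1:6)
  m5 <- region_masks(c(5, 4))
  expect_equal(which(apply(m5$heel, 1, any)), 5L)
  expect_equal(which(apply(m5$toe, 1, any)), 1L)
  for (r in 5:50) {
    mm <- region_masks(c(r, 7))
    expect_false(any(mm$heel & mm$toe))
  }
  expect_error(region_masks(c(30, 9), 0.6, 0.6), "sum")
  expect_error(region_masks(c(4, 9)), "5 rows")
})

test_that("stance events land on the ramps of a trapezoidal force pulse", {
  force <- c(rep(0, 50), seq(0, 900, length.out = 10), rep(900, 30),
             seq(900, 0, length.out = 10), rep(0, 50))
  iv <- detect_stance(force)
  expect_equal(nrow(iv), 1L)
  expect_lte(abs(iv[1, "contact"] - 51L), 1L)    # ramp onset
  expect_lte(abs(iv[1, "toe_off"] - 99L), 2L)    # ramp end
  expect_equal(nrow(detect_stance(rep(0, 500))), 0L)
})

test_that("step metrics match constructed loading patterns", {
  rows <- 25L; cols <- 9L
  masks <- region_masks(c(rows, cols))
  heel_cols <- which(as.vector(t(masks$heel)))
  frames <- matrix(0, 40, rows * cols)
  frames[11:30, heel_cols] <- 50
  rec <- make_rec(frames, rows, cols)
  sm <- step_metrics(rec, c(11L, 31L), masks)
  expect_equal(sm$heel_contact_area, 100)
  expect_equal(sm$peak_heel_pressure, 50)
  expect_equal(sm$toe_contact_area, 0)
  # half the heel sensels loaded every frame -> 50% (even-count grid)
  rows2 <- 20L
  masks2 <- region_masks(c(rows2, cols))
  heel2 <- which(as.vector(t(masks2$heel)))
  frames2 <- matrix(0, 40, rows2 * cols)
  frames2[11:30, heel2[seq_len(length(heel2) / 2)]] <- 30
  sm2 <- step_metrics(make_rec(frames2, rows2, cols), c(11L, 31L), masks2)
  expect_equal(sm2$heel_contact_area, 50)
  expect_error(step_metrics(rec, c(20L, 20L), masks), "empty")
})

test_that("adding heel pressure never decreases heel area or peak", {
  tl <- tiny_lap()
  rec <- tl$recs$pressure
  masks <- region_masks(c(rec$rows, rec$cols))
  iv <- detect_stance(total_force(rec))
  iv <- iv[5, , drop = TRUE]
  base <- step_metrics(rec, iv, masks)
  heel_cols <- which(as.vector(t(masks$heel)))
  set.seed(11)
  for (rep in 1:5) {
    rec2 <- rec
    bump_cols <- sample(heel_cols, 10)
    rec2$frames[iv[1]:(iv[2] - 1L), bump_cols] <-
      rec2$frames[iv[1]:(iv[2] - 1L), bump_cols] + runif(1, 1, 100)
    more <- step_metrics(rec2, iv, masks)
    expect_gte(more$heel_contact_area, base$heel_contact_area)
    expect_gte(more$peak_heel_pressure, base$peak_heel_pressure)
  }
})

test_that("synthetic stance phases are counted and measured correctly", {
  tp <- tiny_processed()
  st <- tp$truth$laps[[1]]$strides
  steps <- tp$pl$steps
  expect_equal(nrow(steps), nrow(st))
  i <- vapply(steps$contact_time, function(x)
    which.min(abs(st$t_start - x)), integer(1))
  expect_true(!anyDuplicated(i))
  # contact-area truth is rounded to the sensel grid (45 heel sensels)
  expect_lt(mean(abs(steps$heel_area - st$heel_area[i])), 1.5)
  expect_lt(mean(abs(steps$toe_area - st$toe_area[i])), 1.5)
  expect_lt(stats::median(abs(steps$heel_peak - st$heel_peak[i]) /
                            st$heel_peak[i]), 0.03)
})
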