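px_recording <- function(xl, yl, xr = xl, yr = yl, dist_mm = 600,
                         valid = TRUE, screen = screen_geometry()) {
  n <- length(xl)
  list(samples = data.frame(t_s = (seq_len(n) - 1) / 60, xl_px = xl,
                            yl_px = yl, xr_px = xr, yr_px = yr,
                            dist_mm = rep_len(dist_mm, n),
                            valid_l = rep_len(valid, n),
                            valid_r = rep_len(valid, n)),
       screen = screen)
}

test_that("pixel-to-degree conversion is anchored at the screen centre", {
  for (d in c(450, 600, 750)) {
    tr <- pixels_to_degrees(px_recording(960, 540, dist_mm = d), "left")
    expect_equal(tr$x, 0)
    expect_equal(tr$y, 0)
  }
})

test_that("the study screen subtends 46 x 24 degrees at 60 cm", {
  rec <- px_recording(c(0, 1920, 960, 960), c(540, 540, 0, 1080))
  tr <- pixels_to_degrees(rec, "left")
  expect_equal(tr$x[2] - tr$x[1], 2 * atan(25.5 / 60) * 180 / pi)
  expect_equal(round(tr$x[2] - tr$x[1]), 46)
  expect_equal(round(tr$y[3] - tr$y[4]), 24)
  # right edge: atan(25.5/60) ~ +23.03 deg; pixel y runs downward
  expect_equal(tr$x[2], atan(25.5 / 60) * 180 / pi, tolerance = 1e-10)
  expect_true(tr$y[3] > 0 && tr$y[4] < 0)
})

test_that("per-sample distance is used and bad distances invalidate", {
  rec <- px_recording(c(1920, 1920, 1920), c(540, 540, 540),
                      dist_mm = c(500, 700, -5))
  tr <- pixels_to_degrees(rec, "left")
  expect_equal(tr$x[1], atan(25.5 / 50) * 180 / pi)
  expect_equal(tr$x[2], atan(25.5 / 70) * 180 / pi)
  expect_false(tr$valid[3])
  # missing distance falls back to nominal
  rec$samples$dist_mm <- NA_real_
  tr2 <- pixels_to_degrees(rec, "left")
  expect_true(all(tr2$valid))
  expect_equal(tr2$x[1], atan(25.5 / 60) * 180 / pi)
})

test_that("binocular merge averages, falls back, and checks lengths", {
  l <- make_trace(c(1, 1, NA), c(0, 0, NA), valid = c(TRUE, TRUE, FALSE))
  r <- make_trace(c(3, 3, 3), c(0, 0, 0), valid = TRUE)
  m <- merge_binocular(l, r)
  expect_equal(m$x, c(2, 2, 3))
  expect_true(all(m$valid))
  # both equal -> identity
  m2 <- merge_binocular(r, r)
  expect_equal(m2$x, r$x)
  # neither valid -> invalid
  l$valid <- r$valid <- FALSE
  expect_false(any(merge_binocular(l, r)$valid))
  expect_error(merge_binocular(make_trace(1:3, 1:3), make_trace(1:4, 1:4)),
               "length mismatch")
})

test_that("a planted 10-degree three-sample ramp yields exactly one saccade", {
  # steps 6, 2, 2 deg: onset speed 360 deg/s (accel 21600), stays > 120
  ev <- detect_events(step_trace(pre = 24, post = 24, steps = c(6, 8, 10)))
  expect_equal(nrow(ev$saccades), 1)
  expect_equal(ev$saccades$amplitude, 10, tolerance = 0.1)
  expect_equal(ev$saccades$peak_velocity, 360)
  expect_equal(nrow(ev$fixations), 2)
  expect_equal(nrow(ev$discarded), 0)
})

test_that("sub-amplitude saccades are discarded with reason small_saccade", {
  # overshoot profile: +2.8 then -2.5 -> amplitude 0.3, suprathreshold speed
  ev <- detect_events(step_trace(steps = c(2.8, 0.3)))
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(ev$discarded$reason, "small_saccade")
})

test_that("a stationary trace yields no saccades", {
  set.seed(7)
  n <- 300  # 5 s
  tr <- make_trace(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05))
  ev <- detect_events(tr)
  expect_equal(nrow(ev$saccades), 0)
  # 5 s of stillness is pursuit-like: one long fixation, discarded
  expect_true(nrow(ev$fixations) >= 1 ||
                any(ev$discarded$reason == "long_fixation"))
})

test_that("fixations longer than 500 ms are discarded", {
  tr <- step_trace(pre = 40, post = 20, steps = c(6, 8, 10))  # pre: 0.65 s
  ev <- detect_events(tr)
  expect_equal(sum(ev$discarded$reason == "long_fixation"), 1)
  expect_equal(nrow(ev$fixations), 1)
  expect_lt(ev$fixations$duration, 0.5 + 1e-9)
})

test_that("doubling all coordinates doubles every reported amplitude", {
  set.seed(11)
  cfg <- tiny_cohort(seed = 2, effect = quiet_effect())
  rec <- generate_cohort(cfg)[[1]]
  tr <- recording_to_trace(rec)
  ev1 <- detect_events(tr)
  tr2 <- tr; tr2$x <- 2 * tr$x; tr2$y <- 2 * tr$y
  ev2 <- detect_events(tr2)
  common <- intersect(round(ev1$saccades$t_on, 6), round(ev2$saccades$t_on, 6))
  a1 <- ev1$saccades$amplitude[match(common, round(ev1$saccades$t_on, 6))]
  a2 <- ev2$saccades$amplitude[match(common, round(ev2$saccades$t_on, 6))]
  expect_gt(length(common), 5)
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("short invalid gaps are bridged, long gaps split events", {
  tr <- make_trace(rep(1, 28), rep(0, 28))
  tr$valid[10:13] <- FALSE                      # 4 samples ~ 67 ms: bridged
  ev <- detect_events(tr)
  expect_equal(nrow(ev$saccades), 0)
  expect_false(any(ev$discarded$reason == "invalid_gap"))
  expect_equal(nrow(ev$fixations), 1)

  tr2 <- make_trace(rep(1, 55), rep(0, 55))
  tr2$valid[20:35] <- FALSE                     # 16 samples ~ 267 ms: split
  ev2 <- detect_events(tr2)
  expect_true(any(ev2$discarded$reason == "invalid_gap"))
  expect_equal(nrow(ev2$fixations), 2)
})

test_that("empty or all-invalid traces are rejected", {
  expect_error(detect_events(make_trace(numeric(0), numeric(0))),
               "no usable samples")
  tr <- make_trace(1:10, 1:10, valid = FALSE)
  expect_error(detect_events(tr), "no usable samples")
})

test_that("event CSV export is time-ordered and complete", {
  ev <- detect_events(step_trace(pre = 40, post = 24, steps = c(6, 8, 10)))
  path <- tempfile(fileext = ".csv")
  write_events(ev, "P01", "video1", path)
  out <- read.csv(path)
  expect_equal(nrow(out),
               nrow(ev$saccades) + nrow(ev$fixations) + nrow(ev$discarded))
  expect_true(!is.unsorted(out$t_on))
  expect_true(all(c("participant", "stimulus", "type", "amplitude_deg",
                    "reason") %in% names(out)))
})
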