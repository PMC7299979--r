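test_that("median amplitude summarises retained saccades", {
  expect_equal(median_amplitude(c(2)), 2)
  expect_equal(median_amplitude(c(1, 3, 10)), 3)
  expect_true(is.na(median_amplitude(numeric(0))))
})

test_that("BCEA matches the closed form on constructed samples", {
  # construct endpoints with *exact* sample SDs 2 and 1 and zero correlation
  set.seed(1)
  n <- 50
  a <- rnorm(n); b <- rnorm(n)
  b <- residuals(lm(b ~ a))                      # exactly uncorrelated
  a <- (a - mean(a)) / sd(a) * 2
  b <- (b - mean(b)) / sd(b) * 1
  ep <- data.frame(dx = a, dy = b)
  k <- -log(1 - 0.95)
  expect_equal(bcea95(ep), 2 * k * pi * 2 * 1, tolerance = 1e-10)
  expect_equal(2 * k * pi * 2, 37.65, tolerance = 0.01)
})

test_that("BCEA is invariant under rotation of the endpoint cloud", {
  set.seed(2)
  ep <- data.frame(dx = rnorm(200, 0, 2), dy = rnorm(200, 0, 0.7))
  b0 <- bcea95(ep)
  for (th in c(0.3, 1.1, 2.5)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    r <- as.matrix(ep) %*% R
    expect_equal(bcea95(data.frame(dx = r[, 1], dy = r[, 2])), b0,
                 tolerance = 1e-9)
  }
})

test_that("degenerate endpoint clouds flag rather than error", {
  same <- data.frame(dx = rep(1, 5), dy = rep(2, 5))
  out <- bcea95(same)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
  line <- data.frame(dx = 1:5, dy = 2 * (1:5))   # perfectly collinear
  expect_equal(as.numeric(bcea95(line)), 0)
  expect_true(attr(bcea95(line), "degenerate"))
  expect_equal(as.numeric(bcea95(data.frame(dx = 1:2, dy = 1:2))), 0)
})

mask_one_cell <- function() {
  g <- grid_242()
  g$sensitivity <- 35
  g$sensitivity[g$x == 3 & g$y == 9] <- 5
  ivf <- integrate_fields(monocular_field("left", g, -2),
                          monocular_field("right", g, -2))
  scotoma_mask(ivf, 20)
}

fake_events <- function(dx, dy) {
  structure(list(saccades = data.frame(x_start = 0, y_start = 0,
                                       x_end = dx, y_end = dy,
                                       amplitude = sqrt(dx^2 + dy^2))),
            class = "event_sequence")
}

test_that("SLV counts aligned endpoints inside the gaze-relative mask", {
  m <- mask_one_cell()            # cell [0,6) x [6,12)
  ev <- fake_events(dx = c(1, 2, 3, -5, 0, 1, 8, 2, 3, 1),
                    dy = c(7, 8, 9, 7, -3, 1, 8, 11, 13, 6.5))
  # inside: (1,7), (2,8), (3,9), (2,11), (1,6.5) -> 5 of 10
  expect_equal(slv(ev, m), 0.5)
  ev3 <- fake_events(dx = c(1, 2, -1), dy = c(7, 8, 7))
  expect_equal(slv(ev3, m), 2 / 3)
  # saturation and empty mask
  expect_equal(slv(fake_events(c(1, 2), c(7, 8)), m), 1)
  g <- grid_242(); g$sensitivity <- 35
  empty <- scotoma_mask(integrate_fields(monocular_field("left", g, 0),
                                         monocular_field("right", g, 0)), 20)
  expect_equal(slv(ev, empty), 0)
  # adding a saccade landing outside the mask strictly decreases SLV
  ev_more <- fake_events(c(1, 2, -1, 10), c(7, 8, 7, -10))
  expect_lt(slv(ev_more, m), slv(ev3, m))
})

test_that("KDE density matches its closed-form peak and is permutation-safe", {
  m1 <- kde_fit(data.frame(x = 0, y = 0), h = 1.5, allow_single = TRUE)
  expect_equal(kde_eval(m1, 0, 0), 1 / (2 * pi * 1.5^2), tolerance = 1e-12)
  expect_equal(round(kde_eval(m1, 0, 0), 4), 0.0707)
  expect_lt(kde_eval(m1, 20, 0), 1e-10)

  set.seed(3)
  pts <- data.frame(x = rnorm(8), y = rnorm(8))
  m <- kde_fit(pts, h = 1.5)
  mp <- kde_fit(pts[sample(8), ], h = 1.5)
  xs <- runif(20, -3, 3); ys <- runif(20, -3, 3)
  expect_equal(kde_eval(m, xs, ys), kde_eval(mp, xs, ys), tolerance = 1e-14)
  expect_true(all(kde_eval(m, xs, ys) >= 0))
  expect_error(kde_fit(data.frame(x = 1, y = 1)), ">= 2")
  expect_error(kde_fit(pts, h = 0), "> 0")
})

test_that("KDE integrates to one over a wide box", {
  set.seed(4)
  m <- kde_fit(data.frame(x = rnorm(6, 0, 3), y = rnorm(6, 0, 2)), h = 1.5)
  gr <- seq(-40, 40, by = 0.4)
  gg <- expand.grid(x = gr, y = gr)
  integral <- sum(kde_eval(m, gg$x, gg$y)) * 0.4^2
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("frame gaze averages non-saccadic samples per half-open frame", {
  # 60 Hz trace over 4 frames at 30 fps; one saccade spanning frame 2
  tr <- make_trace(c(1, 3, 2, 9, 5, 5, 7, 7),
                   c(1, 3, 2, 9, 5, 5, 7, 7))
  ev <- structure(list(saccades = data.frame(t_on = 2 / 60, t_off = 3 / 60),
                       saccade_sample = c(FALSE, FALSE, TRUE, TRUE,
                                          FALSE, FALSE, FALSE, FALSE)),
                  class = "event_sequence")
  fg <- frame_gaze(tr, ev, frame_rate = 30, duration = 4 / 30)
  expect_equal(nrow(fg), 4)
  expect_equal(fg$x[1], 2)          # mean of samples 1, 2
  expect_true(is.na(fg$x[2]))       # both samples inside the saccade
  expect_equal(fg$x[3], 5)
  expect_equal(fg$x[4], 7)
  expect_equal(fg$n_samples, c(2L, 0L, 2L, 2L))
})

test_that("kde scores are symmetric for identical gaze and near-equal for a clone", {
  nf <- 40
  mk <- function(x, y) data.frame(frame = 0:(nf - 1),
                                  t_mid = (0:(nf - 1) + 0.5) / 30,
                                  x = rep(x, nf), y = rep(y, nf),
                                  n_samples = 2L)
  # all participants share identical gaze -> all scores equal
  fp <- lapply(1:6, function(i) mk(1, 1))
  kt <- kde_scores(fp, groups = c(rep("none", 5), "moderate"),
                   contamination = 0)
  expect_equal(length(unique(round(kt$scores[, 1], 12))), 1)

  # a test participant cloning control 1 scores within 10% of that
  # control's own leave-one-out score
  set.seed(9)
  n_ctrl <- 12
  fp2 <- lapply(seq_len(n_ctrl), function(i)
    mk(rnorm(1, 0, 1), rnorm(1, 0, 1)))
  fp2[[n_ctrl + 1]] <- fp2[[1]]
  kt2 <- kde_scores(fp2, groups = c(rep("none", n_ctrl), "moderate"),
                    contamination = 0)
  clone <- kt2$mean_score[n_ctrl + 1]
  own_loo <- kt2$mean_score[1]
  expect_lt(abs(clone - own_loo) / own_loo, 0.10)
})

test_that("planted idiosyncrasy depresses the impaired group's KDE score", {
  eff <- effect_spec(
    amplitude_scale = c(none = 1, moderate = 1, advanced = 1),
    scotoma_attraction = c(none = 0, moderate = 0, advanced = 0),
    idiosyncrasy = c(none = 0.8, moderate = 4, advanced = 0.8))
  cfg <- cohort_config(6, 5, 2,
                       stimuli = list(stimulus_spec("v", "video", 30)),
                       seed = 41, effect = eff)
  bundle <- build_biomarkers(generate_cohort(cfg))
  b <- bundle$biomarkers
  expect_lt(median(b$kde_mean[b$group == "moderate"]),
            median(b$kde_mean[b$group == "none"]))
})

test_that("saccade maps normalise, localise, and mirror under rotation", {
  one <- saccade_map_features(data.frame(dx = 0.5, dy = 0.5))
  expect_equal(sum(one), 1)
  expect_equal(unname(one["map_c07_r4"]), 1)  # cell containing (0.5, 0.5)
  set.seed(5)
  ep <- data.frame(dx = runif(60, -23, 23), dy = runif(60, -13, 13))
  f <- saccade_map_features(ep)
  expect_equal(sum(f), 1)
  # rotating by 180 degrees maps cell (i, j) to (13 - i, 8 - j)
  fr <- saccade_map_features(data.frame(dx = -ep$dx, dy = -ep$dy))
  m <- matrix(f, 12, 7)
  mr <- matrix(fr, 12, 7)
  expect_equal(mr, m[12:1, 7:1], tolerance = 1e-12)
  # out-of-range endpoints clamp to edge cells
  far <- saccade_map_features(data.frame(dx = c(100, -100), dy = c(50, -50)))
  expect_equal(sum(far), 1)
  expect_equal(unname(far["map_c12_r7"] + far["map_c01_r1"]), 1)
  # zero saccades: flagged all-zero vector
  z <- saccade_map_features(data.frame(dx = numeric(0), dy = numeric(0)))
  expect_true(all(z == 0) && attr(z, "empty"))
})
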