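test_that("cohort configuration is validated before any compute", {
  expect_error(cohort_config(n_control = 1), ">= 2")
  expect_error(cohort_config(n_moderate = 0), ">= 2")
  expect_error(cohort_config(stimuli = list()), "non-empty")
  expect_error(effect_spec(amplitude_scale = c(none = 1, moderate = 1.2,
                                               advanced = 0.6)), "\\(0, 1\\]")
  expect_error(effect_spec(scotoma_attraction = c(none = -0.1, moderate = 0,
                                                  advanced = 0)), "\\[0, 1\\]")
  expect_error(effect_spec(idiosyncrasy = c(none = -1, moderate = 1,
                                            advanced = 1)), "SDs")
  expect_error(stimulus_spec("v", "video", 10, frame_rate = 25), "30")
  expect_error(stimulus_spec("i", "image", -3), "> 0")
})

test_that("two control participants and one 10 s image give 2 x ~600 samples", {
  cfg <- cohort_config(2, 2, 2,
                       stimuli = list(stimulus_spec("im", "image", 10)),
                       seed = 4)
  rec <- generate_cohort(cfg)
  expect_equal(length(rec), 6)   # every participant sees every stimulus
  ctrl <- Filter(function(r) r$group == "none", rec)
  expect_equal(length(ctrl), 2)
  for (r in ctrl) expect_equal(nrow(r$samples), 600)
})

test_that("identical seed and config reproduce bit-identical recordings", {
  cfg <- tiny_cohort(seed = 9, duration = 10)
  r1 <- generate_cohort(cfg)
  r2 <- generate_cohort(cfg)
  expect_identical(lapply(r1, `[[`, "samples"), lapply(r2, `[[`, "samples"))
  r3 <- generate_cohort(tiny_cohort(seed = 10, duration = 10))
  expect_false(identical(r1[[1]]$samples, r3[[1]]$samples))
})

test_that("generated samples respect the recording invariants", {
  cfg <- tiny_cohort(seed = 21, duration = 15)
  rec <- generate_cohort(cfg)
  for (r in rec) {
    s <- r$samples
    expect_true(all(diff(s$t_s) > 0))
    expect_equal(median(diff(s$t_s)), 1 / 60)
    expect_true(all(s$xl_px >= 0 & s$xl_px <= 1920))
    expect_true(all(s$yl_px >= 0 & s$yl_px <= 1080))
    expect_true(all(s$dist_mm > 0))
    expect_true(is.logical(s$valid_l) || all(s$valid_l %in% c(0, 1)))
  }
  # blink-like invalid runs exist at the default 2% rate
  inval <- mean(!do.call(rbind, lapply(rec, `[[`, "samples"))$valid_l)
  expect_gt(inval, 0.002)
  expect_lt(inval, 0.08)
})

test_that("all participants of a cohort share the stimulus saliency targets", {
  stim <- stimulus_spec("v1", "video", 30)
  t1 <- saliency_targets(stim, seed = 5)
  t2 <- saliency_targets(stim, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$x >= -20 & t1$x <= 20 & t1$y >= -10 & t1$y <= 10))
  expect_true(all(diff(t1$t_start) >= 1 - 1e-9 & diff(t1$t_start) <= 3 + 1e-9))
  im <- saliency_targets(stimulus_spec("imX", "image", 60), seed = 5)
  expect_true(nrow(im) >= 10 && nrow(im) <= 20)
})

test_that("planted saccades and filters are recovered exactly without noise", {
  # short fixations only rarely exceed 500 ms; small local scatter plants
  # sub-0.5 deg saccades
  eff <- quiet_effect(local_scatter = 0.8,
                      fixation_duration = c(mean = 0.35, sd = 0.15))
  cfg <- cohort_config(2, 2, 2,
                       stimuli = list(stimulus_spec("im", "image", 30)),
                       seed = 17, effect = eff)
  rec <- generate_cohort(cfg)
  n_small <- n_long <- 0
  for (r in rec) {
    ev <- detect_events(recording_to_trace(r))
    tru <- r$truth$saccades
    det_on <- c(ev$saccades$t_on,
                ev$discarded$t_on[ev$discarded$reason == "small_saccade"])
    # recall: every planted saccade is found; precision: nothing else is
    expect_true(all(match_onsets(det_on, tru$t_on)))
    expect_equal(length(det_on), nrow(tru))
    # the 0.5 deg filter removes exactly the planted sub-threshold saccades
    expect_equal(sum(ev$discarded$reason == "small_saccade"),
                 sum(tru$amplitude < 0.5))
    retained <- merge(ev$saccades, tru, by = "t_on")
    expect_equal(retained$amplitude.x, retained$amplitude.y, tolerance = 1e-9)
    # the 500 ms filter removes exactly the planted long fixations
    expect_equal(sum(ev$discarded$reason == "long_fixation"),
                 sum(r$truth$fixations$duration > 0.5))
    n_small <- n_small + sum(tru$amplitude < 0.5)
    n_long <- n_long + sum(r$truth$fixations$duration > 0.5)
  }
  # the cohort actually exercises both filters
  expect_gt(n_small, 0)
  expect_gt(n_long, 0)
})

test_that("decreasing amplitude_scale strictly decreases median amplitude", {
  scales <- c(1, 0.8, 0.6, 0.4)
  med <- matrix(NA_real_, length(scales), 10)
  for (si in seq_along(scales)) for (sd in 1:10) {
    eff <- effect_spec(
      amplitude_scale = c(none = 1, moderate = 1, advanced = scales[si]),
      scotoma_attraction = c(none = 0, moderate = 0, advanced = 0),
      idiosyncrasy = c(none = 0.8, moderate = 0.8, advanced = 0.8))
    cfg <- cohort_config(2, 2, 3,
                         stimuli = list(stimulus_spec("im", "image", 12)),
                         seed = 100 + sd, effect = eff)
    rec <- Filter(function(r) r$group == "advanced", generate_cohort(cfg))
    med[si, sd] <- median(unlist(lapply(rec, function(r)
      r$truth$saccades$amplitude)))
  }
  expect_true(all(diff(rowMeans(med)) < 0))
})

test_that("recordings round-trip through CSV and malformed files error", {
  cfg <- tiny_cohort(seed = 30, duration = 5)
  rec <- generate_cohort(cfg)
  path <- tempfile(fileext = ".csv")
  write_recordings(rec, path)
  back <- read_recordings(path)
  expect_equal(length(back), length(rec))
  key <- function(l) paste0(vapply(l, `[[`, "", "participant"), "/",
                            vapply(l, `[[`, "", "stimulus"))
  ord <- match(key(rec), key(back))
  for (i in seq_along(rec)) {
    expect_equal(back[[ord[i]]]$samples$xl_px, rec[[i]]$samples$xl_px)
    expect_equal(back[[ord[i]]]$samples$t_s, rec[[i]]$samples$t_s)
    expect_equal(back[[ord[i]]]$group, rec[[i]]$group)
  }
  expect_equal(back[[1]]$screen$width_cm, 51)

  # non-monotone timestamps
  rows <- read.csv(path)
  rows$t_s[3] <- rows$t_s[5]
  bad <- tempfile(fileext = ".csv")
  write.csv(rows, bad, row.names = FALSE)
  expect_error(read_recordings(bad), "non-monotone")

  # empty table / missing columns
  write.csv(rows[0, ], bad, row.names = FALSE)
  expect_error(read_recordings(bad), "no samples")
  write.csv(rows[, -4], bad, row.names = FALSE)
  expect_error(read_recordings(bad), "missing columns")
})
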