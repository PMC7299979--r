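#' Planted group-effect specification for the gaze generator
#'
#' Each per-group parameter plants one of the directions the analysis is meant
#' to detect: `amplitude_scale` shrinks every planned saccadic displacement
#' (reduced saccade amplitude and endpoint spread in advanced loss),
#' `scotoma_attraction` is the probability that a saccade is aimed into the
#' group's gaze-relative scotoma (elevated SLV in moderate loss), and
#' `idiosyncrasy` is the SD (degrees) of the per-participant, per-target-epoch
#' perturbation away from the shared saliency target (depressed KDE similarity
#' in moderate loss).
#'
#' @param amplitude_scale named per-group scales in (0, 1].
#' @param spread_scale named per-group scales in (0, 1], applied to the
#'   endpoint scatter.
#' @param scotoma_attraction named per-group probabilities in \[0, 1\];
#'   attracted saccades land uniformly in the near band of the mask (cells
#'   within 6 degrees of its inner edge), so they raise SLV without grossly
#'   inflating saccade amplitude.
#' @param idiosyncrasy named per-group SDs (degrees) >= 0.
#' @param participant_gain_sd SD of the log-normal per-recording saccadic
#'   gain, planting the inter-individual variability that keeps group
#'   separations at realistic (AUC ~0.75-0.9), rather than perfect, levels.
#' @param fixation_duration mean/SD of fixation duration in seconds
#'   (truncated at 0.1 s).
#' @param noise_sd per-sample gaze jitter SD (degrees).
#' @param endpoint_sd saccade endpoint scatter SD (degrees), multiplied by the
#'   group's `spread_scale`.
#' @param local_scatter SD (degrees) of exploratory re-fixation scatter around
#'   the current saliency target.
#' @param binocular_jitter per-eye jitter SD (degrees) around the common
#'   binocular point of regard.
#' @param blink_rate fraction of samples flagged invalid, in runs of 3-10
#'   samples.
#' @param idiosyncrasy_window optional `c(t0, t1)` in seconds: outside this
#'   window impaired groups fall back to the control idiosyncrasy (used to
#'   plant a temporally confined similarity effect).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(amplitude_scale = c(none = 1, moderate = 0.9, advanced = 0.6),
                        spread_scale = c(none = 1, moderate = 0.95, advanced = 0.85),
                        scotoma_attraction = c(none = 0, moderate = 0.15, advanced = 0.05),
                        idiosyncrasy = c(none = 0.8, moderate = 2, advanced = 1.2),
                        fixation_duration = c(mean = 0.3, sd = 0.1),
                        noise_sd = 0.05,
                        endpoint_sd = 0.25,
                        local_scatter = 1.5,
                        binocular_jitter = 0.2,
                        participant_gain_sd = 0.35,
                        blink_rate = 0.02,
                        idiosyncrasy_window = NULL) {
  groups <- c("none", "moderate", "advanced")
  for (nm in c("amplitude_scale", "spread_scale", "scotoma_attraction",
               "idiosyncrasy")) {
    v <- get(nm)
    if (!all(groups %in% names(v)))
      stop(nm, " must be named for groups none/moderate/advanced")
  }
  if (any(amplitude_scale <= 0 | amplitude_scale > 1))
    stop("amplitude_scale must lie in (0, 1]")
  if (any(spread_scale <= 0 | spread_scale > 1))
    stop("spread_scale must lie in (0, 1]")
  if (any(scotoma_attraction < 0 | scotoma_attraction > 1))
    stop("scotoma_attraction must lie in [0, 1]")
  if (any(idiosyncrasy < 0) || noise_sd < 0 || endpoint_sd < 0 ||
      local_scatter < 0 || binocular_jitter < 0 || participant_gain_sd < 0)
    stop("SDs must be >= 0")
  if (blink_rate < 0 || blink_rate > 0.2) stop("blink_rate must lie in [0, 0.2]")
  if (fixation_duration[["mean"]] <= 0 || fixation_duration[["sd"]] < 0)
    stop("invalid fixation_duration")
  structure(list(amplitude_scale = amplitude_scale[groups],
                 spread_scale = spread_scale[groups],
                 scotoma_attraction = scotoma_attraction[groups],
                 idiosyncrasy = idiosyncrasy[groups],
                 fixation_duration = fixation_duration,
                 noise_sd = noise_sd, endpoint_sd = endpoint_sd,
                 local_scatter = local_scatter,
                 binocular_jitter = binocular_jitter,
                 participant_gain_sd = participant_gain_sd,
                 blink_rate = blink_rate,
                 idiosyncrasy_window = idiosyncrasy_window),
            class = "effect_spec")
}

#' Stimulus specification
#'
#' @param id stimulus label.
#' @param kind `"video"` or `"image"`.
#' @param duration seconds (> 0).
#' @param frame_rate frames/s; must be 30 for videos, `NA` for images.
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(id, kind = c("video", "image"), duration,
                          frame_rate = if (kind == "video") 30 else NA) {
  kind <- match.arg(kind)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (kind == "video" && (!is.finite(frame_rate) || frame_rate != 30))
    stop("video frame_rate must be 30")
  structure(list(id = id, kind = kind, duration = duration,
                 frame_rate = if (kind == "video") frame_rate else NA_real_),
            class = "stimulus_spec")
}

#' The study's five stimuli
#'
#' Two videos (301 s and 307 s, 30 frames/s) and three static images (60 s
#' each).
#'
#' @return list of `stimulus_spec`.
#' @export
default_stimuli <- function() {
  list(stimulus_spec("video1", "video", 301),
       stimulus_spec("video2", "video", 307),
       stimulus_spec("image1", "image", 60),
       stimulus_spec("image2", "image", 60),
       stimulus_spec("image3", "image", 60))
}

# bounds (degrees) within which saliency targets are placed; comfortably
# inside the ~46 x 24 degree screen subtense
TARGET_XLIM <- c(-20, 20)
TARGET_YLIM <- c(-10, 10)

stim_hash <- function(id) sum(utf8ToInt(as.character(id))) %% 10000L

#' Shared saliency targets for a stimulus
#'
#' Videos get a piecewise-constant target (a new screen point every 1-3 s);
#' images get a fixed set of 10-20 points among which viewers alternate. The
#' target process is seeded per stimulus so all participants of a cohort share
#' it.
#'
#' @param stim `stimulus_spec`.
#' @param seed cohort seed.
#' @return data.frame `t_start`, `x`, `y` (video) or `x`, `y` (image).
#' @export
saliency_targets <- function(stim, seed) {
  set.seed((seed * 131 + stim_hash(stim$id)) %% 2147483647L)
  if (stim$kind == "video") {
    t_start <- 0
    while (sum(diff(c(t_start, stim$duration))) > 0 &&
           t_start[length(t_start)] < stim$duration)
      t_start <- c(t_start, t_start[length(t_start)] + stats::runif(1, 1, 3))
    t_start <- t_start[t_start < stim$duration]
    data.frame(t_start = t_start,
               x = stats::runif(length(t_start), TARGET_XLIM[1], TARGET_XLIM[2]),
               y = stats::runif(length(t_start), TARGET_YLIM[1], TARGET_YLIM[2]))
  } else {
    n <- sample(10:20, 1)
    data.frame(x = stats::runif(n, TARGET_XLIM[1], TARGET_XLIM[2]),
               y = stats::runif(n, TARGET_YLIM[1], TARGET_YLIM[2]))
  }
}

#' Cohort configuration
#'
#' @param n_control,n_moderate,n_advanced group sizes (each >= 2). Study
#'   cohort: 25/15/15.
#' @param stimuli list of `stimulus_spec` (non-empty);
#'   default [default_stimuli()].
#' @param seed integer seed; fully determines the cohort.
#' @param effect `effect_spec`.
#' @param sample_rate Hz (default 60).
#' @param screen `screen_geometry`.
#' @param scotoma_cutoff dB cutoff for the generator's loss masks.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 25, n_moderate = 15, n_advanced = 15,
                          stimuli = default_stimuli(), seed = 1,
                          effect = effect_spec(), sample_rate = 60,
                          screen = screen_geometry(), scotoma_cutoff = 20) {
  if (any(c(n_control, n_moderate, n_advanced) < 2))
    stop("all group sizes must be >= 2")
  if (length(stimuli) == 0) stop("stimuli must be non-empty")
  stopifnot(inherits(effect, "effect_spec"), inherits(screen, "screen_geometry"))
  seed <- as.integer(seed)
  structure(list(n_control = n_control, n_moderate = n_moderate,
                 n_advanced = n_advanced, stimuli = stimuli, seed = seed,
                 effect = effect, sample_rate = sample_rate, screen = screen,
                 scotoma_cutoff = scotoma_cutoff),
            class = "cohort_config")
}

# saccade sample-profile: displacement fractions along the saccade direction.
# A linear ramp cannot cross the 8000 deg/s^2 acceleration threshold at 60 Hz
# unless a single step exceeds ~2.2 deg, so the profile is front-loaded: a
# first step of >= 2.8 deg (onset acceleration >= ~10000 deg/s^2 from rest)
# followed by corrective steps of at least 0.55 deg/sample (speed stays > 33
# deg/s), overshooting and returning when the amplitude is small.
saccade_profile <- function(amplitude, rate = 60) {
  stopifnot(amplitude > 0)
  d1_min <- 2.8
  step_min <- 0.7
  k <- max(2L, min(6L, 1L + ceiling((amplitude - d1_min) / 1.5)))
  if (amplitude >= d1_min + step_min * (k - 1)) {
    d1 <- amplitude - step_min * (k - 1)
    rest <- rep(step_min, k - 1)
  } else {
    d1 <- max(d1_min, amplitude + step_min * (k - 1))
    rest <- rep((amplitude - d1) / (k - 1), k - 1)
  }
  cumsum(c(d1, rest))  # cumulative displacement at each of the k samples
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# sample positions for a saccade from pos to endpoint: collinear front-loaded
# ramp if it stays on screen, else a two-sample overshoot aimed inward (the
# screen-edge pixel clamp would otherwise flatten the first step below the
# detector's acceleration threshold)
saccade_positions <- function(pos, endpoint, amp, rate = 60) {
  u <- (endpoint - pos) / amp
  safe <- function(P)
    all(abs(P[, 1]) <= 22.6) && all(abs(P[, 2]) <= 11.8)
  steps_ok <- function(P) {
    d <- sqrt(rowSums(diff(rbind(pos, P))^2))
    d[1] >= 2.75 && all(d >= 0.56)
  }
  prof <- saccade_profile(amp, rate)
  P <- cbind(pos[1] + u[1] * prof, pos[2] + u[2] * prof)
  if (safe(P) && steps_ok(P)) return(P)
  dirs <- list(if (sqrt(sum(pos^2)) > 1e-6) -pos / sqrt(sum(pos^2)) else -u,
               -u)
  for (w in dirs) {
    mid <- pos + 2.8 * w
    P2 <- rbind(mid, endpoint)
    if (safe(P2) && steps_ok(P2)) return(P2)
  }
  P   # unreachable for on-screen endpoints; keep the collinear ramp
}

# one participant x stimulus recording; returns samples in degrees plus the
# planted ground truth
simulate_trace <- function(stim, targets, group, effect, mask, rate, seed) {
  set.seed(seed)
  n_total <- round(stim$duration * rate)
  dt <- 1 / rate
  amp_s <- effect$amplitude_scale[[group]]
  spr_s <- effect$spread_scale[[group]]
  attract <- effect$scotoma_attraction[[group]]
  idio_own <- effect$idiosyncrasy[[group]]
  idio_ctrl <- effect$idiosyncrasy[["none"]]
  win <- effect$idiosyncrasy_window
  # per-recording saccadic gain: inter-individual variability in how far
  # this viewer's scan path ranges from screen centre
  gain <- exp(stats::rnorm(1, 0, effect$participant_gain_sd))
  # per-recording attraction heterogeneity (log-normal, mean preserved):
  # how strongly an individual orients into the scotoma varies
  if (attract > 0)
    attract <- min(0.8, attract * exp(stats::rnorm(1, -0.9^2 / 2, 0.9)))
  # near band of the mask: cells within 6 deg of its inner edge, where
  # scotoma-attracted saccades land
  near_cells <- if (nrow(mask$cells) > 0L) {
    ecc <- sqrt(mask$cells$x^2 + mask$cells$y^2)
    mask$cells[ecc <= min(ecc) + 6, , drop = FALSE]
  } else mask$cells

  # constant per-recording idiosyncratic offset: a stable personal bias away
  # from the shared saliency target, so it depresses cross-participant gaze
  # similarity without entering saccadic displacements
  n_epochs <- nrow(targets)
  off_own <- stats::rnorm(2) * idio_own
  off_base <- stats::rnorm(2) * idio_ctrl
  idio_offset <- function(t_now) {
    if (!is.null(win) && group != "none" &&
        !(t_now >= win[1] && t_now < win[2])) off_base else off_own
  }

  current_epoch <- function(t_now) {
    if (stim$kind == "video") findInterval(t_now, targets$t_start) else 0L
  }

  xs <- numeric(n_total); ys <- numeric(n_total)
  pos <- c(0, 0)
  i <- 1L
  truth_sac <- list(); truth_fix <- list()
  img_epoch <- sample(n_epochs, 1)

  fix_start <- 1L   # first sample of the fixation currently being held
  add_fix <- function(last_idx)
    truth_fix[[length(truth_fix) + 1L]] <<-
      data.frame(t_on = (fix_start - 1) * dt,
                 duration = (last_idx - fix_start) * dt)
  while (i <= n_total) {
    # fixation hold (degenerate aims below just keep extending it)
    hold_dur <- max(0.1, stats::rnorm(1, effect$fixation_duration[["mean"]],
                                      effect$fixation_duration[["sd"]]))
    h <- max(7L, round(hold_dur * rate) + 1L)
    h <- min(h, n_total - i + 1L)
    idx <- i:(i + h - 1L)
    xs[idx] <- pos[1]; ys[idx] <- pos[2]
    i <- i + h
    if (i > n_total) {
      add_fix(n_total)
      break
    }
    t_now <- (i - 1) * dt

    # choose the next aim point; amplitude_scale contracts the whole scan
    # path toward the initial central fixation, so saccadic displacements are
    # scale-invariant in shape and the planted scale is recoverable from
    # group median ratios
    # a single uniform draw couples scotoma attraction to the exploratory
    # excursion process: attracted saccades replace excursions of similar
    # magnitude, so they raise SLV without inflating the amplitude
    # distribution
    u_exc <- stats::runif(1)
    if (u_exc < attract && nrow(near_cells) > 0L) {
      cell <- near_cells[sample(nrow(near_cells), 1), ]
      disp <- c(cell$x + stats::runif(1, -mask$half_width, mask$half_width),
                cell$y + stats::runif(1, -mask$half_width, mask$half_width))
      endpoint <- pos + disp
    } else {
      if (stim$kind == "video") {
        ep <- max(1L, current_epoch(t_now))
        tgt <- c(targets$x[ep], targets$y[ep])
      } else {
        if (stats::runif(1) < 0.3) img_epoch <- sample(n_epochs, 1)
        ep <- img_epoch
        tgt <- c(targets$x[ep], targets$y[ep])
      }
      scat <- effect$local_scatter * (if (u_exc < 0.25) 3 else 1)
      aim <- tgt + idio_offset(t_now) + stats::rnorm(2, 0, scat)
      # gain and the screen bound act on the shared aim process first, so
      # amplitude_scale contracts an identical bounded scan path in every
      # group and group amplitude ratios recover the planted scale
      aim <- c(clamp(gain * aim[1], TARGET_XLIM[1] - 0.5, TARGET_XLIM[2] + 0.5),
               clamp(gain * aim[2], TARGET_YLIM[1] - 0.5, TARGET_YLIM[2] + 0.5))
      endpoint <- amp_s * aim +
        stats::rnorm(2, 0, effect$endpoint_sd * spr_s)
    }
    endpoint <- c(clamp(endpoint[1], TARGET_XLIM[1] - 1, TARGET_XLIM[2] + 1),
                  clamp(endpoint[2], TARGET_YLIM[1] - 1, TARGET_YLIM[2] + 1))
    disp <- endpoint - pos
    amp <- sqrt(sum(disp^2))
    if (amp < 0.05) next  # aim indistinguishable from current position: hold on
    P <- saccade_positions(pos, endpoint, amp, rate)
    k <- nrow(P)
    if (i + k - 1L > n_total) {
      # not enough room: extend the final fixation to the end instead
      idx2 <- i:n_total
      xs[idx2] <- pos[1]; ys[idx2] <- pos[2]
      add_fix(n_total)
      i <- n_total + 1L
      break
    }
    add_fix(i - 1L)
    midx <- i:(i + k - 1L)
    xs[midx] <- P[, 1]
    ys[midx] <- P[, 2]
    truth_sac[[length(truth_sac) + 1L]] <-
      data.frame(t_on = (i - 2) * dt, t_off = (i + k - 2) * dt,
                 x_start = pos[1], y_start = pos[2],
                 x_end = endpoint[1], y_end = endpoint[2], amplitude = amp)
    pos <- endpoint
    i <- i + k
    fix_start <- i
  }

  # per-sample jitter
  if (effect$noise_sd > 0) {
    xs <- xs + stats::rnorm(n_total, 0, effect$noise_sd)
    ys <- ys + stats::rnorm(n_total, 0, effect$noise_sd)
  }

  list(t = (seq_len(n_total) - 1L) * dt, x = xs, y = ys,
       truth = list(
         saccades = if (length(truth_sac)) do.call(rbind, truth_sac) else
           data.frame(t_on = numeric(0), t_off = numeric(0),
                      x_start = numeric(0), y_start = numeric(0),
                      x_end = numeric(0), y_end = numeric(0),
                      amplitude = numeric(0)),
         fixations = if (length(truth_fix)) do.call(rbind, truth_fix) else
           data.frame(t_on = numeric(0), duration = numeric(0))))
}

deg_to_px <- function(x_deg, y_deg, dist_cm, scr) {
  px <- scr$width_px / 2 +
    tan(x_deg * pi / 180) * dist_cm / (scr$width_cm / scr$width_px)
  py <- scr$height_px / 2 -
    tan(y_deg * pi / 180) * dist_cm / (scr$height_cm / scr$height_px)
  list(x = clamp(px, 0, scr$width_px), y = clamp(py, 0, scr$height_px))
}

#' Generate a synthetic cohort of gaze recordings
#'
#' One recording per participant x stimulus. All participants of a cohort
#' share the stimulus saliency targets; each group applies its planted effects
#' (see [effect_spec()]). Gaze alternates fixations (truncated-normal
#' durations) and front-loaded saccadic ramps that exceed both detection
#' thresholds; the binocular point of regard is rendered as two eyes with
#' independent jitter, converted to screen pixels with a slowly swaying
#' viewing distance, and a small fraction of samples is flagged invalid in
#' blink-like runs. Each recording carries the planted ground truth
#' (`$truth$saccades`, `$truth$fixations`).
#'
#' @param config `cohort_config`.
#' @return list of `gaze_recording` objects, with attributes `config` and
#'   `masks` (the per-severity scotoma masks used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  scr <- config$screen
  rate <- config$sample_rate
  masks <- list(
    moderate = scotoma_mask(synthetic_perimetry("moderate")$ivf,
                            config$scotoma_cutoff),
    advanced = scotoma_mask(synthetic_perimetry("advanced")$ivf,
                            config$scotoma_cutoff))
  groups <- c(rep("none", config$n_control),
              rep("moderate", config$n_moderate),
              rep("advanced", config$n_advanced))
  ids <- sprintf("P%02d", seq_along(groups))
  targets <- lapply(config$stimuli, saliency_targets, seed = config$seed)
  names(targets) <- vapply(config$stimuli, `[[`, "", "id")

  recordings <- list()
  for (p in seq_along(groups)) {
    grp <- groups[p]
    mask <- if (grp == "none") masks$moderate else masks[[grp]]
    for (s in seq_along(config$stimuli)) {
      stim <- config$stimuli[[s]]
      seed_ps <- (config$seed %% 100000L) * 20011L + p * 211L + s * 7L
      tr <- simulate_trace(stim, targets[[stim$id]], grp, config$effect,
                           mask, rate, seed_ps %% 2147483647L)
      n <- length(tr$t)
      dist_mm <- 600 + 20 * sin(2 * pi * tr$t / 97 + p)
      bj <- config$effect$binocular_jitter
      xl <- tr$x + stats::rnorm(n, 0, bj); yl <- tr$y + stats::rnorm(n, 0, bj)
      xr <- tr$x + stats::rnorm(n, 0, bj); yr <- tr$y + stats::rnorm(n, 0, bj)
      pl <- deg_to_px(xl, yl, dist_mm / 10, scr)
      pr <- deg_to_px(xr, yr, dist_mm / 10, scr)
      valid <- rep(TRUE, n)
      if (config$effect$blink_rate > 0) {
        n_runs <- max(0L, round(config$effect$blink_rate * n / 6.5))
        if (n_runs > 0) {
          starts <- sample(n, n_runs)
          for (st in starts) {
            len <- sample(3:10, 1)
            valid[st:min(n, st + len - 1L)] <- FALSE
          }
        }
      }
      samples <- data.frame(t_s = tr$t, xl_px = pl$x, yl_px = pl$y,
                            xr_px = pr$x, yr_px = pr$y, dist_mm = dist_mm,
                            valid_l = valid, valid_r = valid)
      recordings[[length(recordings) + 1L]] <-
        structure(list(participant = ids[p], group = grp, stimulus = stim$id,
                       samples = samples, screen = scr, truth = tr$truth),
                  class = "gaze_recording")
    }
  }
  attr(recordings, "config") <- config
  attr(recordings, "masks") <- masks
  recordings
}

#' Write / read a cohort of recordings as CSV + sidecar JSON
#'
#' CSV layout: `participant,group,stimulus,t_s,xl_px,yl_px,xr_px,yr_px,
#' dist_mm,valid_l,valid_r` (one file per cohort); the screen geometry goes to
#' `<path>.json`. Planted ground truth is not serialized.
#'
#' @param recordings list of `gaze_recording`.
#' @param path CSV path.
#' @export
write_recordings <- function(recordings, path) {
  if (length(recordings) == 0L) stop("no recordings")
  rows <- do.call(rbind, lapply(recordings, function(r)
    cbind(participant = r$participant, group = r$group, stimulus = r$stimulus,
          r$samples)))
  utils::write.csv(rows, path, row.names = FALSE)
  scr <- recordings[[1]]$screen
  jsonlite::write_json(unclass(scr), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recordings
#' @param strict check timestamp monotonicity per recording.
#' @export
read_recordings <- function(path, strict = TRUE) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "stimulus", "t_s", "xl_px", "yl_px",
            "xr_px", "yr_px", "dist_mm", "valid_l", "valid_r")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("malformed CSV: missing columns ", paste(miss, collapse = ", "))
  if (nrow(rows) == 0L) stop("no samples")
  scr_path <- paste0(path, ".json")
  scr <- if (file.exists(scr_path)) {
    g <- jsonlite::read_json(scr_path, simplifyVector = TRUE)
    screen_geometry(g$width_cm, g$height_cm, g$width_px, g$height_px,
                    g$nominal_distance_cm)
  } else screen_geometry()
  keys <- unique(rows[, c("participant", "stimulus", "group")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- rows$participant == keys$participant[i] &
      rows$stimulus == keys$stimulus[i]
    samples <- rows[sel, setdiff(need, c("participant", "group", "stimulus"))]
    rownames(samples) <- NULL
    if (strict && any(diff(samples$t_s) <= 0)) {
      bad <- which(diff(samples$t_s) <= 0)[1] + 1
      stop("non-monotone timestamps for ", keys$participant[i], "/",
           keys$stimulus[i], " at row ", bad, ", column t_s")
    }
    out[[i]] <- structure(list(participant = keys$participant[i],
                               group = keys$group[i],
                               stimulus = keys$stimulus[i],
                               samples = samples, screen = scr, truth = NULL),
                          class = "gaze_recording")
  }
  out
}
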