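#' Screen geometry
#'
#' Physical and pixel dimensions of the display plus the nominal viewing
#' distance. Defaults are the study display: 51 x 25.5 cm, 1920 x 1080 px,
#' viewed from about 60 cm, subtending about 46 x 24 degrees. The cm and px
#' aspect ratios need not match: each axis is converted with its own cm/px
#' scale.
#'
#' @param width_cm,height_cm physical size (cm).
#' @param width_px,height_px resolution (pixels).
#' @param nominal_distance_cm fallback viewing distance (cm).
#' @return object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_cm = 51, height_cm = 25.5,
                            width_px = 1920, height_px = 1080,
                            nominal_distance_cm = 60) {
  vals <- c(width_cm, height_cm, width_px, height_px, nominal_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen geometry values must be positive")
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 width_px = width_px, height_px = height_px,
                 nominal_distance_cm = nominal_distance_cm),
            class = "screen_geometry")
}

#' Convert pixel gaze to degrees visual angle
#'
#' Converts one eye's raw pixel positions to degrees of visual angle using the
#' per-sample eye-to-screen distance. The origin is the screen centre, +x
#' right, +y up (pixel y runs downward and is flipped). Missing distances fall
#' back to the nominal distance; nonpositive distances flag the sample
#' invalid.
#'
#' @param recording a `gaze_recording` (see [generate_cohort()]), or any list
#'   with `samples` and `screen`.
#' @param eye `"left"` or `"right"`.
#' @return a degrees trace: data.frame with `t` (s), `x`, `y` (degrees),
#'   `valid`.
#' @export
pixels_to_degrees <- function(recording, eye = c("left", "right")) {
  eye <- match.arg(eye)
  s <- recording$samples
  scr <- recording$screen
  px <- if (eye == "left") s$xl_px else s$xr_px
  py <- if (eye == "left") s$yl_px else s$yr_px
  valid <- if (eye == "left") as.logical(s$valid_l) else as.logical(s$valid_r)
  dist_cm <- s$dist_mm / 10
  dist_cm[is.na(dist_cm)] <- scr$nominal_distance_cm
  bad_dist <- !is.na(dist_cm) & dist_cm <= 0
  valid <- valid & !bad_dist & !is.na(px) & !is.na(py)
  dist_cm[bad_dist] <- scr$nominal_distance_cm  # keep arithmetic finite
  cmppx_x <- scr$width_cm / scr$width_px
  cmppx_y <- scr$height_cm / scr$height_px
  x <- atan2((px - scr$width_px / 2) * cmppx_x, dist_cm) * 180 / pi
  y <- atan2(-(py - scr$height_px / 2) * cmppx_y, dist_cm) * 180 / pi
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  data.frame(t = s$t_s, x = x, y = y, valid = valid)
}

#' Merge left- and right-eye degree traces
#'
#' Binocular point of regard: the mean of the two eyes where both are valid,
#' the single valid eye where only one is, invalid where neither is.
#'
#' @param left,right degrees traces (same timestamps, same length).
#' @return merged degrees trace.
#' @export
merge_binocular <- function(left, right) {
  if (nrow(left) != nrow(right))
    stop("trace length mismatch: ", nrow(left), " vs ", nrow(right))
  both <- left$valid & right$valid
  only_l <- left$valid & !right$valid
  only_r <- right$valid & !left$valid
  x <- ifelse(both, (left$x + right$x) / 2, ifelse(only_l, left$x, right$x))
  y <- ifelse(both, (left$y + right$y) / 2, ifelse(only_l, left$y, right$y))
  valid <- both | only_l | only_r
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  data.frame(t = left$t, x = x, y = y, valid = valid)
}

#' Full conversion of a recording to a merged degrees trace
#'
#' @param recording a `gaze_recording`.
#' @return merged binocular degrees trace.
#' @export
recording_to_trace <- function(recording) {
  merge_binocular(pixels_to_degrees(recording, "left"),
                  pixels_to_degrees(recording, "right"))
}

median3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  m <- v
  m[2:(n - 1)] <- pmax(pmin(v[1:(n - 2)], v[2:(n - 1)]),
                       pmin(pmax(v[1:(n - 2)], v[2:(n - 1)]), v[3:n]))
  m
}

#' Classify a degrees trace into saccades, fixations and discards
#'
#' Velocity/acceleration event detection: sample-to-sample speed and its
#' finite-difference derivative are computed per valid segment; a saccade
#' candidate opens at a sample where speed exceeds `vel_thresh` AND
#' acceleration exceeds `acc_thresh`, and extends while speed stays above
#' `vel_thresh`. Candidates shorter than `min_samples` moving samples are
#' treated as noise. Candidates with amplitude (straight-line start-to-end
#' distance) below `min_amplitude` are discarded with reason `small_saccade`.
#' The remaining inter-saccade runs are fixations; fixations longer than
#' `max_fix_duration` are discarded with reason `long_fixation` (removing
#' smooth pursuit). Invalid runs no longer than `max_gap` are bridged by
#' linear interpolation; longer gaps split events and are logged with reason
#' `invalid_gap`.
#'
#' @param trace merged degrees trace (`t`, `x`, `y`, `valid`).
#' @param vel_thresh saccade velocity threshold, degrees/s (default 30).
#' @param acc_thresh saccade acceleration threshold, degrees/s^2 (default
#'   8000).
#' @param min_amplitude minimum saccade amplitude retained, degrees (default
#'   0.5).
#' @param max_fix_duration longest retained fixation, seconds (default 0.5).
#' @param max_gap longest invalid run bridged by interpolation, seconds
#'   (default 0.1).
#' @param min_samples minimum number of moving samples in a saccade (default
#'   2).
#' @param smooth_window odd width of a median pre-filter on positions; 1
#'   disables smoothing (default; at 60 Hz a median-3 filter suppresses the
#'   one-sample velocity transient that small saccades need to cross the
#'   acceleration threshold).
#' @return object of class `event_sequence`: list with data.frames `saccades`
#'   (`t_on`, `t_off`, `x_start`, `y_start`, `x_end`, `y_end`, `amplitude`,
#'   `peak_velocity`), `fixations` (`t_on`, `t_off`, `x`, `y`, `duration`) and
#'   `discarded` (`t_on`, `t_off`, `reason`), plus the sample times of saccade
#'   membership (`saccade_sample` logical per input row).
#' @export
detect_events <- function(trace, vel_thresh = 30, acc_thresh = 8000,
                          min_amplitude = 0.5, max_fix_duration = 0.5,
                          max_gap = 0.1, min_samples = 2, smooth_window = 1) {
  n <- nrow(trace)
  if (n == 0L || sum(trace$valid) < 3L) stop("no usable samples")
  t <- trace$t; x <- trace$x; y <- trace$y; valid <- trace$valid
  dt <- stats::median(diff(t))

  # bridge short invalid runs (linear interpolation between flanking samples)
  r <- rle(!valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == n) next                       # edge gaps: not bridged
    if (t[i1 + 1L] - t[i0 - 1L] > max_gap + dt / 2) next
    idx <- i0:i1
    w <- (t[idx] - t[i0 - 1L]) / (t[i1 + 1L] - t[i0 - 1L])
    x[idx] <- x[i0 - 1L] + w * (x[i1 + 1L] - x[i0 - 1L])
    y[idx] <- y[i0 - 1L] + w * (y[i1 + 1L] - y[i0 - 1L])
    valid[idx] <- TRUE
  }

  saccades <- fixations <- discarded <- list()
  sacc_sample <- rep(FALSE, n)
  add_disc <- function(t_on, t_off, reason)
    discarded[[length(discarded) + 1L]] <<-
      data.frame(t_on = t_on, t_off = t_off, reason = reason)

  # segments of contiguous valid samples; gaps between them are logged
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    add_disc(t[starts[k]], t[ends[k]], "invalid_gap")
  }

  close_fixation <- function(idx) {
    if (length(idx) < 1L) return()
    dur <- t[idx[length(idx)]] - t[idx[1L]]
    if (dur > max_fix_duration + 1e-9) {
      add_disc(t[idx[1L]], t[idx[length(idx)]], "long_fixation")
    } else {
      fixations[[length(fixations) + 1L]] <<-
        data.frame(t_on = t[idx[1L]], t_off = t[idx[length(idx)]],
                   x = mean(x[idx]), y = mean(y[idx]), duration = dur)
    }
  }

  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    seg <- starts[k]:ends[k]
    m <- length(seg)
    if (m < 3L) { close_fixation(seg); next }
    xs <- x[seg]; ys <- y[seg]
    if (smooth_window > 1L) { xs <- median3(xs); ys <- median3(ys) }
    dts <- diff(t[seg])
    v <- c(0, sqrt(diff(xs)^2 + diff(ys)^2) / dts)   # speed at samples 2..m
    a <- c(0, diff(v) / dts)                          # accel at samples 2..m
    in_sacc <- rep(FALSE, m)
    i <- 2L
    while (i <= m) {
      if (v[i] > vel_thresh && a[i] > acc_thresh && !in_sacc[i]) {
        j <- i
        while (j < m && v[j + 1L] > vel_thresh) j <- j + 1L
        if (j - i + 1L >= min_samples) in_sacc[i:j] <- TRUE
        i <- j + 1L
      } else i <- i + 1L
    }
    # saccade runs -> events; start anchored at the last pre-movement sample
    rs <- rle(in_sacc)
    e2 <- cumsum(rs$lengths); s2 <- e2 - rs$lengths + 1L
    fix_start <- 1L
    for (q in seq_along(rs$lengths)) {
      if (!rs$values[q]) next
      i0 <- s2[q]; i1 <- e2[q]
      anchor <- i0 - 1L                       # exists: runs start at i >= 2
      amp <- sqrt((xs[i1] - xs[anchor])^2 + (ys[i1] - ys[anchor])^2)
      g0 <- seg[i0]; g1 <- seg[i1]
      close_fixation(seg[fix_start:anchor])
      fix_start <- i1 + 1L
      if (amp < min_amplitude) {
        add_disc(t[seg[anchor]], t[g1], "small_saccade")
        sacc_sample[g0:g1] <- TRUE
      } else {
        saccades[[length(saccades) + 1L]] <-
          data.frame(t_on = t[seg[anchor]], t_off = t[g1],
                     x_start = xs[anchor], y_start = ys[anchor],
                     x_end = xs[i1], y_end = ys[i1],
                     amplitude = amp, peak_velocity = max(v[i0:i1]))
        sacc_sample[g0:g1] <- TRUE
      }
    }
    if (fix_start <= m) close_fixation(seg[fix_start:m])
  }

  bind <- function(l, cols) {
    if (length(l) == 0L)
      return(stats::setNames(as.data.frame(rep(list(numeric(0)), length(cols))),
                             cols))
    do.call(rbind, l)
  }
  sac <- bind(saccades, c("t_on", "t_off", "x_start", "y_start", "x_end",
                          "y_end", "amplitude", "peak_velocity"))
  fix <- bind(fixations, c("t_on", "t_off", "x", "y", "duration"))
  dis <- if (length(discarded) == 0L)
    data.frame(t_on = numeric(0), t_off = numeric(0), reason = character(0))
  else do.call(rbind, discarded)
  ord <- order(sac$t_on); sac <- sac[ord, , drop = FALSE]
  ord <- order(fix$t_on); fix <- fix[ord, , drop = FALSE]
  ord <- order(dis$t_on); dis <- dis[ord, , drop = FALSE]
  rownames(sac) <- rownames(fix) <- rownames(dis) <- NULL
  structure(list(saccades = sac, fixations = fix, discarded = dis,
                 saccade_sample = sacc_sample, t = t, x = x, y = y,
                 valid = valid),
            class = "event_sequence")
}

#' Write an event sequence to CSV
#'
#' Layout: `participant,stimulus,type,t_on,t_off,x_start,y_start,x_end,y_end,
#' amplitude_deg,reason`.
#'
#' @param events `event_sequence`.
#' @param participant,stimulus labels for the output rows.
#' @param path file path.
#' @export
write_events <- function(events, participant, stimulus, path) {
  stopifnot(inherits(events, "event_sequence"))
  sac <- events$saccades
  fix <- events$fixations
  dis <- events$discarded
  rows <- rbind(
    data.frame(type = rep("saccade", nrow(sac)), t_on = sac$t_on,
               t_off = sac$t_off, x_start = sac$x_start, y_start = sac$y_start,
               x_end = sac$x_end, y_end = sac$y_end,
               amplitude_deg = sac$amplitude, reason = ""),
    data.frame(type = rep("fixation", nrow(fix)), t_on = fix$t_on,
               t_off = fix$t_off, x_start = fix$x, y_start = fix$y,
               x_end = fix$x, y_end = fix$y, amplitude_deg = NA_real_,
               reason = ""),
    data.frame(type = rep("discard", nrow(dis)), t_on = dis$t_on,
               t_off = dis$t_off, x_start = NA_real_, y_start = NA_real_,
               x_end = NA_real_, y_end = NA_real_, amplitude_deg = NA_real_,
               reason = dis$reason))
  rows <- rows[order(rows$t_on), , drop = FALSE]
  rows <- cbind(participant = participant, stimulus = stimulus, rows)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
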