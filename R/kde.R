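#' Fit a 2-D Gaussian kernel density to control gaze positions
#'
#' f(x, y) = (1/n) sum_i N(x; x_i, h^2) N(y; y_i, h^2), evaluated exactly by
#' direct summation; h is the kernel standard deviation (default 1.5 degrees,
#' roughly foveal extent).
#'
#' @param frame_points data.frame or matrix of support points (`x`, `y`,
#'   degrees).
#' @param h kernel SD in degrees (> 0).
#' @param allow_single permit a single support point (testing hook; the
#'   analysis requires >= 2).
#' @return object of class `kde_model`.
#' @export
kde_fit <- function(frame_points, h = 1.5, allow_single = FALSE) {
  if (h <= 0) stop("h must be > 0")
  pts <- as.matrix(as.data.frame(frame_points)[, c("x", "y")])
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 2L && !(allow_single && nrow(pts) == 1L))
    stop("need >= 2 support points")
  structure(list(support = pts, h = h), class = "kde_model")
}

#' Evaluate a fitted KDE
#'
#' @param model `kde_model`.
#' @param x,y evaluation coordinates (vectors, degrees).
#' @return densities in deg^-2.
#' @export
kde_eval <- function(model, x, y) {
  stopifnot(inherits(model, "kde_model"), length(x) == length(y))
  h2 <- model$h^2
  sx <- model$support[, 1]; sy <- model$support[, 2]
  norm <- 1 / (2 * pi * h2)
  vapply(seq_along(x), function(i) {
    mean(norm * exp(-((x[i] - sx)^2 + (y[i] - sy)^2) / (2 * h2)))
  }, numeric(1))
}

#' Per-frame average gaze positions for a video
#'
#' Averages the (at most two, at 60 Hz gaze and 30 frames/s video) valid,
#' non-saccadic samples falling in each half-open frame interval
#' \[k/fps, (k+1)/fps); frames with no usable sample are undefined (`NA`).
#'
#' @param trace merged degrees trace.
#' @param events `event_sequence` for the same trace (saccadic samples are
#'   excluded).
#' @param frame_rate frames/s (default 30).
#' @param duration video duration in seconds (default: last timestamp).
#' @return data.frame `frame` (0-based), `t_mid`, `x`, `y`, `n_samples`.
#' @export
frame_gaze <- function(trace, events, frame_rate = 30, duration = NULL) {
  stopifnot(inherits(events, "event_sequence"))
  if (is.null(duration)) duration <- max(trace$t) + 1 / frame_rate / 2
  n_frames <- ceiling(duration * frame_rate - 1e-9)
  usable <- trace$valid & !events$saccade_sample
  fr <- floor(trace$t * frame_rate + 1e-9)       # boundary samples -> later frame
  fr[fr >= n_frames] <- NA
  ok <- usable & !is.na(fr)
  xs <- tapply(trace$x[ok], factor(fr[ok], levels = 0:(n_frames - 1)), mean)
  ys <- tapply(trace$y[ok], factor(fr[ok], levels = 0:(n_frames - 1)), mean)
  ns <- tapply(rep(1, sum(ok)), factor(fr[ok], levels = 0:(n_frames - 1)), sum)
  data.frame(frame = 0:(n_frames - 1),
             t_mid = (0:(n_frames - 1) + 0.5) / frame_rate,
             x = as.numeric(xs), y = as.numeric(ys),
             n_samples = ifelse(is.na(ns), 0L, as.integer(ns)))
}

#' Per-frame KDE probability scores for a cohort
#'
#' For every video frame: control gaze positions are screened for outliers
#' with a seeded isolation forest (the `contamination` fraction with the
#' highest anomaly scores is dropped), a Gaussian KDE is fitted on the
#' survivors, impaired participants are scored against that model, and each
#' control is scored leave-one-out (against the model refit without that
#' control's own support point). Frames with fewer than 2 surviving controls
#' are skipped for all participants.
#'
#' @param frame_positions list (one element per participant) of data.frames
#'   from [frame_gaze()], all with the same frame count.
#' @param groups character vector of group labels per participant (`"none"` =
#'   control).
#' @param h kernel SD (degrees).
#' @param contamination fraction of controls dropped per frame (default
#'   0.05; the number dropped is `floor(contamination * n)`).
#' @param n_trees isolation-forest size (default 100).
#' @param seed RNG seed for the forest.
#' @return object of class `kde_trace_set`: list with `scores` (participants
#'   x frames matrix of densities, deg^-2), `mean_score` (per participant,
#'   mean over defined frames), `frame_t` (frame mid-times), `groups`,
#'   `skipped` (frame indices skipped).
#' @export
kde_scores <- function(frame_positions, groups, h = 1.5, contamination = 0.05,
                       n_trees = 100, seed = 1) {
  P <- length(frame_positions)
  stopifnot(P == length(groups))
  ctrl <- which(groups == "none")
  if (length(ctrl) < 3L) stop("need >= 3 control participants")
  nf <- nrow(frame_positions[[1]])
  X <- vapply(frame_positions, function(d) d$x, numeric(nf))
  Y <- vapply(frame_positions, function(d) d$y, numeric(nf))  # nf x P
  scores <- matrix(NA_real_, P, nf)
  skipped <- integer(0)
  norm <- 1 / (2 * pi * h^2)
  for (f in seq_len(nf)) {
    cx <- X[f, ctrl]; cy <- Y[f, ctrl]
    def <- which(is.finite(cx) & is.finite(cy))
    if (length(def) < 2L) { skipped <- c(skipped, f); next }
    sup_ids <- ctrl[def]
    n_out <- floor(contamination * length(def))
    if (n_out > 0L && length(def) - n_out >= 2L) {
      sc <- isoforest_scores(cbind(cx[def], cy[def]), n_trees,
                             (seed + f) %% 2147483647L)
      keep <- order(sc)[seq_len(length(def) - n_out)]
      sup_ids <- sup_ids[sort(keep)]
    }
    ns <- length(sup_ids)
    if (ns < 2L) { skipped <- c(skipped, f); next }
    sx <- X[f, sup_ids]; sy <- Y[f, sup_ids]
    px <- X[f, ]; py <- Y[f, ]
    fin <- is.finite(px) & is.finite(py)
    if (!any(fin)) { skipped <- c(skipped, f); next }
    d2 <- outer(px[fin], sx, `-`)^2 + outer(py[fin], sy, `-`)^2
    K <- norm * exp(-d2 / (2 * h^2))
    tot <- rowSums(K)
    row_of <- match(seq_len(P), which(fin))
    for (j in seq_len(P)) {
      r <- row_of[j]
      if (is.na(r)) next
      pos <- match(j, sup_ids)
      if (groups[j] == "none" && !is.na(pos)) {
        if (ns >= 3L) scores[j, f] <- (tot[r] - K[r, pos]) / (ns - 1)
        # ns == 2: removing self leaves a single support point; skip this control
      } else {
        scores[j, f] <- tot[r] / ns
      }
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  mean_score[!is.finite(mean_score)] <- NA_real_
  structure(list(scores = scores, mean_score = mean_score,
                 frame_t = frame_positions[[1]]$t_mid, groups = groups,
                 skipped = skipped),
            class = "kde_trace_set")
}
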