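#' Aligned saccade endpoints
#'
#' Translates every retained saccade so its start sits at the origin; the
#' resulting (dx, dy) cloud is what BCEA, SLV and the saccade-map feature bank
#' operate on.
#'
#' @param events an `event_sequence`, or a data.frame of saccades with
#'   `x_start`, `y_start`, `x_end`, `y_end`.
#' @return data.frame with `dx`, `dy` (degrees).
#' @export
aligned_endpoints <- function(events) {
  sac <- if (inherits(events, "event_sequence")) events$saccades else events
  data.frame(dx = sac$x_end - sac$x_start, dy = sac$y_end - sac$y_start)
}

#' Median saccade amplitude
#'
#' One summary value per participant per stimulus; the saccade-amplitude
#' distribution is skewed, hence the median. Returns `NA` (with a warning
#' attribute consumed by the biomarker table) when no saccades were retained.
#'
#' @param events `event_sequence` or numeric vector of amplitudes.
#' @return degrees (scalar).
#' @export
median_amplitude <- function(events) {
  amps <- if (inherits(events, "event_sequence")) events$saccades$amplitude
          else events
  if (length(amps) == 0L) return(NA_real_)
  stats::median(amps)
}

#' 95% bivariate contour ellipse area of aligned saccade endpoints
#'
#' BCEA = 2 k pi sigma_dx sigma_dy sqrt(1 - rho^2), with
#' k = -ln(1 - P) (P = 0.95 gives k = ln 20 ~ 2.9957), sample SDs and sample
#' correlation. Degenerate clouds (fewer than 3 points, zero variance, or
#' perfectly collinear points) return 0 carrying attribute
#' `degenerate = TRUE` so cohort tables stay rectangular.
#'
#' @param endpoints data.frame `dx`, `dy` (from [aligned_endpoints()]).
#' @param p probability mass of the ellipse (default 0.95).
#' @return deg^2 (scalar).
#' @export
bcea95 <- function(endpoints, p = 0.95) {
  stopifnot(p > 0, p < 1)
  if (nrow(endpoints) < 3L)
    return(structure(0, degenerate = TRUE))
  sx <- stats::sd(endpoints$dx)
  sy <- stats::sd(endpoints$dy)
  if (sx == 0 || sy == 0) return(structure(0, degenerate = TRUE))
  rho <- stats::cor(endpoints$dx, endpoints$dy)
  if (!is.finite(rho) || abs(rho) >= 1 - 1e-12)
    return(structure(0, degenerate = TRUE))
  k <- -log(1 - p)
  2 * k * pi * sx * sy * sqrt(1 - rho^2)
}

#' Proportion of saccades landing on visual-field loss locations (SLV)
#'
#' Fraction of aligned saccade endpoints falling inside the gaze-relative
#' scotoma mask; the denominator is all retained saccades. An empty mask
#' yields 0.
#'
#' @param events `event_sequence` (>= 1 retained saccade).
#' @param mask `scotoma_mask`.
#' @return proportion in \[0, 1\].
#' @export
slv <- function(events, mask) {
  ep <- aligned_endpoints(events)
  if (nrow(ep) == 0L) return(NA_real_)
  if (nrow(mask$cells) == 0L) return(0)
  mean(point_in_mask(mask, ep$dx, ep$dy))
}

#' Saccade-map feature bank (84 features)
#'
#' Aligned saccade endpoints binned on a fixed 12 x 7 grid of 4 x 4 degree
#' cells centred on the origin (spanning +-24 x +-14 degrees), counts
#' normalised by the total saccade count; endpoints outside the span
#' accumulate into the nearest edge cell. This is a documented stand-in for
#' the saccade-map feature bank of the original analysis, whose exact
#' definition is not public; it is deliberately pluggable (any function
#' returning a fixed-length named numeric vector can replace it in
#' [build_feature_table()]).
#'
#' @param events `event_sequence` or aligned-endpoint data.frame.
#' @param smooth_sd SD, in cells, of an optional Gaussian blur over the grid
#'   (0 = raw bin proportions). Saccade-map analyses conventionally smooth
#'   the endpoint density; the classifier uses `smooth_sd = 1`, which pools
#'   neighbouring cells and stabilises the bank at realistic saccade counts.
#' @return named numeric vector of length 84 (`map_c<i>_r<j>`), summing to 1
#'   when at least one saccade exists; all-zero with attribute `empty = TRUE`
#'   otherwise.
#' @export
saccade_map_features <- function(events, smooth_sd = 0) {
  ep <- if (is.data.frame(events) && all(c("dx", "dy") %in% names(events)))
    events else aligned_endpoints(events)
  nx <- 12L; ny <- 7L; cell <- 4
  nm <- as.vector(outer(seq_len(nx), seq_len(ny),
                        function(i, j) sprintf("map_c%02d_r%d", i, j)))
  if (nrow(ep) == 0L)
    return(structure(stats::setNames(rep(0, nx * ny), nm), empty = TRUE))
  ix <- clamp(floor((ep$dx + nx / 2 * cell) / cell) + 1L, 1L, nx)
  iy <- clamp(floor((ep$dy + ny / 2 * cell) / cell) + 1L, 1L, ny)
  counts <- table(factor(ix, levels = seq_len(nx)),
                  factor(iy, levels = seq_len(ny)))
  m <- matrix(as.vector(counts) / nrow(ep), nx, ny)
  if (smooth_sd > 0) {
    r <- ceiling(3 * smooth_sd)
    ker <- outer(-r:r, -r:r,
                 function(i, j) exp(-(i^2 + j^2) / (2 * smooth_sd^2)))
    ker <- ker / sum(ker)
    sm <- matrix(0, nx, ny)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      ii <- clamp(i + (-r:r), 1L, nx)       # clamped-index edge handling
      jj <- clamp(j + (-r:r), 1L, ny)
      sm[i, j] <- sum(m[ii, jj] * ker)
    }
    m <- sm / sum(sm)
  }
  stats::setNames(as.vector(m), nm)
}
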