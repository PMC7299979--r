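#' Standard 24-2 perimetry grid
#'
#' Returns the 54 test locations of the 24-2 pattern in visual-field degrees
#' (x positive temporal-right, y positive superior): 6 degree spacing, offset 3
#' degrees from both meridians, with the nasal row extension to 27 degrees.
#' The two physiologic blind-spot locations sit at (15, 3) and (15, -3).
#'
#' @param drop_blind_spot drop the two blind-spot locations (52 points).
#' @return data.frame with columns `x`, `y` (degrees).
#' @export
grid_242 <- function(drop_blind_spot = FALSE) {
  rows <- list(
    c(y = 21, from = -9,  to = 9),
    c(y = 15, from = -15, to = 15),
    c(y = 9,  from = -21, to = 21),
    c(y = 3,  from = -21, to = 27),
    c(y = -3, from = -21, to = 27),
    c(y = -9, from = -21, to = 21),
    c(y = -15, from = -15, to = 15),
    c(y = -21, from = -9,  to = 9)
  )
  pts <- do.call(rbind, lapply(rows, function(r) {
    x <- seq(r[["from"]], r[["to"]], by = 6)
    data.frame(x = x, y = rep(r[["y"]], length(x)))
  }))
  if (drop_blind_spot)
    pts <- pts[!(pts$x == 15 & abs(pts$y) == 3), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Construct a monocular visual field
#'
#' @param eye `"left"` or `"right"`.
#' @param points data.frame with columns `x`, `y` (degrees) and `sensitivity`
#'   (dB, in \[0, 40\]); must follow the 24-2 layout (blind-spot points may be
#'   absent).
#' @param md mean deviation in dB (supplied by the perimeter, not recomputed).
#' @return object of class `monocular_field`.
#' @export
monocular_field <- function(eye, points, md) {
  eye <- match.arg(eye, c("left", "right"))
  stopifnot(is.data.frame(points), all(c("x", "y", "sensitivity") %in% names(points)))
  if (!is.finite(md)) stop("md must be finite")
  if (any(!is.finite(points$sensitivity)) ||
      any(points$sensitivity < 0 | points$sensitivity > 40))
    stop("sensitivities must lie in [0, 40] dB")
  key <- paste(points$x, points$y)
  full <- grid_242()
  ok <- key %in% paste(full$x, full$y)
  if (!all(ok))
    stop("points off the 24-2 grid: ", paste(key[!ok], collapse = "; "))
  if (anyDuplicated(key)) stop("duplicated grid locations")
  structure(list(eye = eye,
                 points = points[order(-points$y, points$x), , drop = FALSE],
                 md = md),
            class = "monocular_field")
}

#' Classify visual-field severity from mean deviation
#'
#' Moderate loss for -12 <= MD <= -6 dB, advanced for MD < -12 dB, none
#' otherwise.
#'
#' @param md mean deviation (dB).
#' @return `"none"`, `"moderate"` or `"advanced"`.
#' @export
classify_severity <- function(md) {
  if (!is.finite(md)) stop("md must be finite")
  if (md < -12) "advanced" else if (md <= -6) "moderate" else "none"
}

#' Integrate two monocular fields into a binocular field
#'
#' The integrated visual field (IVF) takes the pointwise maximum sensitivity of
#' the two monocular fields at each 24-2 location; severity is classified from
#' the MD of the worse (more negative) eye.
#'
#' @param left,right `monocular_field` objects on the same grid.
#' @return object of class `integrated_field` with `points`, `md_worse_eye`,
#'   `severity`.
#' @export
integrate_fields <- function(left, right) {
  stopifnot(inherits(left, "monocular_field"), inherits(right, "monocular_field"))
  kl <- paste(left$points$x, left$points$y)
  kr <- paste(right$points$x, right$points$y)
  if (length(kl) != length(kr) || !all(kl == kr)) {
    unmatched <- union(setdiff(kl, kr), setdiff(kr, kl))
    stop("grid mismatch at locations: ", paste(unmatched, collapse = "; "))
  }
  pts <- left$points[, c("x", "y")]
  pts$sensitivity <- pmax(left$points$sensitivity, right$points$sensitivity)
  md_worse <- min(left$md, right$md)
  structure(list(points = pts,
                 md_worse_eye = md_worse,
                 severity = classify_severity(md_worse)),
            class = "integrated_field")
}

#' Gaze-relative scotoma mask from an integrated field
#'
#' Loss locations are IVF points whose sensitivity falls below `cutoff`; each
#' contributes a 6x6 degree cell centred on the point, expressed relative to
#' the current gaze position (the simulated scotoma is approximately static in
#' retinal coordinates). Blind-spot locations are excluded. Cell membership is
#' half-open: \[centre-3, centre+3) on each axis.
#'
#' @param ivf `integrated_field`.
#' @param cutoff dB threshold in \[0, 40\]; default 20.
#' @return object of class `scotoma_mask` with `cells` (data.frame x, y of cell
#'   centres, degrees), `half_width` and `severity`.
#' @export
scotoma_mask <- function(ivf, cutoff = 20) {
  stopifnot(inherits(ivf, "integrated_field"))
  if (!is.finite(cutoff) || cutoff < 0 || cutoff > 40)
    stop("cutoff must lie in [0, 40] dB")
  pts <- ivf$points
  keep <- pts$sensitivity < cutoff & !(pts$x == 15 & abs(pts$y) == 3)
  structure(list(cells = pts[keep, c("x", "y"), drop = FALSE],
                 half_width = 3,
                 severity = ivf$severity),
            class = "scotoma_mask")
}

#' Test points against a scotoma mask
#'
#' @param mask `scotoma_mask`.
#' @param x,y gaze-relative coordinates in degrees (vectors).
#' @return logical vector: inside any mask cell.
#' @export
point_in_mask <- function(mask, x, y) {
  stopifnot(inherits(mask, "scotoma_mask"), length(x) == length(y))
  if (nrow(mask$cells) == 0L) return(rep(FALSE, length(x)))
  hw <- mask$half_width
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(mask$cells))) {
    cx <- mask$cells$x[i]; cy <- mask$cells$y[i]
    inside <- inside |
      (x >= cx - hw & x < cx + hw & y >= cy - hw & y < cy + hw)
  }
  inside
}

#' Synthetic monocular perimetry for a severity class
#'
#' Builds left/right 24-2 fields emulating superior binocular field loss of the
#' requested severity: baseline sensitivity ~32 dB with mild eccentricity
#' fall-off, with a superior depression whose depth and extent grow with
#' severity. MD values are planted inside the class definition ranges (none:
#' ~0 dB; moderate: -8 dB; advanced: -16 dB). Labelled synthetic: this is a
#' stand-in for the single real patient's longitudinal perimetry that the
#' original study used, which is not public.
#'
#' @param severity `"none"`, `"moderate"` or `"advanced"`.
#' @return list with `left`, `right` (`monocular_field`) and `ivf`
#'   (`integrated_field`).
#' @export
synthetic_perimetry <- function(severity = c("none", "moderate", "advanced")) {
  severity <- match.arg(severity)
  base_field <- function() {
    g <- grid_242()
    ecc <- sqrt(g$x^2 + g$y^2)
    g$sensitivity <- pmin(40, pmax(0, 33 - 0.15 * ecc))
    g
  }
  depress <- function(g, depth, y_min) {
    hit <- g$y >= y_min
    g$sensitivity[hit] <- pmax(0, g$sensitivity[hit] - depth)
    g
  }
  params <- switch(severity,
    none     = list(depth = 0,  y_min = Inf,  md = -0.5),
    moderate = list(depth = 22, y_min = 9,    md = -8),
    advanced = list(depth = 30, y_min = 3,    md = -16))
  mk <- function(eye) {
    g <- depress(base_field(), params$depth, params$y_min)
    monocular_field(eye, g, params$md)
  }
  left <- mk("left"); right <- mk("right")
  list(left = left, right = right, ivf = integrate_fields(left, right))
}

#' Write / read perimetry JSON
#'
#' JSON layout: `{eye, md, points: [{x_deg, y_deg, db}]}`.
#'
#' @param field `monocular_field`.
#' @param path file path.
#' @export
write_perimetry <- function(field, path) {
  stopifnot(inherits(field, "monocular_field"))
  obj <- list(eye = field$eye, md = field$md,
              points = data.frame(x_deg = field$points$x,
                                  y_deg = field$points$y,
                                  db = field$points$sensitivity))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perimetry
#' @export
read_perimetry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  monocular_field(obj$eye,
                  data.frame(x = obj$points$x_deg, y = obj$points$y_deg,
                             sensitivity = obj$points$db),
                  obj$md)
}
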