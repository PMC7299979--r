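#' Kruskal-Wallis test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (rank H statistic with tie
#' correction, chi-squared reference with k-1 df) returning the pieces the
#' report tables need.
#'
#' @param values numeric vector.
#' @param groups group labels (same length).
#' @return list `chi2`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  keep <- is.finite(values)
  if (length(unique(values[keep])) == 1L)
    return(list(chi2 = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values[keep], droplevels(groups[keep]))
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney U test with rank eta-squared effect size
#'
#' Reports U = min(U_a, U_b), the two-tailed p-value (exact for combined
#' n <= 20 without ties, otherwise normal approximation with tie and
#' continuity correction, via [stats::wilcox.test()]), and the rank
#' effect size eta^2 = Z^2 / (n_a + n_b) where Z comes from the
#' tie-corrected, continuity-corrected normal approximation.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param bonferroni multiply p by this factor (capped at 1); the study
#'   corrects pairwise tests for three comparisons.
#' @return list `U`, `p` (uncorrected), `p_adj`, `z`, `eta2`, `n`.
#' @export
mann_whitney <- function(a, b, bonferroni = 1) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  N <- na + nb
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  U <- min(ua, ub)
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  exact <- (N <= 20) && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  mu <- na * nb / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
  z <- if (sigma == 0) 0 else max(0, abs(ua - mu) - 0.5) / sigma
  list(U = U, p = p, p_adj = min(1, bonferroni * p), z = z,
       eta2 = z^2 / N, n = c(na, nb))
}

#' Group comparison for one feature
#'
#' Kruskal-Wallis across the three impairment conditions followed by the
#' three pairwise Mann-Whitney tests, Bonferroni-corrected for three
#' comparisons.
#'
#' @param values numeric vector.
#' @param groups labels among none/moderate/advanced.
#' @return list `kw` and data.frame `pairwise` (`pair`, `U`, `p_bonferroni`,
#'   `eta2`).
#' @export
group_comparison <- function(values, groups) {
  kw <- kruskal_wallis(values, groups)
  pairs <- list(c("none", "moderate"), c("none", "advanced"),
                c("moderate", "advanced"))
  rows <- lapply(pairs, function(pr) {
    mw <- mann_whitney(values[groups == pr[1]], values[groups == pr[2]],
                       bonferroni = 3)
    data.frame(pair = paste(pr, collapse = "-"), U = mw$U,
               p_bonferroni = mw$p_adj, eta2 = mw$eta2)
  })
  list(kw = kw, pairwise = do.call(rbind, rows))
}

#' Empirical ROC between two groups
#'
#' Threshold sweep at midpoints between adjacent unique pooled scores
#' (ties never split); AUC by the trapezoid rule, which equals the
#' Mann-Whitney pair-count probability U/(n1 n2) with half-credit for ties.
#' `direction` declares whether low or high values indicate impairment
#' (saccade amplitude, BCEA and KDE: lower = impaired; SLV: higher =
#' impaired). Sensitivity at 90% specificity is read off the empirical step
#' function: the largest TPR among points with FPR <= 0.10, no interpolation.
#'
#' @param scores_neg scores of the negative (control) group.
#' @param scores_pos scores of the positive (impaired) group.
#' @param direction `"higher"` or `"lower"`: which tail marks impairment.
#' @return object of class `roc_result`: list `points` (fpr, tpr), `auc`,
#'   `sens_at_spec90`, `direction`, `n`.
#' @export
roc <- function(scores_neg, scores_pos, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  scores_neg <- scores_neg[is.finite(scores_neg)]
  scores_pos <- scores_pos[is.finite(scores_pos)]
  if (length(scores_neg) == 0L || length(scores_pos) == 0L)
    stop("both groups must be non-empty")
  sgn <- if (direction == "lower") -1 else 1
  neg <- sgn * scores_neg; pos <- sgn * scores_pos
  u <- sort(unique(c(neg, pos)))
  thr <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thr <- c(Inf, rev(thr), -Inf)         # sweep from strictest to laxest
  tpr <- vapply(thr, function(th) mean(pos >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(neg >= th), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  sens <- max(tpr[fpr <= 0.10 + 1e-12])
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 sens_at_spec90 = sens, direction = direction,
                 n = c(neg = length(neg), pos = length(pos))),
            class = "roc_result")
}

#' Windowed temporal AUC on KDE traces
#'
#' Restricts each participant's per-frame KDE probability trace to the given
#' time windows, takes the mean over defined frames, and computes the ROC
#' between the two requested groups (lower KDE similarity = impaired).
#'
#' @param traces `kde_trace_set` from [kde_scores()].
#' @param windows data.frame/list with `t_start`, `t_end` (seconds),
#'   non-overlapping, inside the video. `NULL` means the full video.
#' @param neg_group,pos_group group labels (default `"none"` vs
#'   `"moderate"`).
#' @return `roc_result`.
#' @export
windowed_auc <- function(traces, windows = NULL, neg_group = "none",
                         pos_group = "moderate") {
  stopifnot(inherits(traces, "kde_trace_set"))
  tt <- traces$frame_t
  keep <- if (is.null(windows)) rep(TRUE, length(tt)) else {
    w <- as.data.frame(windows)
    sel <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(w)))
      sel <- sel | (tt >= w$t_start[i] & tt < w$t_end[i])
    sel
  }
  sub <- traces$scores[, keep, drop = FALSE]
  if (ncol(sub) == 0L || all(!is.finite(sub)))
    stop("window contains no defined frames")
  m <- rowMeans(sub, na.rm = TRUE)
  roc(m[traces$groups == neg_group], m[traces$groups == pos_group],
      direction = "lower")
}

#' Sliding-window AUC scan (descriptive utility)
#'
#' Reports the windowed AUC over a grid of sliding windows. Purely
#' descriptive: window choice for inference must be made by the analyst, not
#' by this scan.
#'
#' @param traces `kde_trace_set`.
#' @param width window width (s).
#' @param step step between window starts (s).
#' @param neg_group,pos_group groups compared.
#' @return data.frame `t_start`, `t_end`, `auc`.
#' @export
window_scan <- function(traces, width = 30, step = 10, neg_group = "none",
                        pos_group = "moderate") {
  t_max <- max(traces$frame_t)
  starts <- seq(0, max(0, t_max - width), by = step)
  rows <- lapply(starts, function(s) {
    r <- tryCatch(windowed_auc(traces,
                               data.frame(t_start = s, t_end = s + width),
                               neg_group, pos_group),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(t_start = s, t_end = s + width, auc = r$auc)
  })
  do.call(rbind, rows)
}

#' Percentile bootstrap confidence interval
#'
#' @param metric function mapping a data vector (or rows of a data.frame) to
#'   a scalar.
#' @param data numeric vector or data.frame (resampled by row).
#' @param B bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric, data, B = 2000, seed = 1, level = 0.95) {
  if (B < 100) stop("B must be >= 100")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 3) stop("need n >= 3")
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 1))
}
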