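# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

# KDE by an explicit double loop over evaluation and support points
oracle_kde <- function(support, h, x, y) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    acc <- 0
    for (j in seq_len(nrow(support))) {
      kx <- exp(-(x[i] - support[j, 1])^2 / (2 * h^2)) / (sqrt(2 * pi) * h)
      ky <- exp(-(y[i] - support[j, 2])^2 / (2 * h^2)) / (sqrt(2 * pi) * h)
      acc <- acc + kx * ky
    }
    out[i] <- acc / nrow(support)
  }
  out
}

# Mann-Whitney U by exhaustive pair counting (half credit for ties)
oracle_u <- function(a, b) {
  ua <- 0
  for (x in a) for (y in b) ua <- ua + (x > y) + 0.5 * (x == y)
  min(ua, length(a) * length(b) - ua)
}

oracle_u_a <- function(a, b) {
  ua <- 0
  for (x in a) for (y in b) ua <- ua + (x > y) + 0.5 * (x == y)
  ua
}

# AUC as the pair-count probability that a positive outranks a negative
oracle_auc <- function(neg, pos) {
  acc <- 0
  for (p in pos) for (n in neg) acc <- acc + (p > n) + 0.5 * (p == n)
  acc / (length(neg) * length(pos))
}

# Gaussian kernel matrix element by element
oracle_kernel <- function(X, gamma) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-gamma * sum((X[i, ] - X[j, ])^2))
  K
}

# Kruskal-Wallis H from first principles (tie-corrected)
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# hand-built degrees trace at a given rate
make_trace <- function(x, y, rate = 60, valid = TRUE) {
  n <- length(x)
  data.frame(t = (seq_len(n) - 1) / rate, x = x, y = y,
             valid = rep_len(valid, n))
}

# trace with one planted displacement profile between two steady fixations
step_trace <- function(pre = 24, post = 24, steps, from = c(0, 0),
                       rate = 60) {
  x <- c(rep(from[1], pre), from[1] + steps, rep(from[1] + steps[length(steps)], post))
  make_trace(x, rep(from[2], length(x)), rate = rate)
}

quiet_effect <- function(...) {
  effect_spec(noise_sd = 0, binocular_jitter = 0, blink_rate = 0,
              participant_gain_sd = 0, ...)
}

null_effect <- function(...) {
  # identical distributions in all three groups
  effect_spec(amplitude_scale = c(none = 1, moderate = 1, advanced = 1),
              spread_scale = c(none = 1, moderate = 1, advanced = 1),
              scotoma_attraction = c(none = 0, moderate = 0, advanced = 0),
              idiosyncrasy = c(none = 0.8, moderate = 0.8, advanced = 0.8),
              ...)
}

tiny_cohort <- function(seed = 1, n = c(3, 2, 2), duration = 20,
                        kind = "image", effect = effect_spec()) {
  cohort_config(n[1], n[2], n[3],
                stimuli = list(stimulus_spec("s1", kind, duration)),
                seed = seed, effect = effect)
}

# match detected saccade onsets against planted truth (tolerance in seconds)
match_onsets <- function(detected_on, truth_on, tol = 1 / 120) {
  sapply(truth_on, function(t0) any(abs(detected_on - t0) <= tol))
}
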