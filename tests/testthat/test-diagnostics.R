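test_that("Kruskal-Wallis matches a first-principles rank computation", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$chi2, oracle_kw_h(v, g), tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # with ties
  set.seed(6)
  v2 <- sample(rep(1:4, 5))
  g2 <- rep(c("a", "b", "c", "d"), each = 5)
  expect_equal(kruskal_wallis(v2, g2)$chi2, oracle_kw_h(v2, g2),
               tolerance = 1e-12)
  # all identical -> H = 0, p = 1
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3)),
               list(chi2 = 0, df = 2, p = 1))
  expect_error(kruskal_wallis(1:5, c("a", "a", "b", "b", "c")), "n >= 2")
})

test_that("Mann-Whitney U, p, and eta-squared behave per the rank conventions", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)   # 2 / C(4,2)
  # same multiset: U = n^2/2, p ~ 1
  mw2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(mw2$U, 8)
  expect_gt(mw2$p, 0.9)
  expect_equal(mw2$eta2, 0)
  # Bonferroni correction is min(1, 3p)
  mw3 <- mann_whitney(c(1, 2), c(3, 4), bonferroni = 3)
  expect_equal(mw3$p_adj, min(1, 3 * mw3$p))
  expect_equal(mann_whitney(c(1, 5, 2), c(1.5, 4, 6), bonferroni = 3)$p_adj,
               min(1, 3 * mann_whitney(c(1, 5, 2), c(1.5, 4, 6))$p))
})

test_that("U equals exhaustive pair counting on random small samples", {
  set.seed(7)
  for (rep in 1:50) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(0:10, na, replace = TRUE) / 2   # ties likely
    b <- sample(0:10, nb, replace = TRUE) / 2
    expect_equal(mann_whitney(a, b)$U, oracle_u(a, b))
  }
})

test_that("ROC handles the canonical separations and tie cases", {
  r <- roc(c(0.1, 0.2), c(0.8, 0.9), "higher")
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_spec90, 1)
  r2 <- roc(c(1, 2, 3), c(1, 2, 3), "higher")
  expect_equal(r2$auc, 0.5)
  # constant scores in both groups
  expect_equal(roc(rep(2, 4), rep(2, 5), "higher")$auc, 0.5)
  # direction: lower values impaired
  expect_equal(roc(c(5, 6), c(1, 2), "lower")$auc, 1)
  # monotone points
  expect_true(all(diff(r2$points$fpr) >= 0) && all(diff(r2$points$tpr) >= 0))
  expect_error(roc(numeric(0), 1:3), "non-empty")
})

test_that("ROC AUC equals the pair-count probability on random score sets", {
  set.seed(8)
  for (rep in 1:50) {
    nn <- sample(3:10, 1); np <- sample(3:10, 1)
    neg <- sample(0:12, nn, replace = TRUE) / 3
    pos <- sample(0:12, np, replace = TRUE) / 3 + runif(1, 0, 0.5)
    r <- roc(neg, pos, "higher")
    expect_equal(r$auc, oracle_auc(neg, pos), tolerance = 1e-12)
    expect_equal(r$auc, oracle_u_a(pos, neg) / (nn * np), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(9)
  neg <- rnorm(12); pos <- rnorm(10, 0.8)
  a0 <- roc(neg, pos, "higher")$auc
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) atan(x) * 5 + 2)) {
    expect_equal(roc(f(neg), f(pos), "higher")$auc, a0, tolerance = 1e-12)
  }
})

test_that("sensitivity at 90% specificity reads the empirical step function", {
  # 10 controls: one exceeds any threshold below 10 -> fpr 0.1 allowed
  neg <- c(1:9 / 10, 0.95)
  pos <- c(0.5, 0.92, 0.97)
  r <- roc(neg, pos, "higher")
  # at threshold between 0.95 and 0.92: fpr = 0.1, tpr = 2/3
  expect_equal(r$sens_at_spec90, 2 / 3)
})

test_that("windowed AUC equals full AUC on the whole video and errors when empty", {
  nf <- 60
  mk <- function(m) data.frame(frame = 0:(nf - 1),
                               t_mid = (0:(nf - 1) + 0.5) / 30,
                               x = rnorm(nf, m), y = rnorm(nf, m),
                               n_samples = 2L)
  set.seed(10)
  fp <- c(lapply(1:5, function(i) mk(0)), lapply(1:4, function(i) mk(1.5)))
  kt <- kde_scores(fp, c(rep("none", 5), rep("moderate", 4)),
                   contamination = 0)
  full <- windowed_auc(kt, NULL)
  whole <- windowed_auc(kt, data.frame(t_start = 0, t_end = nf / 30))
  expect_equal(whole$auc, full$auc)
  expect_error(windowed_auc(kt, data.frame(t_start = 100, t_end = 120)),
               "no defined frames")
  sc <- window_scan(kt, width = 1, step = 0.5)
  expect_true(all(sc$auc >= 0 & sc$auc <= 1))
})

test_that("bootstrap CI is degenerate on constants and validates inputs", {
  expect_equal(bootstrap_ci(median, rep(3, 10), B = 200), c(3, 3))
  expect_error(bootstrap_ci(median, rnorm(10), B = 1), ">= 100")
  expect_error(bootstrap_ci(median, c(1, 2), B = 200), "n >= 3")
})

test_that("bootstrap CI of a normal-sample median covers zero", {
  set.seed(11)
  hits <- 0
  for (rep in 1:60) {
    x <- rnorm(60)
    ci <- bootstrap_ci(median, x, B = 300, seed = rep)
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(hits / 60, 0.9)
})

test_that("group comparison assembles omnibus and Bonferroni pairwise rows", {
  set.seed(12)
  v <- c(rnorm(8, 0), rnorm(6, 1), rnorm(6, 2))
  g <- c(rep("none", 8), rep("moderate", 6), rep("advanced", 6))
  gc <- group_comparison(v, g)
  expect_equal(nrow(gc$pairwise), 3)
  expect_true(all(gc$pairwise$p_bonferroni >= 0 & gc$pairwise$p_bonferroni <= 1))
  expect_true(all(gc$pairwise$U >= 0))
  expect_true(all(gc$pairwise$eta2 >= 0 & gc$pairwise$eta2 <= 1))
  mw <- mann_whitney(v[g == "none"], v[g == "moderate"], bonferroni = 3)
  expect_equal(gc$pairwise$U[1], mw$U)
})

test_that("ROC AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (rep in 1:10) {
    neg <- rnorm(12); pos <- rnorm(9, 0.7)
    ours <- roc(neg, pos, "higher")$auc
    ref <- suppressMessages(pROC::auc(
      response = rep(c(0, 1), c(12, 9)), predictor = c(neg, pos),
      direction = "<"))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})
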