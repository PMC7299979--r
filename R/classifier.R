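#' Standardize a feature matrix on training statistics
#'
#' @param X numeric matrix (rows = participants).
#' @param center,scale optional precomputed training statistics; computed
#'   from `X` when `NULL`.
#' @return list `X` (standardized), `center`, `scale` (zero-variance columns
#'   get scale 1).
#' @export
standardize_features <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Gaussian kernel matrix between feature vectors
#'
#' K_ij = exp(-gamma * ||X_i - X_j||^2). The squared-distance form
#' `form = "printed"` (K_ij = gamma * ||X_i - X_j||^2) is kept for
#' comparison; it is a scaled distance, not a kernel, and is not used by the
#' classifier.
#'
#' @param X numeric matrix (rows = observations), already standardized.
#' @param gamma kernel width (> 0).
#' @param Y optional second matrix for a cross-kernel (defaults to `X`).
#' @param form `"gaussian"` (default) or `"printed"`.
#' @return matrix `nrow(X)` x `nrow(Y)`.
#' @export
kernel_matrix <- function(X, gamma, Y = NULL, form = c("gaussian", "printed")) {
  form <- match.arg(form)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (is.null(Y)) Y <- X
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  if (form == "printed") gamma * d2 else exp(-gamma * d2)
}

#' Kernel PCA on a training kernel matrix
#'
#' Double-centers K, eigendecomposes it, and retains up to `n_components`
#' components with positive eigenvalues (requests beyond the positive
#' spectrum are truncated with a warning). Projections are alpha-weighted
#' kernel sums scaled by 1/sqrt(eigenvalue), so training projections have
#' unit variance structure; out-of-fold points are projected through the
#' centered cross-kernel.
#'
#' @param K training kernel matrix (n x n).
#' @param n_components requested dimensionality.
#' @return object of class `kpca_model`.
#' @export
kpca_fit <- function(K, n_components) {
  n <- nrow(K)
  one <- matrix(1 / n, n, n)
  Kc <- K - one %*% K - K %*% one + one %*% K %*% one
  eg <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-10 * max(abs(eg$values), 1))
  if (length(pos) < n_components) {
    warning("only ", length(pos), " positive components available; truncating")
    n_components <- length(pos)
  }
  idx <- pos[seq_len(n_components)]
  structure(list(K_train = K, V = eg$vectors[, idx, drop = FALSE],
                 lambda = eg$values[idx],
                 col_means = colMeans(K), total_mean = mean(K)),
            class = "kpca_model")
}

#' Project points through a fitted kernel PCA
#'
#' @param model `kpca_model`.
#' @param K_cross kernel matrix between new points (rows) and the training
#'   points (columns); omit to project the training set itself.
#' @return matrix of projections (rows = points, cols = components).
#' @export
kpca_project <- function(model, K_cross = NULL) {
  if (is.null(K_cross)) K_cross <- model$K_train
  n <- length(model$col_means)
  stopifnot(ncol(K_cross) == n)
  Kc <- sweep(K_cross, 2, model$col_means) -
    matrix(rowMeans(K_cross), nrow(K_cross), n) + model$total_mean
  Kc %*% sweep(model$V, 2, sqrt(model$lambda), "/")
}

#' Fit a discrete AdaBoost ensemble of decision trees
#'
#' Classic exponential-loss reweighting with depth-limited
#' [rpart::rpart()] trees as weak learners and a shrinkage factor on the
#' stage weights. Initial case weights are class-balanced (each class carries
#' half the total weight), which removes the systematic tilt against the
#' held-out participant's class that the one-sample imbalance of
#' leave-one-out folds would otherwise induce. Training stops early if a
#' weak learner achieves zero weighted error (its vote is capped) or no
#' better than chance.
#'
#' @param X numeric matrix of inputs.
#' @param y labels coercible to two classes; the second factor level is
#'   scored positive.
#' @param rounds boosting rounds (default 50).
#' @param depth maximum tree depth (default 1: stumps).
#' @param learning_rate shrinkage on stage weights (default 1).
#' @param seed RNG seed (rpart tie-breaks).
#' @return object of class `adaboost_model`.
#' @export
adaboost_fit <- function(X, y, rounds = 50, depth = 1, learning_rate = 1,
                         seed = 1) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("binary labels required")
  ypm <- ifelse(y == levels(y)[2], 1, -1)
  n <- nrow(X)
  w <- as.numeric(1 / (2 * table(y)[y]))
  w <- w / sum(w)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  trees <- list(); alphas <- numeric(0)
  set.seed(seed)
  ctl <- rpart::rpart.control(maxdepth = depth, minsplit = 2, minbucket = 1,
                              cp = -1, xval = 0, maxcompete = 0,
                              maxsurrogate = 0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(yy ~ ., data = cbind(yy = y, df), weights = w,
                        method = "class", control = ctl)
    pred <- ifelse(stats::predict(fit, df, type = "class") == levels(y)[2],
                   1, -1)
    err <- sum(w * (pred != ypm))
    if (err >= 0.5 - 1e-12) {
      if (m == 1) { trees <- list(fit); alphas <- 0 }
      break
    }
    alpha <- if (err < 1e-12) 5 else 0.5 * log((1 - err) / err)
    alpha <- learning_rate * alpha
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-12) break
    w <- w * exp(-alpha * ypm * pred)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y),
                 n_features = ncol(X)),
            class = "adaboost_model")
}

#' Real-valued AdaBoost decision score
#'
#' Weighted sum of the weak learners' votes; positive values favour the
#' second class level.
#'
#' @param model `adaboost_model`.
#' @param X numeric matrix of inputs.
#' @return numeric decision scores.
#' @export
adaboost_score <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  s <- numeric(nrow(df))
  for (m in seq_along(model$trees)) {
    pred <- ifelse(stats::predict(model$trees[[m]], df, type = "class") ==
                     model$levels[2], 1, -1)
    s <- s + model$alphas[m] * pred
  }
  s
}

#' Weighted training error per boosting round (diagnostic)
#'
#' @param model `adaboost_model`.
#' @param X,y the training data.
#' @return numeric vector of ensemble 0-1 training error after each round.
#' @export
adaboost_staged_error <- function(model, X, y) {
  y <- factor(y, levels = model$levels)
  ypm <- ifelse(y == model$levels[2], 1, -1)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  s <- numeric(nrow(df))
  errs <- numeric(length(model$trees))
  for (m in seq_along(model$trees)) {
    pred <- ifelse(stats::predict(model$trees[[m]], df, type = "class") ==
                     model$levels[2], 1, -1)
    s <- s + model$alphas[m] * pred
    errs[m] <- mean(sign(s) * ypm <= 0)
  }
  errs
}

#' Default classifier hyperparameter grid
#'
#' gamma values are per-dimension (divided by the feature count at fit
#' time).
#'
#' @return list of vectors `gamma_over_d`, `n_components`, `depth`,
#'   `learning_rate`.
#' @export
default_hyper_grid <- function() {
  list(gamma_over_d = c(0.01, 0.1, 1), n_components = c(5, 10, 15),
       depth = c(1, 2, 3), learning_rate = c(0.1, 0.5, 1.0))
}

# fit standardize -> KPCA -> AdaBoost on training rows; project/score others
fit_kpca_boost <- function(X_train, y_train, hyper, rounds, seed) {
  std <- standardize_features(X_train)
  gamma <- hyper$gamma_over_d / ncol(X_train)
  K <- kernel_matrix(std$X, gamma)
  ncomp <- min(hyper$n_components, nrow(X_train) - 1L)
  kp <- suppressWarnings(kpca_fit(K, ncomp))
  Z <- kpca_project(kp)
  ab <- adaboost_fit(Z, y_train, rounds = rounds, depth = hyper$depth,
                     learning_rate = hyper$learning_rate, seed = seed)
  list(std = std, gamma = gamma, kp = kp, ab = ab,
       train_scores = adaboost_score(ab, Z))
}

score_kpca_boost <- function(fit, X_new) {
  Xs <- sweep(sweep(X_new, 2, fit$std$center), 2, fit$std$scale, "/")
  Kc <- kernel_matrix(Xs, fit$gamma, Y = fit$std$X)
  Z <- kpca_project(fit$kp, Kc)
  adaboost_score(fit$ab, Z)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

hyper_grid_rows <- function(grid) {
  expand.grid(gamma_over_d = grid$gamma_over_d,
              n_components = grid$n_components, depth = grid$depth,
              learning_rate = grid$learning_rate,
              KEEP.OUT.ATTRS = FALSE)
}

#' Leave-one-out evaluation of the KPCA + AdaBoost classifier
#'
#' For each participant, an inner stratified cross-validation on the
#' remaining N-1 selects the hyperparameters (Gaussian kernel width, number
#' of kernel principal components, tree depth, learning rate) by pooled
#' inner AUC; standardization statistics, the KPCA eigenbasis and the
#' boosted ensemble are then fit on those N-1 and applied to the held-out
#' participant. Pooled held-out decision scores yield the ROC. Nothing from
#' the held-out row ever enters the fold's fitted model.
#'
#' @param X numeric feature matrix (rows = participants).
#' @param labels binary group labels; `positive` marks the impaired class.
#' @param hyper_grid list as [default_hyper_grid()]; a single-combination
#'   grid skips the inner CV.
#' @param seed RNG seed (fold splits, tree fitting).
#' @param rounds boosting rounds.
#' @param inner_k inner CV folds (default 5).
#' @param positive label treated as impaired (default `"moderate"` if
#'   present else the rarer label).
#' @param return_models keep each fold's fitted model (standardization,
#'   KPCA basis, ensemble) in the result, for leakage audits.
#' @return object of class `loo_result`: list `scores` (held-out decision
#'   score per participant), `labels`, `roc` (`roc_result`), `chosen`
#'   (data.frame of per-fold hyperparameters), and `models` if requested.
#' @export
adaboost_loo <- function(X, labels, hyper_grid = default_hyper_grid(),
                         seed = 1, rounds = 50, inner_k = 5,
                         positive = NULL, return_models = FALSE) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("binary labels required")
  if (is.null(positive))
    positive <- if ("none" %in% lv) setdiff(lv, "none") else lv[2]
  negative <- setdiff(lv, positive)
  if (min(table(labels)) < 3) stop("each class needs n >= 3")
  y <- factor(labels, levels = c(negative, positive))
  N <- nrow(X)
  grid <- hyper_grid_rows(hyper_grid)
  scores <- numeric(N)
  chosen <- vector("list", N)
  models <- if (return_models) vector("list", N) else NULL
  for (i in seq_len(N)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2) stop("degenerate fold: single-class training set")
    fold_seed <- (seed + 7919L * i) %% 2147483647L
    best <- grid[1, ]
    if (nrow(grid) > 1) {
      folds <- stratified_folds(as.character(ytr), inner_k, fold_seed)
      best_auc <- -Inf
      for (g in seq_len(nrow(grid))) {
        cv_scores <- rep(NA_real_, length(ytr))
        for (f in sort(unique(folds))) {
          tr <- folds != f
          if (length(unique(ytr[tr])) < 2) next
          ft <- fit_kpca_boost(Xtr[tr, , drop = FALSE], ytr[tr], grid[g, ],
                               rounds, fold_seed + f)
          cv_scores[!tr] <- score_kpca_boost(ft, Xtr[!tr, , drop = FALSE]) -
            mean(ft$train_scores)
        }
        ok <- is.finite(cv_scores)
        if (sum(ok & ytr == positive) == 0 || sum(ok & ytr == negative) == 0)
          next
        auc_g <- roc(cv_scores[ok & ytr == negative],
                     cv_scores[ok & ytr == positive], "higher")$auc
        if (auc_g > best_auc) { best_auc <- auc_g; best <- grid[g, ] }
      }
    }
    fit <- fit_kpca_boost(Xtr, ytr, best, rounds, fold_seed)
    scores[i] <- score_kpca_boost(fit, X[i, , drop = FALSE]) -
      mean(fit$train_scores)
    rownames(best) <- NULL
    chosen[[i]] <- cbind(participant = i, best)
    if (return_models) models[[i]] <- fit
  }
  pooled <- roc(scores[y == negative], scores[y == positive], "higher")
  structure(list(scores = scores, labels = labels, roc = pooled,
                 chosen = do.call(rbind, chosen), positive = positive,
                 models = models),
            class = "loo_result")
}
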