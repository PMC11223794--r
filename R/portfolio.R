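#' Bi-level search space: selector and regressor portfolios
#'
#' The default upper-level space crosses 7 feature-selection methods (6
#' selector families plus the pass-through `NONE`) with 12 regressor
#' families, 84 combinations in total. Hyperparameter domains for every
#' family are frozen here; integer and real domains may be log-scaled,
#' categorical domains enumerate their choices.
#'
#' @param fs_portfolio Character vector of selector labels (subset of
#'   [fs_labels()]).
#' @param model_portfolio Character vector of regressor labels (subset of
#'   [model_labels()]).
#' @return An `im_search_space` with the portfolios and per-family
#'   hyperparameter domains.
#' @examples
#' sp <- search_space()
#' nrow(space_pairs(sp))
#' @export
search_space <- function(fs_portfolio = fs_labels(),
                         model_portfolio = model_labels()) {
  stopifnot(all(fs_portfolio %in% fs_labels()),
            all(model_portfolio %in% model_labels()))
  structure(
    list(fs_portfolio = fs_portfolio,
         model_portfolio = model_portfolio,
         hyper_domains = hyper_domains()),
    class = "im_search_space"
  )
}

#' @rdname search_space
#' @export
fs_labels <- function() c("NONE", "GUS", "SFM", "SFS", "RFE", "RFECV", "VT")

#' @rdname search_space
#' @export
model_labels <- function() {
  c("RIDGE", "DTR", "RFR", "GBR", "SVR", "MLPR", "ETR", "BR", "ABR", "STR",
    "HGBR", "XGBR")
}

#' All (selector, model) pairs of a search space
#'
#' @param space An `im_search_space`.
#' @return A tibble with columns `fs_method` and `model`.
#' @export
space_pairs <- function(space) {
  tidyr::expand_grid(fs_method = space$fs_portfolio, model = space$model_portfolio)
}

#' @export
print.im_search_space <- function(x, ...) {
  cat(sprintf("bi-level search space: %d selectors x %d models = %d combinations\n",
              length(x$fs_portfolio), length(x$model_portfolio),
              length(x$fs_portfolio) * length(x$model_portfolio)))
  invisible(x)
}

dom_real <- function(lo, hi, log = FALSE) list(type = "real", lo = lo, hi = hi, log = log)
dom_int <- function(lo, hi, log = FALSE) list(type = "int", lo = lo, hi = hi, log = log)
dom_cat <- function(choices) list(type = "cat", choices = choices)

# Frozen hyperparameter domains per family. Selector parameters are prefixed
# "fs.", model parameters "m.", so one flat map covers both families of a
# candidate configuration without name clashes.
hyper_domains <- function() {
  list(
    NONE = list(),
    GUS = list(
      fs.mode = dom_cat(c("percentile", "k_best")),
      fs.percentile = dom_int(10L, 90L),
      fs.k_best = dom_int(1L, 33L)
    ),
    SFM = list(
      fs.estimator = dom_cat(c("rf", "ridge")),
      fs.n_estimators = dom_int(50L, 200L),
      fs.max_depth = dom_int(2L, 8L),
      fs.threshold = dom_real(0.25, 1.5),
      fs.max_features = dom_int(5L, 33L)
    ),
    SFS = list(
      fs.k_features = dom_int(3L, 20L)
    ),
    RFE = list(
      fs.estimator = dom_cat(c("ridge", "tree")),
      fs.n_features_to_select = dom_int(3L, 25L),
      fs.max_depth = dom_int(2L, 8L)
    ),
    RFECV = list(
      fs.min_features_to_select = dom_int(3L, 15L),
      fs.estimator = dom_cat(c("ridge", "tree")),
      fs.max_depth = dom_int(2L, 8L)
    ),
    VT = list(
      fs.threshold = dom_real(0, 0.3)
    ),
    RIDGE = list(
      m.alpha = dom_real(1e-3, 1e3, log = TRUE)
    ),
    DTR = list(
      m.max_depth = dom_int(2L, 12L),
      m.min_samples_split = dom_int(2L, 20L),
      m.min_samples_leaf = dom_int(1L, 10L)
    ),
    RFR = list(
      m.n_estimators = dom_int(50L, 300L),
      m.max_depth = dom_int(2L, 15L),
      m.min_samples_leaf = dom_int(1L, 10L),
      m.mtry_frac = dom_real(0.2, 1)
    ),
    GBR = list(
      m.n_estimators = dom_int(50L, 300L),
      m.learning_rate = dom_real(0.01, 0.3, log = TRUE),
      m.max_depth = dom_int(2L, 6L),
      m.min_samples_leaf = dom_int(1L, 10L)
    ),
    SVR = list(
      m.C = dom_real(0.1, 100, log = TRUE),
      m.kernel = dom_cat(c("radial", "linear", "sigmoid"))
    ),
    MLPR = list(
      m.hidden = dom_int(8L, 64L, log = TRUE),
      m.alpha = dom_real(1e-5, 1e-1, log = TRUE),
      m.max_iter = dom_int(100L, 300L)
    ),
    ETR = list(
      m.n_estimators = dom_int(50L, 300L),
      m.max_depth = dom_int(2L, 15L),
      m.min_samples_leaf = dom_int(1L, 10L)
    ),
    BR = list(
      m.n_estimators = dom_int(30L, 200L),
      m.max_samples = dom_real(0.5, 1),
      m.max_depth = dom_int(3L, 15L)
    ),
    ABR = list(
      m.n_estimators = dom_int(10L, 80L),
      m.learning_rate = dom_real(0.05, 1, log = TRUE),
      m.max_depth = dom_int(2L, 6L)
    ),
    STR = list(
      m.final_estimator = dom_cat(c("ridge", "lm")),
      m.n_estimators = dom_int(50L, 200L),
      m.max_depth = dom_int(2L, 8L)
    ),
    HGBR = list(
      m.max_iter = dom_int(50L, 300L),
      m.learning_rate = dom_real(0.02, 0.3, log = TRUE),
      m.max_depth = dom_int(2L, 10L),
      m.min_samples_leaf = dom_int(1L, 20L)
    ),
    XGBR = list(
      m.lambda = dom_real(1e-3, 10, log = TRUE),
      m.alpha = dom_real(1e-3, 10, log = TRUE),
      m.subsample = dom_real(0.5, 1),
      m.colsample_bytree = dom_real(0.5, 1),
      m.max_depth = dom_int(2L, 10L),
      m.min_child_weight = dom_int(1L, 10L),
      m.eta = dom_real(1e-3, 0.3, log = TRUE),
      m.gamma = dom_real(0, 5)
    )
  )
}

config_domain <- function(space, fs_method, model) {
  c(space$hyper_domains[[fs_method]], space$hyper_domains[[model]])
}

# ---- internal ridge solver used inside selectors (plumbing, not a model) ----
ridge_solve <- function(X, y, alpha = 1e-2) {
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  pen <- diag(rep(alpha, p))
  pen[1, 1] <- 0
  beta <- tryCatch(
    solve(crossprod(X) + pen, crossprod(X, y)),
    error = function(e) matrix(c(mean(y), rep(0, p - 1L)), ncol = 1)
  )
  drop(beta)
}

ridge_predict <- function(beta, X) drop(cbind(1, X) %*% beta)

# ---- feature selectors -------------------------------------------------------
# Each selector maps (X, y, hp, seed) to a sorted integer vector of kept
# columns; at least one column is always kept (fallback: highest |cor|).

fit_selector <- function(fs_method, X, y, hp, seed) {
  idx <- switch(
    fs_method,
    NONE = seq_len(ncol(X)),
    GUS = sel_gus(X, y, hp),
    SFM = sel_sfm(X, y, hp, seed),
    SFS = sel_sfs(X, y, hp, seed),
    RFE = sel_rfe(X, y, hp),
    RFECV = sel_rfecv(X, y, hp, seed),
    VT = sel_vt(X, hp),
    stop("unknown selector: ", fs_method)
  )
  idx <- sort(unique(idx))
  if (length(idx) == 0L) idx <- which.max(abs(univariate_scores(X, y)))
  idx
}

univariate_scores <- function(X, y) {
  sc <- suppressWarnings(as.vector(stats::cor(X, y)))^2
  sc[is.na(sc)] <- -Inf
  sc
}

sel_gus <- function(X, y, hp) {
  sc <- univariate_scores(X, y)
  k <- if (identical(hp$fs.mode, "k_best")) {
    min(hp$fs.k_best, ncol(X))
  } else {
    max(1L, ceiling(hp$fs.percentile / 100 * ncol(X)))
  }
  order(sc, decreasing = TRUE)[seq_len(k)]
}

sel_sfm <- function(X, y, hp, seed) {
  if (identical(hp$fs.estimator, "rf")) {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = hp$fs.n_estimators,
      max.depth = hp$fs.max_depth, importance = "impurity",
      seed = seed, num.threads = 1
    )
    imp <- fit$variable.importance
  } else {
    imp <- abs(ridge_solve(X, y)[-1L])
  }
  imp[!is.finite(imp)] <- 0
  keep <- which(imp >= hp$fs.threshold * mean(imp))
  if (length(keep) > hp$fs.max_features) {
    keep <- keep[order(imp[keep], decreasing = TRUE)[seq_len(hp$fs.max_features)]]
  }
  keep
}

# Forward sequential selection scored on a seeded holdout with a ridge probe.
sel_sfs <- function(X, y, hp, seed) {
  n <- nrow(X)
  set.seed(seed)
  hold <- sample(n, max(2L, floor(0.3 * n)))
  Xtr <- X[-hold, , drop = FALSE]; ytr <- y[-hold]
  Xte <- X[hold, , drop = FALSE]; yte <- y[hold]
  k <- min(hp$fs.k_features, ncol(X))
  chosen <- integer(0)
  remaining <- seq_len(ncol(X))
  while (length(chosen) < k && length(remaining) > 0L) {
    scores <- vapply(remaining, function(j) {
      cols <- c(chosen, j)
      beta <- ridge_solve(Xtr[, cols, drop = FALSE], ytr)
      pred <- ridge_predict(beta, Xte[, cols, drop = FALSE])
      -mean((yte - pred)^2)
    }, numeric(1))
    best <- remaining[which.max(scores)]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  chosen
}

rfe_ranking <- function(X, y, hp) {
  # returns column indices ordered from last-eliminated (most important)
  # to first-eliminated
  active <- seq_len(ncol(X))
  eliminated <- integer(0)
  while (length(active) > 1L) {
    imp <- if (identical(hp$fs.estimator, "tree")) {
      fit <- rpart::rpart(
        y ~ ., data = data.frame(y = y, X[, active, drop = FALSE]),
        method = "anova",
        control = rpart::rpart.control(maxdepth = hp$fs.max_depth, cp = 1e-4)
      )
      vi <- rep(0, length(active))
      names(vi) <- colnames(X)[active]
      got <- fit$variable.importance
      vi[names(got)[names(got) %in% names(vi)]] <- got[names(got) %in% names(vi)]
      vi
    } else {
      abs(ridge_solve(X[, active, drop = FALSE], y)[-1L])
    }
    imp[!is.finite(imp)] <- 0
    worst <- active[which.min(imp)]
    eliminated <- c(worst, eliminated)
    active <- setdiff(active, worst)
  }
  c(active, eliminated)
}

sel_rfe <- function(X, y, hp) {
  k <- min(hp$fs.n_features_to_select, ncol(X))
  rfe_ranking(X, y, hp)[seq_len(k)]
}

sel_rfecv <- function(X, y, hp, seed) {
  ranking <- rfe_ranking(X, y, hp)
  n <- nrow(X)
  set.seed(seed)
  folds <- sample(rep(1:3, length.out = n))
  kmin <- min(hp$fs.min_features_to_select, ncol(X))
  counts <- unique(pmin(ncol(X), seq(kmin, ncol(X), by = 2L)))
  cv_r2 <- vapply(counts, function(k) {
    cols <- ranking[seq_len(k)]
    r2s <- vapply(1:3, function(f) {
      tr <- folds != f
      beta <- ridge_solve(X[tr, cols, drop = FALSE], y[tr])
      pred <- ridge_predict(beta, X[!tr, cols, drop = FALSE])
      fold_r2(y[!tr], pred)
    }, numeric(1))
    mean(r2s)
  }, numeric(1))
  ranking[seq_len(counts[which.max(cv_r2)])]
}

sel_vt <- function(X, hp) {
  v <- apply(X, 2L, stats::var)
  if (all(v <= 0)) return(integer(0))
  which(v > hp$fs.threshold * max(v))
}

# ---- regressors --------------------------------------------------------------
# Unified interface. Constant columns are dropped before fitting (scale-
# sensitive backends choke on them); the kept set is recorded for predict.

fit_regressor <- function(model, X, y, hp, seed) {
  keep <- which(apply(X, 2L, function(col) stats::var(col) > 0))
  if (length(keep) == 0L) {
    return(structure(list(model = "CONST", mean = mean(y), keep = keep),
                     class = "im_fit"))
  }
  Xk <- X[, keep, drop = FALSE]
  set.seed(seed)
  fit <- switch(
    model,
    RIDGE = fit_ridge(Xk, y, hp),
    DTR = fit_dtr(Xk, y, hp),
    RFR = fit_ranger(Xk, y, hp, seed, extratrees = FALSE,
                     mtry = max(1L, floor(hp$m.mtry_frac * ncol(Xk)))),
    GBR = fit_xgb(Xk, y, seed, nrounds = hp$m.n_estimators,
                  eta = hp$m.learning_rate, max_depth = hp$m.max_depth,
                  min_child_weight = hp$m.min_samples_leaf,
                  tree_method = "exact"),
    SVR = e1071::svm(x = Xk, y = y, type = "eps-regression",
                     kernel = hp$m.kernel, cost = hp$m.C),
    MLPR = nnet::nnet(x = Xk, y = y, size = hp$m.hidden, linout = TRUE,
                      decay = hp$m.alpha, maxit = hp$m.max_iter,
                      trace = FALSE, MaxNWts = 20000L),
    ETR = fit_ranger(Xk, y, hp, seed, extratrees = TRUE, mtry = ncol(Xk)),
    BR = ranger::ranger(
      x = as.data.frame(Xk), y = y, num.trees = hp$m.n_estimators,
      max.depth = hp$m.max_depth, mtry = ncol(Xk), replace = TRUE,
      sample.fraction = hp$m.max_samples, seed = seed, num.threads = 1
    ),
    ABR = fit_adaboost_r2(Xk, y, hp, seed),
    STR = fit_stacking(Xk, y, hp, seed),
    HGBR = fit_xgb(Xk, y, seed, nrounds = hp$m.max_iter,
                   eta = hp$m.learning_rate, max_depth = hp$m.max_depth,
                   min_child_weight = hp$m.min_samples_leaf,
                   tree_method = "hist"),
    XGBR = fit_xgb(Xk, y, seed, nrounds = 150L, eta = hp$m.eta,
                   max_depth = hp$m.max_depth,
                   min_child_weight = hp$m.min_child_weight,
                   tree_method = "hist", subsample = hp$m.subsample,
                   colsample_bytree = hp$m.colsample_bytree,
                   lambda = hp$m.lambda, alpha = hp$m.alpha,
                   gamma = hp$m.gamma),
    stop("unknown model: ", model)
  )
  structure(list(model = model, fit = fit, keep = keep), class = "im_fit")
}

predict_regressor <- function(object, X) {
  if (identical(object$model, "CONST")) return(rep(object$mean, nrow(X)))
  Xk <- X[, object$keep, drop = FALSE]
  fit <- object$fit
  switch(
    object$model,
    RIDGE = ridge_predict(fit, Xk),
    DTR = unname(stats::predict(fit, data.frame(Xk))),
    RFR = ,
    ETR = ,
    BR = stats::predict(fit, data = as.data.frame(Xk), num.threads = 1)$predictions,
    GBR = ,
    HGBR = ,
    XGBR = stats::predict(fit, xgboost::xgb.DMatrix(Xk)),
    SVR = unname(stats::predict(fit, Xk)),
    MLPR = drop(stats::predict(fit, Xk)),
    ABR = predict_adaboost_r2(fit, Xk),
    STR = predict_stacking(fit, Xk),
    stop("unknown model: ", object$model)
  )
}

fit_ridge <- function(X, y, hp) {
  df <- data.frame(y = y, X)
  fit <- MASS::lm.ridge(y ~ ., data = df, lambda = hp$m.alpha)
  stats::coef(fit)
}

fit_dtr <- function(X, y, hp) {
  rpart::rpart(
    y ~ ., data = data.frame(y = y, X), method = "anova",
    control = rpart::rpart.control(
      maxdepth = hp$m.max_depth, minsplit = hp$m.min_samples_split,
      minbucket = hp$m.min_samples_leaf, cp = 1e-5, xval = 0
    )
  )
}

fit_ranger <- function(X, y, hp, seed, extratrees, mtry) {
  args <- list(
    x = as.data.frame(X), y = y, num.trees = hp$m.n_estimators,
    max.depth = hp$m.max_depth, min.node.size = hp$m.min_samples_leaf,
    mtry = mtry, seed = seed, num.threads = 1
  )
  if (extratrees) {
    args$splitrule <- "extratrees"
    args$replace <- FALSE
    args$sample.fraction <- 1
  }
  do.call(ranger::ranger, args)
}

fit_xgb <- function(X, y, seed, nrounds, eta, max_depth, min_child_weight,
                    tree_method, subsample = 1, colsample_bytree = 1,
                    lambda = 1, alpha = 0, gamma = 0) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror", eta = eta, max_depth = max_depth,
      min_child_weight = min_child_weight, tree_method = tree_method,
      subsample = subsample, colsample_bytree = colsample_bytree,
      lambda = lambda, alpha = alpha, gamma = gamma, seed = seed,
      nthread = 1
    ),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

# AdaBoost.R2 (linear loss) over shallow regression trees.
fit_adaboost_r2 <- function(X, y, hp, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  models <- list()
  betas <- numeric(0)
  lr <- hp$m.learning_rate
  set.seed(seed)
  for (t in seq_len(hp$m.n_estimators)) {
    idx <- sample(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(
      y ~ ., data = data.frame(y = y[idx], X[idx, , drop = FALSE]),
      method = "anova",
      control = rpart::rpart.control(maxdepth = hp$m.max_depth, cp = 1e-4, xval = 0)
    )
    pred <- unname(stats::predict(fit, data.frame(X)))
    err <- abs(pred - y)
    D <- max(err)
    if (D <= 0) {
      models[[length(models) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    L <- err / D
    eps <- sum(w * L)
    if (eps >= 0.5) {
      if (length(models) == 0L) {
        models[[1L]] <- fit
        betas <- 0.5
      }
      break
    }
    beta <- eps / (1 - eps)
    models[[length(models) + 1L]] <- fit
    betas <- c(betas, beta)
    w <- w * beta^(lr * (1 - L))
    w <- w / sum(w)
  }
  list(models = models, weights = lr * log(1 / betas))
}

predict_adaboost_r2 <- function(fit, X) {
  preds <- vapply(fit$models, function(m) {
    unname(stats::predict(m, data.frame(X)))
  }, numeric(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X))
  w <- fit$weights
  if (all(w <= 0)) w <- rep(1, length(w))
  apply(preds, 1L, function(p) weighted_median(p, w))
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

# Stacking: ridge + tree + small random forest bases, out-of-fold meta
# features, linear or ridge meta-learner.
fit_stacking <- function(X, y, hp, seed) {
  n <- nrow(X)
  set.seed(seed)
  folds <- sample(rep(1:3, length.out = n))
  base_fit <- function(Xtr, ytr, s) {
    list(
      ridge = ridge_solve(Xtr, ytr, alpha = 1),
      tree = rpart::rpart(
        y ~ ., data = data.frame(y = ytr, Xtr), method = "anova",
        control = rpart::rpart.control(maxdepth = hp$m.max_depth, cp = 1e-4, xval = 0)
      ),
      rf = ranger::ranger(x = as.data.frame(Xtr), y = ytr,
                          num.trees = hp$m.n_estimators,
                          max.depth = hp$m.max_depth, seed = s, num.threads = 1)
    )
  }
  base_predict <- function(b, Xn) {
    cbind(
      ridge = ridge_predict(b$ridge, Xn),
      tree = unname(stats::predict(b$tree, data.frame(Xn))),
      rf = stats::predict(b$rf, data = as.data.frame(Xn), num.threads = 1)$predictions
    )
  }
  meta_X <- matrix(NA_real_, n, 3L)
  for (f in 1:3) {
    tr <- folds != f
    b <- base_fit(X[tr, , drop = FALSE], y[tr], seed + f)
    meta_X[!tr, ] <- base_predict(b, X[!tr, , drop = FALSE])
  }
  meta <- if (identical(hp$m.final_estimator, "lm")) {
    ridge_solve(meta_X, y, alpha = 1e-8)
  } else {
    ridge_solve(meta_X, y, alpha = 1)
  }
  list(bases = base_fit(X, y, seed), meta = meta, base_predict = NULL)
}

predict_stacking <- function(fit, X) {
  mx <- cbind(
    ridge = ridge_predict(fit$bases$ridge, X),
    tree = unname(stats::predict(fit$bases$tree, data.frame(X))),
    rf = stats::predict(fit$bases$rf, data = as.data.frame(X),
                        num.threads = 1)$predictions
  )
  ridge_predict(fit$meta, mx)
}

fold_r2 <- function(y_true, y_pred) {
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) return(-Inf)
  1 - sum((y_true - y_pred)^2) / ss_tot
}
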