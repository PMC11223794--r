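#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, the objective at both optimisation levels.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must have
#'   positive variance.
#' @return A scalar no greater than 1; exactly 1 iff predictions are exact.
#' @examples
#' r2_score(c(1, 2, 3), c(1, 2, 4))
#' @export
r2_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) stop("y_true has zero variance; R² is undefined", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Budget of the bi-level search
#'
#' Presets span quick exploratory runs to an exhaustive sweep of the
#' 84-combination default space: `swift_basic` = 8 upper rounds x 10 TPE
#' trials, `balanced` = 20 x 25, `thorough` = 40 x 60, `best_performance` =
#' 84 x 150. Supplying `upper_rounds`/`tpe_trials` overrides the preset.
#'
#' @param preset Preset name.
#' @param upper_rounds,tpe_trials Optional custom budget.
#' @param cv_folds Cross-validation folds of the objective (default 5).
#' @return An `im_budget` list.
#' @export
automl_budget <- function(preset = c("balanced", "swift_basic", "thorough",
                                     "best_performance"),
                          upper_rounds = NULL, tpe_trials = NULL,
                          cv_folds = 5L) {
  preset <- match.arg(preset)
  presets <- list(
    swift_basic = c(8L, 10L), balanced = c(20L, 25L),
    thorough = c(40L, 60L), best_performance = c(84L, 150L)
  )
  pr <- presets[[preset]]
  b <- list(
    upper_rounds = as.integer(upper_rounds %||% pr[1]),
    tpe_trials = as.integer(tpe_trials %||% pr[2]),
    cv_folds = as.integer(cv_folds),
    preset = if (is.null(upper_rounds) && is.null(tpe_trials)) preset else "custom"
  )
  stopifnot(b$upper_rounds >= 1L, b$tpe_trials >= 1L, b$cv_folds >= 2L)
  class(b) <- "im_budget"
  b
}

#' Cross-validated objective of one candidate configuration
#'
#' Mean out-of-fold R-squared of the pipeline (selector fitted inside each
#' fold on the fold-training data only, then the regressor on the selected
#' columns). A failed fit yields `-Inf` rather than an error so the search
#' can continue.
#'
#' @param config List with `fs_method`, `model` and a `hyperparams` map
#'   covering both families (selector keys prefixed `fs.`, model keys `m.`).
#' @param X Normalized numeric feature matrix (rows = motifs).
#' @param y Numeric response vector.
#' @param cv_folds Number of folds.
#' @param seed Integer seed; folds and stochastic fits are deterministic
#'   in it.
#' @param space An `im_search_space`.
#' @return Mean out-of-fold R-squared (scalar), or `-Inf` on failure.
#' @export
evaluate_config <- function(config, X, y, cv_folds = 5L, seed = 1L,
                            space = search_space()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), n >= 2L * cv_folds)
  hp <- config$hyperparams %||% default_hyperparams(space, config$fs_method, config$model)
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  r2s <- vapply(seq_len(cv_folds), function(f) {
    tr <- folds != f
    tryCatch({
      idx <- fit_selector(config$fs_method, X[tr, , drop = FALSE], y[tr], hp,
                          seed = seed + f)
      fit <- fit_regressor(config$model, X[tr, idx, drop = FALSE], y[tr], hp,
                           seed = seed + f)
      pred <- predict_regressor(fit, X[!tr, idx, drop = FALSE])
      fold_r2(y[!tr], pred)
    }, error = function(e) -Inf)
  }, numeric(1))
  if (any(!is.finite(r2s))) return(-Inf)
  mean(r2s)
}

#' Midpoint default hyperparameters for a configuration
#'
#' @inheritParams tpe_optimize
#' @return A named list covering both families.
#' @export
default_hyperparams <- function(space, fs_method, model) {
  domain <- config_domain(space, fs_method, model)
  lapply(domain, function(d) {
    switch(
      d$type,
      cat = d$choices[1],
      int = as.integer(round(if (isTRUE(d$log)) exp(mean(log(c(d$lo, d$hi))))
                             else mean(c(d$lo, d$hi)))),
      real = if (isTRUE(d$log)) exp(mean(log(c(d$lo, d$hi)))) else mean(c(d$lo, d$hi))
    )
  })
}

stable_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 1000003
  as.integer(h)
}

config_seed <- function(seed, fs_method, model) {
  (abs(as.integer(seed)) %% 100000L) * 10007L + stable_hash(paste(fs_method, model))
}

#' Upper-level Tabu search over (selector, model) combinations
#'
#' Walks the combinatorial space of feature-selection x regressor pairs.
#' Each round evaluates one previously unvisited neighbour of the current
#' pair (neighbours differ in exactly one of the two coordinates) by running
#' the full lower-level TPE budget; visited pairs enter a full-memory tabu
#' list and are never re-evaluated. When the current pair has no unvisited
#' neighbours the walk restarts from the best visited pair that still has
#' some. The search stops after `budget$upper_rounds` evaluations or when
#' the whole space has been visited, whichever comes first. The per-pair
#' TPE seed depends only on (`seed`, pair), so results are independent of
#' visit order and reproducible.
#'
#' @param space An `im_search_space`.
#' @param X Normalized numeric feature matrix (training split only).
#' @param y Numeric response (training split only).
#' @param budget An [automl_budget()].
#' @param seed Integer seed.
#' @return An `im_automl_result` with `best_config` (labels, tuned
#'   hyperparameters, objective), `lower_objective`, a complete `history`
#'   tibble (round, fs_method, model, objective, hyperparams), `seed` and
#'   `budget`.
#' @export
tabu_search <- function(space, X, y, budget = automl_budget(), seed = 1L) {
  X <- as.matrix(X)
  pairs <- space_pairs(space)
  total <- nrow(pairs)
  visited <- character(0)
  scores <- list()
  history <- list()
  key <- function(fs, mo) paste(fs, mo, sep = "|")

  eval_pair <- function(fs, mo, round) {
    res <- tpe_optimize(fs, mo, X, y, trials = budget$tpe_trials,
                        cv_folds = budget$cv_folds,
                        seed = config_seed(seed, fs, mo), space = space)
    visited <<- c(visited, key(fs, mo))
    scores[[key(fs, mo)]] <<- res
    history[[length(history) + 1L]] <<- tibble::tibble(
      round = round, fs_method = fs, model = mo,
      objective = res$best_obj, hyperparams = list(res$best_hp)
    )
    res$best_obj
  }
  neighbours <- function(fs, mo) {
    nb <- dplyr::filter(pairs, xor(.data$fs_method == fs, .data$model == mo))
    nb[!(paste(nb$fs_method, nb$model, sep = "|") %in% visited), , drop = FALSE]
  }

  set.seed(seed)
  cur <- pairs[sample(total, 1L), ]
  cur_obj <- eval_pair(cur$fs_method, cur$model, 1L)
  best <- cur
  best_obj <- cur_obj
  round <- 1L
  while (round < budget$upper_rounds && length(visited) < total) {
    nb <- neighbours(cur$fs_method, cur$model)
    if (nrow(nb) == 0L) {
      # restart from the best visited pair that still has unvisited neighbours
      ranked <- dplyr::arrange(dplyr::bind_rows(history), dplyr::desc(.data$objective))
      moved <- FALSE
      for (i in seq_len(nrow(ranked))) {
        nb_i <- neighbours(ranked$fs_method[i], ranked$model[i])
        if (nrow(nb_i) > 0L) {
          cur <- ranked[i, c("fs_method", "model")]
          cur_obj <- ranked$objective[i]
          nb <- nb_i
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
    round <- round + 1L
    set.seed((seed + 7919L * round) %% .Machine$integer.max)
    pick <- nb[sample(nrow(nb), 1L), ]
    obj <- eval_pair(pick$fs_method, pick$model, round)
    if (obj > cur_obj) {
      cur <- pick
      cur_obj <- obj
    }
    if (obj > best_obj) {
      best <- pick
      best_obj <- obj
    }
  }
  history <- dplyr::bind_rows(history)
  if (!is.finite(best_obj)) {
    stop("tabu search exhausted its budget without a single feasible configuration",
         call. = FALSE)
  }
  bk <- key(best$fs_method, best$model)
  structure(
    list(
      best_config = list(
        fs_method = best$fs_method, model = best$model,
        hyperparams = scores[[bk]]$best_hp
      ),
      lower_objective = best_obj,
      upper_objective = best_obj,
      test_r2 = NA_real_,
      history = history,
      seed = as.integer(seed),
      budget = budget
    ),
    class = "im_automl_result"
  )
}

#' Refit the best configuration on the full training split
#'
#' @param result An `im_automl_result` from [tabu_search()].
#' @param X_train,y_train Full (normalized) training split the search saw.
#' @param X_test,y_test Optional held-out split; when given, the test
#'   R-squared is computed once and stored on the returned pipeline and on
#'   `result`-style output.
#' @param seed Integer seed for stochastic refits.
#' @return An `im_pipeline`: fitted selector + regressor with the selected
#'   feature names, ready for [stats::predict()] on a full feature matrix.
#' @export
train_final <- function(result, X_train, y_train, X_test = NULL, y_test = NULL,
                        seed = result$seed) {
  X_train <- as.matrix(X_train)
  cfg <- result$best_config
  idx <- fit_selector(cfg$fs_method, X_train, y_train, cfg$hyperparams,
                      seed = seed)
  fit <- fit_regressor(cfg$model, X_train[, idx, drop = FALSE], y_train,
                       cfg$hyperparams, seed = seed)
  pipe <- structure(
    list(
      fs_method = cfg$fs_method, model = cfg$model,
      hyperparams = cfg$hyperparams,
      feature_names = colnames(X_train),
      selected = colnames(X_train)[idx],
      selected_idx = idx,
      fit = fit,
      cv_r2 = result$lower_objective,
      test_r2 = NA_real_
    ),
    class = "im_pipeline"
  )
  if (!is.null(X_test)) {
    pred <- stats::predict(pipe, X_test)
    pipe$test_r2 <- r2_score(y_test, pred)
  }
  pipe
}

#' @export
predict.im_pipeline <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$feature_names %in% colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  predict_regressor(object$fit, X[, object$selected_idx, drop = FALSE])
}

#' @export
print.im_pipeline <- function(x, ...) {
  cat(sprintf("i-motif scoring pipeline: %s + %s (%d/%d features)\n",
              x$fs_method, x$model, length(x$selected), length(x$feature_names)))
  cat(sprintf("  cross-validated R²: %.4f", x$cv_r2))
  if (is.finite(x$test_r2)) cat(sprintf(", test R²: %.4f", x$test_r2))
  cat("\n")
  invisible(x)
}

#' @export
print.im_automl_result <- function(x, ...) {
  cat(sprintf("bi-level AutoML result: %d configurations evaluated\n",
              nrow(x$history)))
  cat(sprintf("  best: %s + %s, cross-validated R² = %.4f\n",
              x$best_config$fs_method, x$best_config$model, x$lower_objective))
  invisible(x)
}

#' Train an end-to-end i-motif scoring model from labelled sequences
#'
#' Full AutoML entry point: re-validates training sequences against the
#' detection grammar (invalid rows are dropped with a warning), extracts the
#' canonical 33 features, makes a seeded train/test split, fits the
#' normalizer on the training split, runs the bi-level search there, refits
#' the winning configuration, and reports the held-out test R-squared once.
#'
#' @param data Data frame with columns `sequence` and `label` (any
#'   quantitative i-motif property: transition pH, melting point, ...).
#' @param params [detection_params()] used for validation and stored with
#'   the model.
#' @param budget An [automl_budget()].
#' @param seed Integer seed controlling the split, the search and all fits.
#' @param features Optional pinned subset of [imotif_feature_names];
#'   selectors then operate only within it.
#' @param test_prop Held-out fraction (default 0.2).
#' @param normalize `"zscore"` (default) or `"minmax"`.
#' @param label_kind Free-text description of the label stored with the
#'   model (e.g. `"transition pH"`).
#' @param space An `im_search_space`.
#' @return An `im_model`: the fitted pipeline, normalizer, detection params,
#'   label calibration range, and the full `im_automl_result`.
#' @export
automl_train <- function(data, params = detection_params(),
                         budget = automl_budget(), seed = 1L,
                         features = NULL, test_prop = 0.2,
                         normalize = c("zscore", "minmax"),
                         label_kind = "transition pH",
                         space = search_space()) {
  normalize <- match.arg(normalize)
  stopifnot(all(c("sequence", "label") %in% names(data)))
  stopifnot(is.numeric(data$label))
  feats <- featurize_sequences(data$sequence, params)
  bad <- !feats$valid
  if (any(bad)) {
    warning(sum(bad), " of ", nrow(data),
            " training sequences failed i-motif re-validation and were dropped")
  }
  keep <- which(!bad)
  if (length(keep) < 10L) {
    stop("fewer than 10 valid training sequences after re-validation", call. = FALSE)
  }
  X_all <- as.matrix(feats[keep, imotif_feature_names])
  y_all <- data$label[keep]
  if (!is.null(features)) {
    stopifnot(all(features %in% imotif_feature_names))
    X_all <- X_all[, features, drop = FALSE]
  }
  n <- nrow(X_all)
  set.seed(seed)
  test_idx <- sample(n, max(1L, round(test_prop * n)))
  X_tr_raw <- X_all[-test_idx, , drop = FALSE]
  X_te_raw <- X_all[test_idx, , drop = FALSE]
  y_tr <- y_all[-test_idx]
  y_te <- y_all[test_idx]
  norm <- fit_normalizer(X_tr_raw, method = normalize)
  X_tr <- apply_normalizer(norm, X_tr_raw)
  X_te <- apply_normalizer(norm, X_te_raw)
  result <- tabu_search(space, X_tr, y_tr, budget = budget, seed = seed)
  pipe <- train_final(result, X_tr, y_tr, X_te, y_te, seed = seed)
  result$test_r2 <- pipe$test_r2
  structure(
    list(
      pipeline = pipe,
      normalizer = norm,
      detection_params = params,
      feature_names = colnames(X_all),
      label_kind = label_kind,
      label_min = min(y_all),
      label_max = max(y_all),
      result = result,
      seed = as.integer(seed),
      n_train = n - length(test_idx),
      n_test = length(test_idx)
    ),
    class = "im_model"
  )
}

#' @export
print.im_model <- function(x, ...) {
  cat("end-to-end i-motif scoring model\n")
  cat(sprintf("  pipeline: %s + %s\n", x$pipeline$fs_method, x$pipeline$model))
  cat(sprintf("  label: %s in [%.3g, %.3g]\n", x$label_kind, x$label_min, x$label_max))
  cat(sprintf("  cross-validated R² %.4f, test R² %.4f (n = %d + %d)\n",
              x$pipeline$cv_r2, x$pipeline$test_r2, x$n_train, x$n_test))
  invisible(x)
}

# ---- broom-style accessors and plotting -------------------------------------

#' Tidy the search history of an AutoML result
#'
#' @param x An `im_automl_result` (or `im_model`).
#' @param ... Unused.
#' @return The per-round history tibble.
#' @export
tidy.im_automl_result <- function(x, ...) x$history

#' @export
tidy.im_model <- function(x, ...) tidy.im_automl_result(x$result)

#' One-row summary of an AutoML result
#'
#' @param x An `im_automl_result` (or `im_model`).
#' @param ... Unused.
#' @return A one-row tibble: best selector/model, cross-validated and test
#'   R-squared, configurations evaluated.
#' @export
glance.im_automl_result <- function(x, ...) {
  tibble::tibble(
    fs_method = x$best_config$fs_method,
    model = x$best_config$model,
    cv_r2 = x$lower_objective,
    test_r2 = x$test_r2,
    n_configs = nrow(x$history)
  )
}

#' @export
glance.im_model <- function(x, ...) {
  out <- glance.im_automl_result(x$result)
  out$test_r2 <- x$pipeline$test_r2
  out
}

#' Plot the upper-level search trajectory
#'
#' @param object An `im_automl_result`.
#' @param ... Unused.
#' @return A ggplot: per-round objective with the running best overlaid.
#' @export
autoplot.im_automl_result <- function(object, ...) {
  h <- object$history
  h$running_best <- cummax(ifelse(is.finite(h$objective), h$objective, -Inf))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$round)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$objective, colour = .data$model)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$running_best), linetype = 2) +
    ggplot2::labs(x = "tabu round", y = "cross-validated R²",
                  title = "bi-level AutoML search trajectory") +
    ggplot2::theme_minimal()
}
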