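# Small shared fixtures: a linear regression problem in feature space
make_linear_problem <- function(n, p = 10, sd = 0.2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 2 * X[, 1] - 1.5 * X[, 2] + 0.5 * X[, 3] + rnorm(n, 0, sd)
  list(X = X, y = y)
}

test_that("r2_score matches its closed form", {
  y <- c(1, 2, 3)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(mean(y), 3)), 0)
  expect_equal(r2_score(y, c(1, 2, 4)), 0.5) # SS_res = 1, SS_tot = 2
  expect_lt(r2_score(y, c(3, 2, 1)), 0)
  expect_error(r2_score(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("the default search space enumerates 7 x 12 = 84 combinations", {
  sp <- search_space()
  expect_length(sp$fs_portfolio, 7L)
  expect_length(sp$model_portfolio, 12L)
  pairs <- space_pairs(sp)
  expect_equal(nrow(pairs), 84L)
  expect_equal(nrow(dplyr::distinct(pairs)), 84L)
  # every portfolio family has a hyperparameter domain entry
  expect_true(all(c(fs_labels(), model_labels()) %in% names(sp$hyper_domains)))
})

test_that("cross-validated evaluation is deterministic and sane", {
  prob <- make_linear_problem(150)
  sp <- search_space()
  cfg <- list(fs_method = "NONE", model = "RIDGE",
              hyperparams = list(m.alpha = 1e-3))
  v1 <- evaluate_config(cfg, prob$X, prob$y, cv_folds = 5, seed = 7, space = sp)
  v2 <- evaluate_config(cfg, prob$X, prob$y, cv_folds = 5, seed = 7, space = sp)
  expect_identical(v1, v2)
  expect_gte(v1, 0.95) # near-noiseless linear signal, near-unpenalised ridge

  # pure noise: out-of-fold R2 stays near or below zero
  set.seed(3)
  noise_r2 <- replicate(5, {
    Xn <- matrix(rnorm(500 * 10), 500, 10, dimnames = list(NULL, paste0("f", 1:10)))
    yn <- rnorm(500)
    evaluate_config(cfg, Xn, yn, cv_folds = 5, seed = 11, space = sp)
  })
  expect_lt(mean(noise_r2), 0.1)
})

test_that("every model family fits, predicts, and handles constant columns", {
  prob <- make_linear_problem(90, p = 8, sd = 0.3)
  X <- cbind(prob$X, const = rep(1, nrow(prob$X)))
  sp <- search_space()
  for (mo in model_labels()) {
    hp <- default_hyperparams(sp, "NONE", mo)
    fit <- imotifr:::fit_regressor(mo, X, prob$y, hp, seed = 2)
    pred <- imotifr:::predict_regressor(fit, X)
    expect_length(pred, nrow(X))
    expect_true(all(is.finite(pred)), info = mo)
    # better than the mean predictor on its own training data
    expect_gt(imotifr:::fold_r2(prob$y, pred), 0, label = paste(mo, "training R2"))
  }
})

test_that("every selector returns a valid non-empty feature subset", {
  prob <- make_linear_problem(90, p = 12)
  sp <- search_space()
  for (fs in fs_labels()) {
    hp <- default_hyperparams(sp, fs, "RIDGE")
    idx <- imotifr:::fit_selector(fs, prob$X, prob$y, hp, seed = 4)
    expect_true(length(idx) >= 1L && all(idx %in% seq_len(ncol(prob$X))),
                info = fs)
    expect_false(is.unsorted(idx), info = fs)
  }
  # NONE passes everything through
  expect_equal(imotifr:::fit_selector("NONE", prob$X, prob$y, list(), 1),
               seq_len(ncol(prob$X)))
  # informative features dominate a univariate selection
  idx <- imotifr:::fit_selector("GUS", prob$X, prob$y,
                      list(fs.mode = "k_best", fs.k_best = 3L), 1)
  expect_setequal(idx, 1:3)
})

test_that("TPE finds the optimum of a small finite domain and respects budgets", {
  prob <- make_linear_problem(80, p = 5)
  sp <- search_space()
  # 1-D discrete domain smaller than the budget: exhaustive, so optimal
  sp$hyper_domains$DTR <- list(m.max_depth = imotifr:::dom_int(1L, 6L),
                               m.min_samples_split = imotifr:::dom_cat(2L),
                               m.min_samples_leaf = imotifr:::dom_cat(1L))
  r <- tpe_optimize("NONE", "DTR", prob$X, prob$y, trials = 10, cv_folds = 3,
                    seed = 5, space = sp)
  expect_equal(nrow(r$trials), 6L) # finite domain enumerated once
  objs <- vapply(1:6, function(d) {
    evaluate_config(list(fs_method = "NONE", model = "DTR",
                         hyperparams = list(m.max_depth = d,
                                            m.min_samples_split = 2L,
                                            m.min_samples_leaf = 1L)),
                    prob$X, prob$y, cv_folds = 3, seed = 5, space = sp)
  }, numeric(1))
  expect_equal(r$best_obj, max(objs))
  expect_equal(r$best_hp$m.max_depth, which.max(objs))

  # a single-trial budget returns the single sampled point
  r1 <- tpe_optimize("NONE", "RIDGE", prob$X, prob$y, trials = 1, cv_folds = 3,
                     seed = 5, space = search_space())
  expect_equal(nrow(r1$trials), 1L)
  expect_equal(r1$best_obj, r1$trials$objective[1])

  # continuous domain: runs exactly the requested number of trials,
  # deterministically, and beats or matches a fixed default
  r2 <- tpe_optimize("NONE", "RIDGE", prob$X, prob$y, trials = 12, cv_folds = 3,
                     seed = 9, space = search_space())
  expect_equal(nrow(r2$trials), 12L)
  r2b <- tpe_optimize("NONE", "RIDGE", prob$X, prob$y, trials = 12, cv_folds = 3,
                      seed = 9, space = search_space())
  expect_identical(r2$trials$objective, r2b$trials$objective)
  at_default <- evaluate_config(
    list(fs_method = "NONE", model = "RIDGE",
         hyperparams = default_hyperparams(search_space(), "NONE", "RIDGE")),
    prob$X, prob$y, cv_folds = 3, seed = 9, space = search_space()
  )
  expect_gte(r2$best_obj, at_default)
})

test_that("tabu search matches brute force under an exhaustive budget", {
  prob <- make_linear_problem(120, p = 8)
  sub <- search_space(c("NONE", "VT", "GUS"), c("RIDGE", "DTR", "SVR"))
  budget <- automl_budget(upper_rounds = 9, tpe_trials = 5, cv_folds = 3)
  res <- tabu_search(sub, prob$X, prob$y, budget = budget, seed = 21)
  expect_equal(nrow(res$history), 9L) # visited the whole 3x3 space
  expect_equal(nrow(dplyr::distinct(res$history[, c("fs_method", "model")])), 9L)

  pairs <- space_pairs(sub)
  brute <- purrr::pmap_dbl(pairs, function(fs_method, model) {
    tpe_optimize(fs_method, model, prob$X, prob$y, trials = 5, cv_folds = 3,
                 seed = imotifr:::config_seed(21, fs_method, model),
                 space = sub)$best_obj
  })
  expect_equal(res$lower_objective, max(brute))
  best_pair <- pairs[which.max(brute), ]
  expect_equal(res$best_config$fs_method, best_pair$fs_method)
  expect_equal(res$best_config$model, best_pair$model)
  # the reported best is the max over history
  expect_equal(res$lower_objective, max(res$history$objective))
})

test_that("tabu search never revisits a pair and is reproducible", {
  prob <- make_linear_problem(100, p = 6)
  sub <- search_space(c("NONE", "GUS"), c("RIDGE", "DTR"))
  budget <- automl_budget(upper_rounds = 4, tpe_trials = 3, cv_folds = 3)
  r1 <- tabu_search(sub, prob$X, prob$y, budget = budget, seed = 8)
  r2 <- tabu_search(sub, prob$X, prob$y, budget = budget, seed = 8)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_config, r2$best_config)
  keys <- paste(r1$history$fs_method, r1$history$model)
  expect_false(any(duplicated(keys)))

  # 1x1 portfolio: a single evaluation
  one <- search_space("NONE", "RIDGE")
  r3 <- tabu_search(one, prob$X, prob$y,
                    automl_budget(upper_rounds = 5, tpe_trials = 3, cv_folds = 3),
                    seed = 8)
  expect_equal(nrow(r3$history), 1L)
})

test_that("final refit recovers a planted linear signal and records features", {
  prob <- make_linear_problem(260, p = 10, sd = 0.1, seed = 33)
  tr <- 1:200
  sub <- search_space(c("NONE", "GUS"), c("RIDGE", "SVR"))
  budget <- automl_budget(upper_rounds = 4, tpe_trials = 6, cv_folds = 3)
  res <- tabu_search(sub, prob$X[tr, ], prob$y[tr], budget = budget, seed = 13)
  pipe <- train_final(res, prob$X[tr, ], prob$y[tr],
                      prob$X[-tr, ], prob$y[-tr])
  expect_s3_class(pipe, "im_pipeline")
  expect_gte(pipe$test_r2, 0.9)
  expect_true(all(pipe$selected %in% colnames(prob$X)))
  if (pipe$fs_method == "NONE") {
    expect_equal(pipe$selected, colnames(prob$X))
  }
  pred <- predict(pipe, prob$X[-tr, ])
  expect_equal(r2_score(prob$y[-tr], pred), pipe$test_r2)
})

test_that("the search never looks at the held-out split", {
  ds <- labelled_dataset(120, seed = 41)
  budget <- automl_budget(upper_rounds = 2, tpe_trials = 3, cv_folds = 3)
  sub <- search_space(c("NONE"), c("RIDGE", "DTR"))
  m1 <- automl_train(ds, budget = budget, seed = 5, space = sub)
  # shuffle only the labels that end up in the test split: best config and
  # search history must not change
  set.seed(5)
  test_idx <- sample(nrow(ds), max(1L, round(0.2 * nrow(ds))))
  ds2 <- ds
  set.seed(999)
  ds2$label[test_idx] <- sample(ds2$label[test_idx])
  m2 <- automl_train(ds2, budget = budget, seed = 5, space = sub)
  expect_identical(m1$result$history, m2$result$history)
  expect_identical(m1$result$best_config, m2$result$best_config)
})

test_that("automl_train drops invalid sequences and returns a scored model", {
  ds <- labelled_dataset(60, seed = 51)
  bad <- tibble::tibble(sequence = c("ACGTACGT", "CCCCCC"), label = c(6, 6.2))
  budget <- automl_budget(upper_rounds = 2, tpe_trials = 3, cv_folds = 3)
  sub <- search_space("NONE", "RIDGE")
  expect_warning(
    m <- automl_train(dplyr::bind_rows(ds, bad), budget = budget, seed = 3,
                      space = sub),
    "re-validation"
  )
  expect_s3_class(m, "im_model")
  expect_equal(m$n_train + m$n_test, 60L)
  expect_lt(m$label_min, m$label_max)

  g <- glance(m)
  expect_equal(nrow(g), 1L)
  expect_true(is.finite(g$test_r2))
  h <- tidy(m)
  expect_equal(nrow(h), nrow(m$result$history))
  expect_s3_class(autoplot(m$result), "ggplot")
})

test_that("pinned features restrict the pipeline's feature space", {
  ds <- labelled_dataset(60, seed = 61)
  pin <- c("loop_len_mean", "tract_len_mean", "frac_C", "motif_length")
  m <- automl_train(ds, budget = automl_budget(upper_rounds = 2, tpe_trials = 3,
                                               cv_folds = 3),
                    seed = 9, features = pin, space = search_space("GUS", "RIDGE"))
  expect_true(all(m$pipeline$selected %in% pin))
  expect_equal(m$feature_names, pin)
})

test_that("budget presets are ordered and custom budgets validated", {
  expect_equal(automl_budget("swift_basic")$upper_rounds, 8L)
  expect_equal(automl_budget("balanced")$tpe_trials, 25L)
  expect_equal(automl_budget("best_performance")$upper_rounds, 84L)
  b <- automl_budget(upper_rounds = 3, tpe_trials = 2)
  expect_equal(b$preset, "custom")
  expect_error(automl_budget(upper_rounds = 0), "upper_rounds")
})
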