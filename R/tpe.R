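# Tree-structured Parzen Estimator for the lower-level hyperparameter search.
#
# Univariate TPE in the classic formulation: past trials are split into a
# "good" set (top gamma fraction by objective) and a "bad" set; for each
# parameter a Parzen (kernel) density is built over each set and candidates
# are drawn from the good density, keeping the one maximising l(x)/g(x).
# Log-scaled domains are modelled on the log scale, integers are rounded,
# categoricals use smoothed count ratios. When the whole configuration
# space is finite and no larger than the trial budget, it is enumerated
# exhaustively instead (the density model adds nothing there).

tpe_gamma <- 0.25
tpe_n_candidates <- 24L

domain_cardinality <- function(domain) {
  if (length(domain) == 0L) return(1)
  sizes <- vapply(domain, function(d) {
    switch(d$type,
           cat = length(d$choices),
           int = d$hi - d$lo + 1,
           real = Inf)
  }, numeric(1))
  prod(sizes)
}

enumerate_domain <- function(domain) {
  if (length(domain) == 0L) return(list(list()))
  grids <- lapply(domain, function(d) {
    switch(d$type, cat = d$choices, int = seq(d$lo, d$hi))
  })
  grid <- expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

sample_domain <- function(domain) {
  lapply(domain, function(d) {
    switch(
      d$type,
      cat = sample(d$choices, 1L),
      int = {
        if (isTRUE(d$log)) {
          as.integer(round(exp(stats::runif(1, log(d$lo), log(d$hi)))))
        } else {
          as.integer(sample(seq(d$lo, d$hi), 1L))
        }
      },
      real = {
        if (isTRUE(d$log)) {
          exp(stats::runif(1, log(d$lo), log(d$hi)))
        } else {
          stats::runif(1, d$lo, d$hi)
        }
      }
    )
  })
}

parzen_density <- function(x, obs, lo, hi) {
  if (length(obs) == 0L) return(rep(1 / (hi - lo + 1e-12), length(x)))
  bw <- 1.06 * stats::sd(obs) * length(obs)^(-0.2)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 20
  bw <- max(bw, (hi - lo) / 100, 1e-12)
  kde <- vapply(x, function(xi) mean(stats::dnorm(xi, obs, bw)), numeric(1))
  0.75 * kde + 0.25 / (hi - lo + 1e-12)
}

propose_param <- function(d, good, bad) {
  if (d$type == "cat") {
    score <- vapply(d$choices, function(ch) {
      l <- (sum(unlist(good) == ch) + 1) / (length(good) + length(d$choices))
      g <- (sum(unlist(bad) == ch) + 1) / (length(bad) + length(d$choices))
      l / g
    }, numeric(1))
    return(d$choices[which.max(score)])
  }
  tx <- function(v) if (isTRUE(d$log)) log(as.numeric(v)) else as.numeric(v)
  itx <- function(v) if (isTRUE(d$log)) exp(v) else v
  lo <- tx(d$lo); hi <- tx(d$hi)
  g_obs <- tx(unlist(good)); b_obs <- tx(unlist(bad))
  bw <- 1.06 * stats::sd(g_obs) * max(length(g_obs), 1)^(-0.2)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 20
  cand <- if (length(g_obs) > 0L) {
    stats::rnorm(tpe_n_candidates, sample(g_obs, tpe_n_candidates, replace = TRUE), bw)
  } else {
    stats::runif(tpe_n_candidates, lo, hi)
  }
  cand <- pmin(pmax(cand, lo), hi)
  score <- parzen_density(cand, g_obs, lo, hi) / parzen_density(cand, b_obs, lo, hi)
  v <- itx(cand[which.max(score)])
  if (d$type == "int") v <- as.integer(round(pmin(pmax(v, d$lo), d$hi)))
  v
}

tpe_propose <- function(domain, history_hp, history_obj) {
  finite <- is.finite(history_obj)
  if (sum(finite) < 2L) return(sample_domain(domain))
  hp <- history_hp[finite]
  obj <- history_obj[finite]
  n_good <- max(1L, ceiling(tpe_gamma * length(obj)))
  ord <- order(obj, decreasing = TRUE)
  good_idx <- ord[seq_len(n_good)]
  bad_idx <- setdiff(seq_along(obj), good_idx)
  out <- list()
  for (nm in names(domain)) {
    good <- lapply(hp[good_idx], `[[`, nm)
    bad <- lapply(hp[bad_idx], `[[`, nm)
    out[[nm]] <- propose_param(domain[[nm]], good, bad)
  }
  out
}

#' Tune hyperparameters of one (selector, model) pair with TPE
#'
#' Runs the lower-level optimisation: up to `trials` evaluations of
#' [evaluate_config()] (cross-validated R-squared), proposing configurations
#' with a Tree-structured Parzen Estimator after a seeded random start-up
#' phase. A finite configuration space no larger than the budget is
#' enumerated exhaustively.
#'
#' @param fs_method,model Portfolio labels (see [search_space()]).
#' @param X Normalized numeric feature matrix.
#' @param y Numeric response.
#' @param trials Evaluation budget.
#' @param cv_folds Cross-validation folds for the objective.
#' @param seed Integer seed; the whole trajectory is deterministic in it.
#' @param space An `im_search_space` supplying hyperparameter domains.
#' @return A list with `best_hp`, `best_obj` (mean out-of-fold R-squared)
#'   and a `trials` tibble (trial, objective, hyperparams list-column).
#'   `best_obj` is `-Inf` when every trial failed.
#' @export
tpe_optimize <- function(fs_method, model, X, y, trials, cv_folds = 5L,
                         seed = 1L, space = search_space()) {
  domain <- config_domain(space, fs_method, model)
  card <- domain_cardinality(domain)
  hps <- list()
  objs <- numeric(0)
  eval_hp <- function(hp) {
    cfg <- list(fs_method = fs_method, model = model, hyperparams = hp)
    evaluate_config(cfg, X, y, cv_folds = cv_folds, seed = seed, space = space)
  }
  if (is.finite(card) && card <= trials) {
    all_hp <- enumerate_domain(domain)
    for (i in seq_along(all_hp)) {
      hps[[i]] <- all_hp[[i]]
      objs[i] <- eval_hp(all_hp[[i]])
    }
  } else {
    n_startup <- max(3L, min(10L, floor(trials / 3)))
    for (t in seq_len(trials)) {
      set.seed((seed + 131L * t) %% .Machine$integer.max)
      hp <- if (t <= n_startup) {
        sample_domain(domain)
      } else {
        tpe_propose(domain, hps, objs)
      }
      hps[[t]] <- hp
      objs[t] <- eval_hp(hp)
    }
  }
  best <- which.max(objs)
  if (length(best) == 0L || !is.finite(objs[best])) {
    return(list(best_hp = hps[[1]] %||% list(), best_obj = -Inf,
                trials = tpe_trials_tbl(hps, objs)))
  }
  list(best_hp = hps[[best]], best_obj = objs[best],
       trials = tpe_trials_tbl(hps, objs))
}

tpe_trials_tbl <- function(hps, objs) {
  tibble::tibble(trial = seq_along(objs), objective = objs, hyperparams = hps)
}
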