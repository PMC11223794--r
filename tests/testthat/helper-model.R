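# A small trained model shared across bundle/genomestats tests, built once
# per test session.
local_model_cache <- new.env(parent = emptyenv())

small_model <- function() {
  if (is.null(local_model_cache$model)) {
    ds <- labelled_dataset(80, seed = 404)
    local_model_cache$model <- automl_train(
      ds,
      budget = automl_budget(upper_rounds = 2, tpe_trials = 4, cv_folds = 3),
      seed = 404,
      space = search_space(c("NONE", "GUS"), c("RIDGE", "DTR"))
    )
  }
  local_model_cache$model
}
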