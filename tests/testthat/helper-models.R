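# Trained-model fixtures, built once per test run and cached for every file
# that needs them.
#
# scaled_model(): the study conditions at reduced length — all defaults
# (eta 0.05, availability 0.8, 100/200/400 units) but 2e5 babbling
# iterations instead of 1.2e6; used by the learning and reaching checks
# over seeds 1..3 with a majority rule.
#
# small_model(): a 3000-iteration model for mechanics-only checks (shapes,
# determinism of the experiment runners) where learning quality is
# irrelevant.

.model_cache <- new.env(parent = emptyenv())

scaled_model <- function(seed) {
  key <- paste0("scaled_", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- train(train_config(
      n_iterations = 200000, seed = seed, checkpoint_every = 20000))
  }
  .model_cache[[key]]
}

small_model <- function(seed = 99) {
  key <- paste0("small_", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- train(train_config(
      n_iterations = 3000, seed = seed, checkpoint_every = 3000))
  }
  .model_cache[[key]]
}
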