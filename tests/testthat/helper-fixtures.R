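# Shared fixtures, computed lazily once per test run (structure parsing
# and fingerprinting are the expensive steps).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

small_compounds <- function() cached("small_compounds", generate_compounds(60, seed = 101))

small_activities <- function() {
  cached("small_activities", generate_activities(
    small_compounds(), targets = "AChE", seed = 102
  ))
}

# A noise-free activity table for oracle checks.
noisefree_activities <- function() {
  cached("noisefree_activities", generate_activities(
    generate_compounds(150, seed = 201), noise_sd = 0, seed = 202
  ))
}

# One small trained model shared by prediction-level tests.
small_model <- function() {
  cached("small_model", {
    parts <- split_dataset(small_activities(), 0.8, seed = 103)
    evaluate_model(
      train_qsar(parts$train, num_trees = 150L, k_folds = 0L, seed = 103),
      parts$test
    )
  })
}

canon <- function(s) canonicalize_smiles(s)
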