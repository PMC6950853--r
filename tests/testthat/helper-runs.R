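# Heavy end-to-end runs are shared across test files via a session cache:
# the default synthetic protocol (d = 8, 4-sigma separation, 2000 + 2000
# training points, 100 epochs, batch 32) takes about a minute per seed.
.e2e_cache <- new.env(parent = emptyenv())

default_e2e_run <- function(seed, lambda2 = 0.1) {
  key <- sprintf("seed%d_lambda2_%g", seed, lambda2)
  if (is.null(.e2e_cache[[key]])) {
    .e2e_cache[[key]] <- end_to_end_check(
      toy_task_spec(seed = seed),
      weights = loss_weights(0.3, lambda2),
      n_constrained = 0)
  }
  .e2e_cache[[key]]
}
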