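# Shared small fixtures, built once per test run.

lv_preset <- ode_preset("lotka_volterra")

# tiny noisy predator-prey dataset for pipeline-level unit tests
tiny_lv_dataset <- function(level = 0.01, seed = 11, n_train = 12,
                            n_val = 8, n_test = 4) {
  make_dataset(lv_preset$system, lv_preset$x0, lv_preset$train_grid,
               lv_preset$test_grid, noise_spec("additive", level),
               n_train = n_train, n_val = n_val, n_test = n_test,
               seed = seed)
}

# two-species uncoupled exponential decay x' = -x: the true right-hand side
# is species-wise linear, so it can be expressed exactly as a known_part
decay_system <- ode_system(function(x, p) -x, d = 2, name = "decay")

decay_dataset <- function(level = 0.05, seed = 5, n_train = 6, n_val = 50) {
  make_dataset(decay_system, c(2, 3), sim_grid(0, 4, 0.1),
               sim_grid(0, 4, 0.1), noise_spec("additive", level),
               n_train = n_train, n_val = n_val, n_test = 2, seed = seed)
}

# a hybrid model whose network is exactly zero (all weights zero)
zero_nn_hybrid <- function(known, hidden = 4) {
  spec <- nn_spec(known$d, hidden = hidden, init_seed = 1)
  hybrid_model(known, spec, theta = rep(0, spec$n_params))
}

# one small trained LV fit reused across stage-2 unit tests (built lazily)
.trained_lv <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- tiny_lv_dataset()
      known <- known_part(c(1.3, -1.8))
      spec <- nn_spec(2, hidden = 8, init_seed = 7)
      cache <<- list(
        dataset = ds,
        fit = train_hybrid(ds, known, spec, w = 5, b = 5,
                           cfg = train_config(lr = 0.01, epochs = 3,
                                              seed = 7)))
    }
    cache
  }
})
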