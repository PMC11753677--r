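test_that("network spec counts parameters and initializes reproducibly", {
  spec <- nn_spec(2, hidden = 8, init_seed = 4)
  expect_equal(spec$n_params, 2 * 8 + 8 + 8 * 2 + 2)
  spec2 <- nn_spec(3, hidden = c(8, 8), init_seed = 4)
  expect_equal(spec2$n_params, 3 * 8 + 8 + 8 * 8 + 8 + 8 * 3 + 3)
  expect_identical(hybriddx:::nn_init(spec), hybriddx:::nn_init(spec))
  # fan-in bound on initial weights
  th <- hybriddx:::nn_init(spec)
  expect_true(all(abs(th) <= 1 / sqrt(2) + 1e-12))
})

test_that("a zero network with the true linear prior fits noise-free
          windows exactly", {
  ds <- decay_dataset(level = 0)
  fit <- zero_nn_hybrid(known_part(c(-1, -1)))
  win <- sliding_windows(ds$train[[1]], 5)[[3]]
  expect_lt(window_loss(fit, win, substeps = 8), 1e-8)
  expect_lt(validation_loss(fit, ds$validation, substeps = 8), 1e-8)
})

test_that("zero prior and zero network predict constants", {
  ds <- tiny_lv_dataset(level = 0, n_train = 1, n_val = 1, n_test = 1)
  fit <- zero_nn_hybrid(known_zero(2))
  win <- sliding_windows(ds$train[[1]], 10)[[1]]
  expected <- mean(sweep(win$states, 2, win$states[1, ])^2)
  expect_equal(window_loss(fit, win), expected, tolerance = 1e-12)
})

test_that("batch loss is the mean of window losses", {
  ds <- tiny_lv_dataset(n_train = 2, n_val = 2, n_test = 2)
  known <- known_part(c(1.3, -1.8))
  spec <- nn_spec(2, hidden = 4, init_seed = 3)
  fit <- hybrid_model(known, spec)
  wins <- hybriddx:::pool_windows(ds$train, 5)[1:6]
  per_window <- vapply(wins, function(wd) window_loss(fit, wd, substeps = 4),
                       numeric(1))
  Y <- array(0, dim = c(5, 2, 6))
  for (i in 1:6) Y[, , i] <- wins[[i]]$states
  batch <- hybriddx:::cpp_batch_grad(fit$theta, spec$layers, known$coef,
                                     wins[[1]]$times, Y, 4)
  expect_equal(batch$loss, mean(per_window), tolerance = 1e-10)
})

test_that("solver gradients match central finite differences", {
  spec <- nn_spec(2, hidden = c(5, 4), init_seed = 9)
  theta <- hybriddx:::nn_init(spec)
  a <- c(0.5, -0.5)
  times <- seq(0, 0.4, by = 0.1)
  set.seed(8)
  Y <- array(rnorm(5 * 2 * 2, mean = 1.5, sd = 0.4), dim = c(5, 2, 2))
  g <- hybriddx:::cpp_batch_grad(theta, spec$layers, a, times, Y, 3)$grad
  idx <- c(1, 7, 20, length(theta))  # spot-check a few weights
  for (i in idx) {
    e <- 1e-6
    tp <- theta; tp[i] <- tp[i] + e
    tm <- theta; tm[i] <- tm[i] - e
    num <- (hybriddx:::cpp_batch_grad(tp, spec$layers, a, times, Y, 3)$loss -
            hybriddx:::cpp_batch_grad(tm, spec$layers, a, times, Y, 3)$loss) /
      (2 * e)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("validation loss is invariant to duplicating samples and zero for
          a perfect model", {
  ds <- decay_dataset(level = 0, n_val = 3)
  fit <- zero_nn_hybrid(known_part(c(-1, -1)))
  v1 <- validation_loss(fit, ds$validation, substeps = 8)
  v2 <- validation_loss(fit, c(ds$validation, ds$validation), substeps = 8)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_lt(v1, 1e-8)
})

test_that("with the true prior and a zero network, validation loss sits at
          the analytic noise floor", {
  eps <- 0.05
  ds <- decay_dataset(level = eps, n_val = 50)
  fit <- zero_nn_hybrid(known_part(c(-1, -1)))
  vl <- validation_loss(fit, ds$validation, substeps = 8)
  # residual at time j: delta0*exp(-t_j) - noise_j, independent noise
  # (exactly zero at j = 1 where the simulation starts at the observation)
  t <- ds$validation[[1]]$times
  sigma2 <- (eps * colMeans(ds$truth_train$states))^2
  per_species <- vapply(sigma2, function(s2)
    sum(s2 * (1 + exp(-2 * t[-1]))) / length(t), numeric(1))
  expect_equal(vl, mean(per_species), tolerance = 0.2)
})

test_that("training is reproducible and improves the fit", {
  ds <- tiny_lv_dataset()
  known <- known_part(c(1.3, -1.8))
  spec <- nn_spec(2, hidden = 8, init_seed = 7)
  cfg <- train_config(lr = 0.01, epochs = 3, seed = 7)
  f1 <- train_hybrid(ds, known, spec, w = 5, b = 5, cfg = cfg)
  f2 <- train_hybrid(ds, known, spec, w = 5, b = 5, cfg = cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$history, f2$history)
  # trained model beats the untrained initialization on validation data
  f0 <- hybrid_model(known, spec)
  expect_lt(f1$val_loss, validation_loss(f0, ds$validation))
  # history bookkeeping
  expect_equal(nrow(f1$history), 3)
  expect_equal(f1$val_loss, min(f1$history$val_loss))
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
})

test_that("training with the true model and no noise does not degrade an
          already-perfect fit", {
  ds <- decay_dataset(level = 0, n_train = 3, n_val = 2)
  known <- known_part(c(-1, -1))
  spec <- nn_spec(2, hidden = 4, init_seed = 2)
  fit <- hybrid_model(known, spec, theta = rep(0, spec$n_params))
  expect_lt(validation_loss(fit, ds$validation, substeps = 8), 1e-8)
  # Adam rescales even near-zero gradients to lr-sized steps, so the
  # weights drift slightly off the exact optimum; the fit must stay far
  # below the data scale (state magnitudes ~2-3)
  trained <- train_hybrid(ds, known, spec, w = 5, b = 5,
                          cfg = train_config(lr = 0.001, epochs = 2,
                                             seed = 1))
  expect_lt(trained$val_loss, 5e-3)
})

test_that("grid search returns the lowest-validation-loss combination", {
  ds <- tiny_lv_dataset()
  known <- known_part(c(1.3, -1.8))
  spec <- nn_spec(2, hidden = 8, init_seed = 7)
  gs <- grid_search_nn(ds, known, spec, w_values = 5, b_values = 5,
                       lr_values = c(0.001, 0.01),
                       cfg = train_config(epochs = 2, seed = 7))
  expect_equal(nrow(gs$table), 2)
  expect_equal(gs$fit$val_loss, min(gs$table$val_loss))
  # a single-combination grid is equivalent to train_hybrid
  g1 <- grid_search_nn(ds, known, spec, w_values = 5, b_values = 5,
                       lr_values = 0.01,
                       cfg = train_config(epochs = 2, seed = 7))
  direct <- train_hybrid(ds, known, spec, 5, 5,
                         train_config(lr = 0.01, epochs = 2, seed = 7))
  expect_identical(g1$fit$theta, direct$theta)
})

test_that("fitted models round-trip through the JSON archive", {
  tl <- .trained_lv()
  path <- withr::local_tempfile(fileext = ".json")
  write_hybrid_fit(tl$fit, path)
  back <- read_hybrid_fit(path)
  expect_equal(back$theta, tl$fit$theta, tolerance = 1e-15)
  expect_equal(back$known$coef, tl$fit$known$coef)
  expect_equal(back$spec$layers, tl$fit$spec$layers)
  v1 <- validation_loss(tl$fit, tl$dataset$validation)
  v2 <- validation_loss(back, tl$dataset$validation)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("regression data re-simulates at the requested resolution", {
  tl <- .trained_lv()
  rd1 <- simulate_regression_data(tl$fit, tl$dataset, dt = 0.1, n_ic = 4)
  rd2 <- simulate_regression_data(tl$fit, tl$dataset, dt = 0.05, n_ic = 4)
  expect_equal(nrow(rd1$X), 4 * 41)
  expect_equal(nrow(rd2$X), 4 * 81)
  expect_equal(dim(rd1$targets), dim(rd1$X))
  # targets are exactly NN evaluated on the simulated states
  expect_equal(rd1$targets, nn_eval(tl$fit, rd1$X))
})
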