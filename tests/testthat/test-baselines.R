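test_that("finite differences are exact for polynomials up to degree 2", {
  t <- seq(0, 2, by = 0.1)
  lin <- trajectory(t, cbind(3 + 2 * t, 1 - 0.5 * t))
  d <- finite_difference(lin)
  expect_equal(d$values, cbind(rep(2, 21), rep(-0.5, 21)),
               tolerance = 1e-12, ignore_attr = TRUE)
  quad <- trajectory(t, cbind(t^2, 4 + t - t^2))
  dq <- finite_difference(quad)
  expect_equal(dq$values[, 1], 2 * t, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(dq$values[, 2], 1 - 2 * t, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("finite differences converge at second order", {
  err_at <- function(dt) {
    tr <- simulate_ode(lv_preset$system, lv_preset$x0, sim_grid(0, 4, dt))
    truth <- t(apply(tr$states, 1, lv_preset$system$rhs,
                     p = lv_preset$system$params))
    max(abs(finite_difference(tr)$values - truth))
  }
  e1 <- err_at(0.1)
  e2 <- err_at(0.05)
  expect_gt(e1 / e2, 3)  # halving the step should divide the error by ~4
  expect_lt(e1 / e2, 5)
})

test_that("finite differences validate their inputs", {
  expect_error(finite_difference(trajectory(c(0, 1), cbind(c(1, 2)))),
               "at least 3")
  expect_error(finite_difference(
    trajectory(c(0, 0.1, 0.3), cbind(1:3))), "uniform")
})

test_that("base SINDy on noise-free data recovers the predator-prey model", {
  ds <- tiny_lv_dataset(level = 0, n_train = 1, n_val = 8, n_test = 1)
  grid <- selection_grid(NULL, "poly_max_2", c(0, 0.05), lambda = 0.1)
  rep <- base_sindy(ds, grid)
  expect_true(rep$topology_correct[1])
  bm <- best_model(rep, 1)
  expect_equal(coef(bm)["x1", 1], 1.3, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(coef(bm)["x1*x2", 1], -0.9, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(coef(bm)["x1*x2", 2], 0.8, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(coef(bm)["x2", 2], -1.8, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("base-known with a zero prior reproduces base SINDy exactly", {
  ds <- tiny_lv_dataset(level = 0.01, n_train = 3, n_val = 4, n_test = 1)
  grid <- selection_grid(NULL, c("poly_max_2", "poly_2_3"), c(0.05, 0.5),
                         lambda = 0.1)
  r1 <- base_sindy(ds, grid)
  r2 <- base_known(ds, known_zero(2), grid)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  for (i in seq_len(nrow(r1)))
    expect_equal(coef(best_model(r1, i)), coef(best_model(r2, i)),
                 tolerance = 1e-12)
})

test_that("base-known with the full true prior learns nothing extra", {
  # decay system: the prior already explains the dynamics, so every
  # learned coefficient should fall below the threshold
  ds <- decay_dataset(level = 0, n_train = 2, n_val = 8)
  grid <- selection_grid(NULL, "poly_max_2", 0, lambda = 0.1)
  rep <- suppressWarnings(base_known(ds, known_part(c(-1, -1)), grid,
                                     truth = NULL))
  expect_equal(n_learned(best_model(rep, 1)), 0L)
})

test_that("weak-form features match closed-form integrals on a linear
          system", {
  # x' = A x with known solution; weak features computed on a fine grid
  # should satisfy the weak-form identity for each test function
  A <- matrix(c(-0.5, 0.3, 0.2, -0.8), 2, 2, byrow = TRUE)
  sys <- ode_system(function(x, p) as.numeric(A %*% x), d = 2)
  ds <- make_dataset(sys, c(2, 1), sim_grid(0, 4, 0.02),
                     sim_grid(0, 4, 0.02), noise_spec("additive", 0),
                     n_train = 1, n_val = 10, n_test = 1, seed = 1)
  grid <- selection_grid(NULL, "poly_max_2", 0, lambda = 0.05)
  rep <- weak_sindy(ds, grid, truth = NULL, K = 40, seed = 3)
  co <- coef(best_model(rep, 1))
  expect_equal(co["x1", 1], A[1, 1], tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(co["x2", 1], A[1, 2], tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(co["x1", 2], A[2, 1], tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(co["x2", 2], A[2, 2], tolerance = 0.02, ignore_attr = TRUE)
})

test_that("weak features vanish on constant trajectories", {
  t <- seq(0, 4, by = 0.1)
  const <- trajectory(t, cbind(rep(2, 41), rep(3, 41)))
  ds <- list(train = list(const, const),
             validation = list(const), system = NULL)
  class(ds) <- "trajectory_dataset"
  grid <- selection_grid(NULL, "poly_1_2", 0, lambda = 0.05)
  rep <- suppressWarnings(weak_sindy(ds, grid, truth = NULL, K = 20,
                                     seed = 2))
  expect_equal(n_learned(best_model(rep, 1)), 0L)
})

test_that("the pure-NN method is the hybrid pipeline with a zero prior", {
  ds <- tiny_lv_dataset()
  spec <- nn_spec(2, hidden = 8, init_seed = 5)
  cfg <- train_config(lr = 0.01, epochs = 2, seed = 5)
  grid <- selection_grid(0.1, "poly_max_2", 0.05, lambda = 0.1)
  pn <- pure_nn(ds, spec, w = 5, b = 5, cfg = cfg, grid = grid, n_ic = 4)
  direct_fit <- train_hybrid(ds, known_zero(2), spec, 5, 5, cfg)
  expect_identical(pn$fit$theta, direct_fit$theta)
  direct_rep <- select_models(direct_fit, ds, grid, n_ic = 4)
  expect_equal(as.data.frame(pn$report), as.data.frame(direct_rep),
               tolerance = 1e-12)
})
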