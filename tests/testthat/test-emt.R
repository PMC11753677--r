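test_that("proportion profiles validate their closure invariant", {
  m <- cbind(c(0.8, 0.5), c(0.15, 0.3), c(0.05, 0.2))
  p <- proportion_profile(m, matrix(0.05, 2, 3))
  expect_equal(p$n_bins, 2L)
  expect_error(proportion_profile(m * 1.1, matrix(0.05, 2, 3)), "sum to 1")
  expect_error(proportion_profile(cbind(1.2, -0.1, -0.1),
                                  matrix(0, 1, 3)), ">= 0")
})

test_that("zero-sd sampling reproduces the medians exactly", {
  prof <- synthetic_emt_profile(9, sd = 0)
  tr <- sample_proportion_trajectory(prof, seed = 1)
  expect_equal(tr$states, prof$medians, ignore_attr = TRUE)
})

test_that("sampled rows sum to one exactly with entries in [0, 1]", {
  prof <- synthetic_emt_profile(12, sd = 0.05)
  for (seed in 1:25) {
    tr <- sample_proportion_trajectory(prof, seed = seed)
    expect_equal(unname(rowSums(tr$states)), rep(1, 12), tolerance = 1e-12)
    expect_true(all(tr$states >= 0 & tr$states <= 1))
  }
})

test_that("drawn states follow the stated truncated Gaussian", {
  # bin with comfortable margins so closure redraws are rare; the sd of a
  # normal truncated to within one sd of its mean has the closed form
  # sigma * sqrt(1 - 2 phi(1) / (Phi(1) - Phi(-1)))
  sigma <- 0.04
  prof <- proportion_profile(matrix(c(0.5, 0.3, 0.2), 1, 3),
                             matrix(sigma, 1, 3))
  draws <- vapply(1:8000, function(s)
    sample_proportion_trajectory(prof, seed = s)$states[1, 1], numeric(1))
  sd_oracle <- sigma * sqrt(1 - 2 * dnorm(1) / (2 * pnorm(1) - 1))
  expect_equal(sd(draws), sd_oracle, tolerance = 0.05)
  expect_equal(mean(draws), 0.5, tolerance = 0.01)
  # all draws inside the one-sd truncation window
  expect_true(all(abs(draws - 0.5) <= sigma + 1e-12))
})

test_that("the draw order determines which state is closed", {
  prof <- synthetic_emt_profile(6, sd = 0.03)
  tr <- sample_proportion_trajectory(prof, seed = 3, draw_order = c(2, 3))
  # states 2 and 3 land within their truncation windows; 1 is closed
  expect_true(all(abs(tr$states[, 2] - prof$medians[, 2]) <= 0.03 + 1e-12))
  expect_true(all(abs(tr$states[, 3] - prof$medians[, 3]) <= 0.03 + 1e-12))
  expect_equal(unname(rowSums(tr$states)), rep(1, 6), tolerance = 1e-12)
})

test_that("the synthetic transition profile has the canonical shape", {
  prof <- synthetic_emt_profile(9)
  m <- prof$medians
  expect_equal(unname(rowSums(m)), rep(1, 9), tolerance = 1e-9)
  expect_true(all(diff(m[, "E"]) <= 1e-9))   # E falls
  expect_true(all(diff(m[, "M"]) >= -1e-9))  # M rises
  expect_gt(m[9, "M"], 0.9)
  # intermediate rises then falls
  i_peak <- which.max(m[, "I"])
  expect_true(i_peak > 1 && i_peak < 9)
})

test_that("extreme sharpness approaches a step-function profile", {
  prof <- synthetic_emt_profile(9, sharpness = c(60, 60))
  m <- prof$medians
  expect_gt(m[1, "E"], 0.99)
  expect_lt(m[9, "E"], 0.01)
  expect_gt(m[9, "M"], 0.99)
})

test_that("compositional datasets have the configured shape and are
          reproducible", {
  prof <- synthetic_emt_profile(9)
  prof13 <- synthetic_emt_profile(13)
  ds <- make_emt_dataset(prof, test_profile = prof13, n_train = 8,
                         n_val = 4, n_test = 3, seed = 5)
  expect_length(ds$train, 8)
  expect_equal(dim(ds$train[[1]]$states), c(9L, 3L))
  expect_equal(dim(ds$test[[1]]$states), c(13L, 3L))
  ds2 <- make_emt_dataset(prof, test_profile = prof13, n_train = 8,
                          n_val = 4, n_test = 3, seed = 5)
  expect_identical(ds$train, ds2$train)
  for (tr in ds$train)
    expect_equal(unname(rowSums(tr$states)), rep(1, 9), tolerance = 1e-12)
})

test_that("the default cell-state selection grid offers the mixed
          Hill/polynomial bases", {
  g <- default_selection_grid("emt")
  expect_true(all(c("hill_3_poly_1", "hill_max_3_poly_1", "poly_max_2")
                  %in% g$library_names))
})

test_that("discovery on a known transition chain recovers the dynamics,
          including cancellation of an unsupported loss term", {
  # ground truth: E -> I -> M linear chain with no loss from M; the prior
  # assumes unit loss from every state, so the learned part must cancel
  # the -x3 term. Coefficients on compositional data are non-unique
  # (x1 + x2 + x3 is nearly constant), so the checks are on the model
  # field, which is identified.
  k1 <- 0.5; k2 <- 0.5
  chain <- ode_system(function(x, p)
    c(-k1 * x[1], k1 * x[1] - k2 * x[2], k2 * x[2]),
    d = 3, name = "chain")
  gen <- function(n, block, seed = 3) lapply(seq_len(n), function(i) {
    s <- seed + block * 1000 + i
    x0 <- hybriddx:::withr_seed(s, c(0.9, 0.06, 0.04) +
                                  runif(3, -0.03, 0.08))
    apply_noise(simulate_ode(chain, x0, sim_grid(1, 9, 1)),
                noise_spec("additive", 0.002), seed = s + 7)
  })
  ds <- structure(list(train = gen(60, 1), validation = gen(20, 2),
                       test = gen(2, 3), system = chain, seed = 3),
                  class = "trajectory_dataset")
  grid <- selection_grid(c(0.5, 1), c("poly_max_2", "poly_1_2"),
                         c(0.05, 0.1, 0.5, 1), lambda = 0.1)
  res <- discover_emt_model(ds, w = 5, b = 10, grid = grid,
                            cfg = train_config(lr = 0.01, epochs = 10,
                                               seed = 3))
  bm <- best_model(res$report, 1)
  expect_lt(res$report$rss[1], 1)
  # field accuracy along the transition manifold
  rhs <- model_rhs(bm)
  states <- simulate_ode(chain, c(0.92, 0.05, 0.03),
                         sim_grid(1, 9, 0.5))$states
  errs <- t(apply(states, 1, function(x) rhs(x) - chain$rhs(x, NULL)))
  expect_lt(max(abs(errs)), 0.3)
  # near the terminal all-M state the prior loss -x3 alone would give
  # x3' ~ -0.93; the discovered model must have cancelled it
  expect_lt(abs(rhs(c(0.05, 0.02, 0.93))[3]), 0.1)
})
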