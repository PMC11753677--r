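#' Neural-network residual specification
#'
#' A small fully-connected multilayer perceptron NN(x) with tanh hidden
#' activations and a linear output layer, mapping the d-dimensional state to
#' d residual derivatives. The smooth bounded-derivative nonlinearity
#' matters because the network is integrated by a Runge-Kutta solver.
#' Weights are initialized uniformly on `(-1/sqrt(fan_in), 1/sqrt(fan_in))`.
#'
#' @param d state dimension (input and output width).
#' @param hidden integer vector of hidden-layer widths (default one layer
#'   of 8 neurons; the three-species benchmarks use `c(8, 8)`).
#' @param init_seed seed for weight initialization.
#' @return object of class `nn_spec` with fields `layers` (full width
#'   vector), `init_seed`, `n_params`.
#' @export
nn_spec <- function(d, hidden = 8, init_seed = 1) {
  stopifnot(d >= 1, all(hidden >= 1))
  layers <- as.integer(c(d, hidden, d))
  np <- sum(layers[-length(layers)] * layers[-1] + layers[-1])
  structure(list(layers = layers, init_seed = as.integer(init_seed),
                 n_params = np),
            class = "nn_spec")
}

# fan-in-scaled uniform init, packed layer-by-layer (W column-major, then b)
nn_init <- function(spec) {
  layers <- spec$layers
  withr_seed(spec$init_seed, {
    unlist(lapply(seq_len(length(layers) - 1), function(l) {
      fan_in <- layers[l]; fan_out <- layers[l + 1]
      bound <- 1 / sqrt(fan_in)
      stats::runif(fan_in * fan_out + fan_out, -bound, bound)
    }))
  })
}

#' Training configuration for the hybrid model
#'
#' @param lr Adam learning rate.
#' @param epochs number of passes over the batched training windows.
#' @param substeps RK4 substeps per data interval during training and
#'   validation simulation.
#' @param seed base seed for batch shuffling (epoch-indexed: batches are
#'   reshuffled every epoch).
#' @param reshuffle reshuffle batches each epoch (default TRUE).
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, epochs = 10, substeps = 4, seed = 1,
                         reshuffle = TRUE) {
  stopifnot(lr > 0, epochs >= 1, substeps >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 substeps = as.integer(substeps), seed = as.integer(seed),
                 reshuffle = isTRUE(reshuffle)),
            class = "train_config")
}

#' Construct a (possibly untrained) hybrid model
#'
#' @param known a [known_part()] giving g(x).
#' @param spec an [nn_spec()]; its dimension must match `known`.
#' @param theta packed weight vector (default: fresh initialization from
#'   `spec$init_seed`; use `0 * nn_init(spec)` for an exactly-zero network).
#' @return object of class `hybrid_fit`.
#' @export
hybrid_model <- function(known, spec, theta = NULL) {
  stopifnot(inherits(known, "known_part"), inherits(spec, "nn_spec"))
  stopifnot(spec$layers[1] == known$d)
  if (is.null(theta)) theta <- nn_init(spec)
  stopifnot(length(theta) == spec$n_params)
  structure(list(known = known, spec = spec, theta = as.numeric(theta),
                 config = NULL, history = NULL, best_epoch = NA_integer_,
                 val_loss = NA_real_),
            class = "hybrid_fit")
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat("<hybrid_fit> d =", x$known$d,
      " layers:", paste(x$spec$layers, collapse = "-"),
      " (", x$spec$n_params, "weights )\n")
  if (!is.null(x$history)) {
    cat("  trained", nrow(x$history), "epochs; best epoch", x$best_epoch,
        "validation loss", signif(x$val_loss, 4), "\n")
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.hybrid_fit <- function(object, ...) object$theta

#' Predict trajectories from a fitted hybrid model
#'
#' @param object a `hybrid_fit`.
#' @param x0 initial state.
#' @param times time points to predict at.
#' @param substeps RK4 substeps per interval.
#' @param ... unused.
#' @return a [trajectory()] or `NULL` on solver blow-up.
#' @export
predict.hybrid_fit <- function(object, x0, times, substeps = 4, ...) {
  simulate_hybrid(object, x0, times, substeps)
}

#' Evaluate the network residual on states
#' @param fit a `hybrid_fit`.
#' @param X state matrix (`n x d`) or vector.
#' @return `n x d` matrix of NN(x) values.
#' @export
nn_eval <- function(fit, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  cpp_nn_eval(fit$theta, fit$spec$layers, X)
}

#' Simulate the hybrid model on given time points
#'
#' Fixed-step RK4 with `substeps` steps per interval; returns `NULL` on
#' numerical blow-up.
#'
#' @param fit a `hybrid_fit`.
#' @param x0 initial state.
#' @param times time points (first entry is the initial time).
#' @param substeps RK4 substeps per interval.
#' @return a [trajectory()] or `NULL`.
#' @export
simulate_hybrid <- function(fit, x0, times, substeps = 4) {
  res <- cpp_sim_hybrid(fit$theta, fit$spec$layers, fit$known$coef,
                        x0, times, substeps)
  if (!res$ok) return(NULL)
  trajectory(times, res$states)
}

#' Loss of the hybrid model on one window segment
#'
#' Simulates from the window's first observed (noisy) state over the
#' window's time points and returns the MSE between simulated and observed
#' states over all points and species. Blow-up yields `Inf`.
#'
#' @param fit a `hybrid_fit`.
#' @param segment a window segment from [sliding_windows()].
#' @param substeps RK4 substeps per interval.
#' @return scalar loss.
#' @export
window_loss <- function(fit, segment, substeps = 4) {
  sim <- simulate_hybrid(fit, segment$states[1, ], segment$times, substeps)
  if (is.null(sim)) return(Inf)
  mean((sim$states - segment$states)^2)
}

#' Validation loss of a hybrid model
#'
#' For each validation sample, simulate from that sample's first
#' observation over the sample's full time grid and compute the per-sample
#' MSE; returns the mean over samples. Any failed simulation yields `Inf`
#' (penalizing unstable fits).
#'
#' @param fit a `hybrid_fit`.
#' @param validation list of [trajectory()]s on a shared grid.
#' @param substeps RK4 substeps per interval.
#' @return mean validation MSE.
#' @export
validation_loss <- function(fit, validation, substeps = 4) {
  stopifnot(length(validation) >= 1)
  Y <- traj_cube(validation)
  cpp_val_loss(fit$theta, fit$spec$layers, fit$known$coef,
               validation[[1]]$times, Y, substeps)
}

# stack a list of same-grid trajectories into a (T x d x n) array
traj_cube <- function(trajs) {
  Td <- dim(trajs[[1]]$states)
  arr <- array(0, dim = c(Td[1], Td[2], length(trajs)))
  for (i in seq_along(trajs)) arr[, , i] <- trajs[[i]]$states
  arr
}

#' Save / load a fitted hybrid model
#'
#' Serializes the weights together with the full configuration (network
#' shape, known part, training settings, history) as a single JSON
#' archive, so a fit can be reloaded and re-simulated elsewhere.
#'
#' @param fit a `hybrid_fit`.
#' @param path file path for the JSON archive.
#' @return `write_hybrid_fit` returns `path` invisibly; `read_hybrid_fit`
#'   returns the reconstructed `hybrid_fit`.
#' @export
write_hybrid_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hybrid_fit"))
  payload <- list(
    theta = fit$theta,
    layers = fit$spec$layers,
    init_seed = fit$spec$init_seed,
    known_coef = fit$known$coef,
    config = fit$config,
    history = fit$history,
    best_epoch = fit$best_epoch,
    val_loss = fit$val_loss)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hybrid_fit
#' @export
read_hybrid_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- as.integer(p$layers)
  spec <- nn_spec(layers[1], hidden = layers[-c(1, length(layers))],
                  init_seed = p$init_seed)
  fit <- hybrid_model(known_part(p$known_coef), spec, theta = p$theta)
  fit$config <- p$config
  fit$history <- p$history
  fit$best_epoch <- p$best_epoch
  fit$val_loss <- p$val_loss
  fit
}

#' Train the hybrid dynamical model
#'
#' Runs `epochs` passes of Adam over shuffled batches of sliding-window
#' segments. Each gradient step simulates every window in the batch from
#' its first observed state and backpropagates the batch-mean window MSE
#' through the RK4 solve (exact gradients of the discrete solution via
#' forward sensitivities). After every epoch the model is scored on the
#' validation split; the returned weights are those of the best
#' (lowest-validation-loss) epoch. Windows whose simulation blows up are
#' skipped within their batch.
#'
#' @param dataset a [make_dataset()] result (train split non-empty).
#' @param known a [known_part()].
#' @param spec an [nn_spec()].
#' @param w sliding-window size.
#' @param b batch size.
#' @param cfg a [train_config()].
#' @return a trained `hybrid_fit` with a `history` data frame (per-epoch
#'   mean training batch loss and validation loss).
#' @export
train_hybrid <- function(dataset, known, spec, w, b, cfg = train_config()) {
  stopifnot(length(dataset$train) >= 1)
  fit <- hybrid_model(known, spec)
  windows <- pool_windows(dataset$train, w)
  val <- dataset$validation
  valY <- traj_cube(val)
  val_times <- val[[1]]$times
  layers <- spec$layers
  a <- known$coef
  theta <- fit$theta
  # Adam state
  m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_theta <- theta; best_val <- Inf; best_epoch <- NA_integer_
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    shuffle_seed <- if (cfg$reshuffle) cfg$seed + 7919L * epoch else cfg$seed
    bs <- make_batches(windows, b, seed = shuffle_seed)
    epoch_losses <- numeric(0)
    for (batch in bs$batches) {
      Y <- array(0, dim = c(w, known$d, length(batch)))
      for (i in seq_along(batch)) Y[, , i] <- batch[[i]]$states
      res <- cpp_batch_grad(theta, layers, a, batch[[1]]$times, Y,
                            cfg$substeps)
      if (!is.finite(res$loss)) next  # whole batch failed: skip
      t_step <- t_step + 1L
      g <- as.numeric(res$grad)
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      mh <- m1 / (1 - b1^t_step)
      vh <- m2 / (1 - b2^t_step)
      theta <- theta - cfg$lr * mh / (sqrt(vh) + eps)
      epoch_losses <- c(epoch_losses, res$loss)
    }
    vl <- cpp_val_loss(theta, layers, a, val_times, valY, cfg$substeps)
    hist <- rbind(hist, data.frame(
      epoch = epoch,
      train_loss = if (length(epoch_losses)) mean(epoch_losses) else Inf,
      val_loss = vl))
    if (is.finite(vl) && vl < best_val) {
      best_val <- vl; best_theta <- theta; best_epoch <- epoch
    }
  }
  fit$theta <- as.numeric(best_theta)
  fit$config <- c(cfg, list(w = w, b = b))
  fit$history <- hist
  fit$best_epoch <- best_epoch
  fit$val_loss <- best_val
  fit
}

#' Stage-1 hyperparameter grid search
#'
#' Trains one hybrid model per (window size, batch size, learning rate)
#' combination and returns the fit with the lowest mean validation loss
#' together with the full search table. Combinations whose training fails
#' (non-finite validation loss throughout) are recorded, not raised.
#'
#' @param dataset a [make_dataset()] result.
#' @param known a [known_part()].
#' @param spec an [nn_spec()].
#' @param w_values,b_values,lr_values hyperparameter candidate values
#'   (defaults are the benchmark grid: w in 5/10, b in 5/10/20,
#'   lr in 0.001/0.01/0.1).
#' @param cfg base [train_config()]; `lr` is overridden per combination.
#' @return list with elements `fit` (best `hybrid_fit`) and `table`
#'   (data frame: w, b, lr, val_loss, best_epoch).
#' @export
grid_search_nn <- function(dataset, known, spec,
                           w_values = c(5, 10),
                           b_values = c(5, 10, 20),
                           lr_values = c(0.001, 0.01, 0.1),
                           cfg = train_config()) {
  stopifnot(length(w_values) >= 1, length(b_values) >= 1,
            length(lr_values) >= 1)
  combos <- expand.grid(w = w_values, b = b_values, lr = lr_values)
  fits <- vector("list", nrow(combos))
  tab <- combos
  tab$val_loss <- NA_real_
  tab$best_epoch <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    cfg_i <- cfg
    cfg_i$lr <- combos$lr[i]
    f <- tryCatch(
      train_hybrid(dataset, known, spec, combos$w[i], combos$b[i], cfg_i),
      error = function(e) NULL)
    fits[[i]] <- f
    if (!is.null(f)) {
      tab$val_loss[i] <- f$val_loss
      tab$best_epoch[i] <- f$best_epoch
    }
  }
  finite <- which(is.finite(tab$val_loss))
  if (!length(finite))
    stop("grid search failed: no hyperparameter combination trained ",
         "to a finite validation loss")
  best <- finite[which.min(tab$val_loss[finite])]
  list(fit = fits[[best]], table = tab)
}

#' Re-simulate the fitted hybrid model for sparse regression
#'
#' Simulates f(x) = g(x) + NN(x) from each training sample's first
#' observation over the training span at step `dt` (which may be finer than
#' the data grid), and evaluates NN(x) pointwise on the simulated states.
#' These (states, residual-derivative) pairs form the regression problem
#' NN(X) = Theta(X) Xi. Initial conditions whose simulation fails are
#' dropped with a warning.
#'
#' @param fit a trained `hybrid_fit`.
#' @param dataset the dataset whose training samples seed the simulations.
#' @param dt simulation step size.
#' @param n_ic optional cap on the number of initial conditions used
#'   (default: all training samples).
#' @param substeps RK4 substeps per `dt` interval.
#' @return object of class `regression_data`: list with `X` (stacked
#'   simulated states), `targets` (matching NN evaluations), `dt`,
#'   `n_traj`.
#' @export
simulate_regression_data <- function(fit, dataset, dt,
                                     n_ic = NULL, substeps = 4) {
  stopifnot(dt > 0)
  tr <- dataset$train
  if (!is.null(n_ic)) tr <- tr[seq_len(min(n_ic, length(tr)))]
  t0 <- tr[[1]]$times[1]
  t1 <- tr[[1]]$times[length(tr[[1]]$times)]
  times <- grid_times(sim_grid(t0, t1, dt))
  sims <- list()
  dropped <- 0
  for (s in tr) {
    sim <- simulate_hybrid(fit, s$states[1, ], times, substeps)
    if (is.null(sim)) { dropped <- dropped + 1; next }
    sims[[length(sims) + 1L]] <- sim$states
  }
  if (dropped > 0)
    warning(dropped, " initial condition(s) dropped: simulation failed")
  if (!length(sims)) stop("all regression simulations failed")
  X <- do.call(rbind, sims)
  structure(list(X = X, targets = nn_eval(fit, X), dt = dt,
                 n_traj = length(sims)),
            class = "regression_data")
}

#' Stage-2 model selection for a fitted hybrid model
#'
#' For every (dt, library, alpha) cell of the grid: re-simulate regression
#' data at step dt, fit STLSQ at the grid's threshold, assemble the full
#' model g + Theta Xi, then score every candidate by AICc on the validation
#' split (RSS from simulating each candidate over the training span from
#' each validation sample's first observation).
#'
#' @param fit a trained `hybrid_fit`.
#' @param dataset the dataset (validation split is used for scoring).
#' @param grid a [selection_grid()]; `dt_values` must be non-NULL.
#' @param truth optional [ode_system()] with a term table; adds a
#'   topology-correctness flag per candidate.
#' @param n_ic optional cap on regression initial conditions.
#' @return a `ranked_models` report (one row per candidate, sorted by
#'   AICc), carrying the fitted models as an attribute.
#' @export
select_models <- function(fit, dataset, grid, truth = dataset$system,
                          n_ic = NULL) {
  stopifnot(inherits(grid, "selection_grid"), !is.null(grid$dt_values))
  candidates <- list()
  for (dt in grid$dt_values) {
    rd <- simulate_regression_data(fit, dataset, dt, n_ic = n_ic)
    for (lib_name in grid$library_names) {
      lib <- build_library(lib_name, fit$known$d)
      Theta <- eval_basis(lib, rd$X)
      for (alpha in grid$alpha_values) {
        co <- suppressWarnings(
          stlsq(Theta, rd$targets, alpha = alpha, lambda = grid$lambda))
        model <- assemble_model(fit$known, co, lib)
        candidates[[length(candidates) + 1L]] <- list(
          model = model,
          hyper = list(dt = dt, library = lib_name, alpha = alpha))
      }
    }
  }
  rank_candidates(candidates, dataset$validation, truth)
}
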