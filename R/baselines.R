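#' Finite-difference derivative estimate
#'
#' Second-order centered differences at interior points and second-order
#' one-sided stencils at the endpoints; exact for quadratics. Requires a
#' uniform time grid with at least three points.
#'
#' @param traj a [trajectory()].
#' @return object of class `derivative_estimate`: list with `times`,
#'   `values` (matrix matching the trajectory shape), `method`.
#' @export
finite_difference <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  t <- traj$times
  n <- length(t)
  if (n < 3) stop("need at least 3 time points for finite differences")
  h <- diff(t)
  if (max(abs(h - h[1])) > 1e-8 * h[1])
    stop("finite differences require a uniform grid")
  h <- h[1]
  X <- traj$states
  D <- matrix(0, n, ncol(X))
  D[2:(n - 1), ] <- (X[3:n, , drop = FALSE] -
                     X[1:(n - 2), , drop = FALSE]) / (2 * h)
  D[1, ] <- (-3 * X[1, ] + 4 * X[2, ] - X[3, ]) / (2 * h)
  D[n, ] <- (3 * X[n, ] - 4 * X[n - 1, ] + X[n - 2, ]) / (2 * h)
  structure(list(times = t, values = D, method = "fd2"),
            class = "derivative_estimate")
}

# stack training states and FD-derivative targets over all samples
fd_regression_data <- function(dataset) {
  X <- do.call(rbind, lapply(dataset$train, function(tr) tr$states))
  D <- do.call(rbind, lapply(dataset$train, function(tr)
    finite_difference(tr)$values))
  list(X = X, targets = D)
}

# shared stage-2 loop for derivative/weak-form methods: one candidate per
# (library, alpha), scored on the validation split
rank_feature_candidates <- function(features_fun, known, dataset, grid,
                                    truth) {
  candidates <- list()
  for (lib_name in grid$library_names) {
    lib <- build_library(lib_name, known$d)
    feats <- features_fun(lib)
    colnames(feats$Theta) <- lib$labels
    for (alpha in grid$alpha_values) {
      co <- suppressWarnings(
        stlsq(feats$Theta, feats$targets, alpha = alpha,
              lambda = grid$lambda))
      model <- assemble_model(known, co, lib)
      candidates[[length(candidates) + 1L]] <- list(
        model = model,
        hyper = list(dt = NULL, library = lib_name, alpha = alpha))
    }
  }
  rank_candidates(candidates, dataset$validation, truth)
}

#' Base SINDy: single-step sparse regression on finite differences
#'
#' Estimates derivatives of every training sample by finite differences,
#' stacks all samples, and runs STLSQ over the (library, alpha) grid with
#' AICc selection on the validation split. No prior knowledge and no
#' interpolation step-size hyperparameter.
#'
#' @param dataset a [make_dataset()] result.
#' @param grid a [selection_grid()] (its `dt_values` are ignored).
#' @param truth optional [ode_system()] for topology flags.
#' @return a `ranked_models` report.
#' @export
base_sindy <- function(dataset, grid, truth = dataset$system) {
  d <- ncol(dataset$train[[1]]$states)
  rd <- fd_regression_data(dataset)
  rank_feature_candidates(
    function(lib) list(Theta = eval_basis(lib, rd$X), targets = rd$targets),
    known_zero(d), dataset, grid, truth)
}

#' Base-known: finite-difference SINDy with known terms subtracted
#'
#' Identical to [base_sindy()] except the known part g(x) is evaluated on
#' the observed states and subtracted from the finite-difference
#' derivatives before regression; the inferred model is g plus the learned
#' terms. With `known = known_zero(d)` this reduces exactly to
#' [base_sindy()].
#'
#' @param dataset a [make_dataset()] result.
#' @param known a [known_part()].
#' @param grid a [selection_grid()].
#' @param truth optional [ode_system()] for topology flags.
#' @return a `ranked_models` report.
#' @export
base_known <- function(dataset, known, grid, truth = dataset$system) {
  rd <- fd_regression_data(dataset)
  targets <- rd$targets - known_eval(known, rd$X)
  rank_feature_candidates(
    function(lib) list(Theta = eval_basis(lib, rd$X), targets = targets),
    known, dataset, grid, truth)
}

#' Weak-form SINDy
#'
#' Converts the pointwise regression X' = Theta(X) Xi into its weak form:
#' for compactly supported polynomial bump test functions
#' `phi(t) = ((t - a)(b - t))^p` on random subwindows `[a, b]` of each
#' sample, integration by parts turns the left side into
#' `-integral(phi' x)` (phi vanishes at the subwindow ends) and the right
#' side into `integral(phi Theta(x))`, both computed by trapezoidal
#' quadrature on the data grid. STLSQ then runs on the stacked
#' (subwindow x sample) feature rows. Derivative-free, hence more robust
#' to moderate noise.
#'
#' @param dataset a [make_dataset()] result.
#' @param grid a [selection_grid()] (`dt_values` ignored).
#' @param truth optional [ode_system()] for topology flags.
#' @param K number of random subwindows per sample.
#' @param p bump exponent (smoothness of the test function).
#' @param min_len,max_len subwindow length range, as fractions of the full
#'   span.
#' @param seed RNG seed for subwindow placement.
#' @return a `ranked_models` report.
#' @export
weak_sindy <- function(dataset, grid, truth = dataset$system,
                       K = 100, p = 3, min_len = 0.2, max_len = 0.8,
                       seed = 1) {
  trajs <- dataset$train
  t <- trajs[[1]]$times
  n <- length(t)
  d <- ncol(trajs[[1]]$states)
  if (n < 5) stop("weak form needs at least 5 time points")
  # draw subwindows once (shared across samples and libraries)
  wins <- withr_seed(seed, {
    lapply(seq_len(K), function(k) {
      len <- stats::runif(1, min_len, max_len) * (n - 1)
      len <- max(4L, min(n - 1L, round(len)))
      i0 <- sample.int(n - len, 1)
      c(i0, i0 + len)
    })
  })
  # precompute phi and phi' per subwindow on the grid
  tf <- lapply(wins, function(wi) {
    idx <- wi[1]:wi[2]
    a <- t[wi[1]]; b <- t[wi[2]]
    u <- (t[idx] - a) * (b - t[idx])
    scale <- ((b - a) / 2)^(2 * p)  # normalize peak to 1
    phi <- u^p / scale
    dphi <- p * u^(p - 1) * (a + b - 2 * t[idx]) / scale
    list(idx = idx, tt = t[idx], phi = phi, dphi = dphi)
  })
  trap <- function(tt, y) sum(diff(tt) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)
  weak_features <- function(lib) {
    rows_T <- list(); rows_b <- list()
    for (tr in trajs) {
      Th_full <- eval_basis(lib, tr$states)
      for (f in tf) {
        Xw <- tr$states[f$idx, , drop = FALSE]
        b_row <- vapply(seq_len(d), function(j)
          -trap(f$tt, f$dphi * Xw[, j]), numeric(1))
        T_row <- vapply(seq_len(lib$size), function(m)
          trap(f$tt, f$phi * Th_full[f$idx, m]), numeric(1))
        rows_b[[length(rows_b) + 1L]] <- b_row
        rows_T[[length(rows_T) + 1L]] <- T_row
      }
    }
    list(Theta = do.call(rbind, rows_T), targets = do.call(rbind, rows_b))
  }
  rank_feature_candidates(weak_features, known_zero(d), dataset, grid, truth)
}

#' Pure-NN discovery: the hybrid pipeline with no prior
#'
#' Sets g(x) = 0 so the network approximates the entire right-hand side,
#' then runs the identical stage-1 training and stage-2 sparse-regression
#' selection as the hybrid method.
#'
#' @param dataset a [make_dataset()] result.
#' @param spec an [nn_spec()].
#' @param w,b,cfg stage-1 settings as in [train_hybrid()] (scalars; use
#'   [grid_search_nn()] directly with `known_zero` for a full stage-1
#'   search).
#' @param grid a [selection_grid()] for stage 2.
#' @param truth optional [ode_system()] for topology flags.
#' @param n_ic optional cap on regression initial conditions.
#' @return list with `fit` (the trained `hybrid_fit`) and `report`
#'   (`ranked_models`).
#' @export
pure_nn <- function(dataset, spec, w, b, cfg = train_config(), grid,
                    truth = dataset$system, n_ic = NULL) {
  d <- ncol(dataset$train[[1]]$states)
  fit <- train_hybrid(dataset, known_zero(d), spec, w, b, cfg)
  report <- select_models(fit, dataset, grid, truth = truth, n_ic = n_ic)
  list(fit = fit, report = report)
}
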