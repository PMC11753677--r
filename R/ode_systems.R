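#' Construct an ODE system
#'
#' An `ode_system` bundles a vector-valued right-hand side with named
#' parameters, species names and (optionally) the canonical term table used
#' for topology checks against discovered models.
#'
#' @param rhs function of signature `function(x, params)` returning a numeric
#'   vector of length `d`.
#' @param d state dimension.
#' @param params named numeric vector of parameters; all must be finite.
#' @param species character vector of species names (default `x1..xd`).
#' @param name optional identifier.
#' @param terms optional data frame with columns `eq`, `label`, `sign`
#'   describing the true term structure (see [topology_correct()]).
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(rhs, d, params = numeric(), species = NULL,
                       name = NULL, terms = NULL) {
  stopifnot(is.function(rhs), length(d) == 1L, d >= 1)
  if (length(params) && any(!is.finite(params)))
    stop("all parameters must be finite")
  if (is.null(species)) species <- paste0("x", seq_len(d))
  stopifnot(length(species) == d)
  out <- rhs(rep(1, d), params)
  if (length(out) != d)
    stop("rhs output dimension (", length(out), ") does not equal d (", d, ")")
  structure(list(rhs = rhs, d = as.integer(d), params = params,
                 species = species, name = name, terms = terms),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  d =", x$d, " species:", paste(x$species, collapse = ", "), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), signif(x$params, 4),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Lotka-Volterra predator-prey system
#'
#' Two-species system `x1' = alpha*x1 - beta*x1*x2`,
#' `x2' = gamma*x1*x2 - delta*x2` where `x1` is the prey and `x2` the
#' predator population.
#'
#' @param params named numeric vector with positive entries `alpha`, `beta`,
#'   `gamma`, `delta`.
#' @return An `ode_system` of dimension 2.
#' @export
lotka_volterra <- function(params = c(alpha = 1.3, beta = 0.9,
                                      gamma = 0.8, delta = 1.8)) {
  need <- c("alpha", "beta", "gamma", "delta")
  if (!all(need %in% names(params)))
    stop("params must contain: ", paste(need, collapse = ", "))
  params <- params[need]
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all Lotka-Volterra parameters must be positive and finite")
  rhs <- function(x, p) {
    c(p[["alpha"]] * x[1] - p[["beta"]] * x[1] * x[2],
      p[["gamma"]] * x[1] * x[2] - p[["delta"]] * x[2])
  }
  terms <- data.frame(
    eq = c(1L, 1L, 2L, 2L),
    label = c("x1", "x1*x2", "x1*x2", "x2"),
    sign = c(1, -1, 1, -1))
  ode_system(rhs, 2L, params, name = "lotka_volterra", terms = terms)
}

#' Repressilator gene-circuit system
#'
#' Three proteins in a cyclic negative-feedback loop: each species is
#' repressed by its upstream neighbour through a Hill function,
#' `xi' = beta_i / (1 + x_{i-1}^{n_i}) - gamma * xi` (indices cyclic, so
#' `x1` is repressed by `x3`). The half-maximal constant is fixed at
#' `k = 1` and is not configurable.
#'
#' @param beta basal production rate: positive scalar (symmetric circuit) or
#'   length-3 vector (asymmetric, one rate per species).
#' @param n Hill order (cooperativity): positive integer scalar or length-3
#'   integer vector.
#' @param gamma positive degradation rate, shared across species.
#' @return An `ode_system` of dimension 3.
#' @export
repressilator <- function(beta = 10, n = 3, gamma = 1) {
  if (!length(beta) %in% c(1L, 3L) || any(!is.finite(beta)) || any(beta <= 0))
    stop("beta must be a positive scalar or length-3 vector")
  if (!length(n) %in% c(1L, 3L) || any(n < 1) || any(n != round(n)))
    stop("n must be a positive integer (scalar or length-3)")
  if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a positive scalar")
  beta <- rep(beta, length.out = 3)
  n <- as.integer(rep(n, length.out = 3))
  params <- c(beta1 = beta[1], beta2 = beta[2], beta3 = beta[3],
              n1 = n[1], n2 = n[2], n3 = n[3], gamma = gamma)
  rep_idx <- c(3L, 1L, 2L)  # species i is repressed by rep_idx[i]
  rhs <- function(x, p) {
    b <- c(p[["beta1"]], p[["beta2"]], p[["beta3"]])
    nn <- c(p[["n1"]], p[["n2"]], p[["n3"]])
    b / (1 + x[rep_idx]^nn) - p[["gamma"]] * x
  }
  terms <- data.frame(
    eq = rep(1:3, each = 2),
    label = c(hill_label(3L, n[1]), "x1",
              hill_label(1L, n[2]), "x2",
              hill_label(2L, n[3]), "x3"),
    sign = rep(c(1, -1), 3))
  nm <- if (length(unique(beta)) == 1L && length(unique(n)) == 1L)
    "repressilator" else "repressilator_asym"
  ode_system(rhs, 3L, params, name = nm, terms = terms)
}

#' Named benchmark presets
#'
#' Returns a benchmark system together with its reference initial condition
#' and the default data-generation grids. `"lotka_volterra"` is the main
#' parameterization (params 1.3/0.9/0.8/1.8, x0 = c(0.4425, 4.6281));
#' `"lotka_volterra_alt"` keeps those parameters with x0 = c(2.5, 0.7);
#' `"lotka_volterra_alt2"` uses params 2.1/1.2/0.7/1.1 (the two alternative
#' parameterizations circulate with conflicting descriptions, so both are
#' exposed). `"repressilator"` is the symmetric circuit (beta = 10, n = 3),
#' `"repressilator_asym"` the asymmetric one (beta = c(7, 6, 8), n = 2).
#'
#' @param name preset identifier.
#' @return list with elements `system`, `x0`, `train_grid`, `test_grid`.
#' @export
ode_preset <- function(name = c("lotka_volterra", "lotka_volterra_alt",
                                "lotka_volterra_alt2", "repressilator",
                                "repressilator_asym")) {
  name <- match.arg(name)
  switch(name,
    lotka_volterra = list(
      system = lotka_volterra(),
      x0 = c(0.4425, 4.6281),
      train_grid = sim_grid(0, 4, 0.1),
      test_grid = sim_grid(0, 20, 0.1)),
    lotka_volterra_alt = list(
      system = lotka_volterra(),
      x0 = c(2.5, 0.7),
      train_grid = sim_grid(0, 4, 0.1),
      test_grid = sim_grid(0, 20, 0.1)),
    lotka_volterra_alt2 = list(
      system = lotka_volterra(c(alpha = 2.1, beta = 1.2,
                                gamma = 0.7, delta = 1.1)),
      x0 = c(2.5, 0.7),
      train_grid = sim_grid(0, 4, 0.1),
      test_grid = sim_grid(0, 20, 0.1)),
    repressilator = list(
      system = repressilator(beta = 10, n = 3, gamma = 1),
      x0 = c(1, 1, 1.2),
      train_grid = sim_grid(0, 10, 0.2),
      test_grid = sim_grid(0, 30, 0.2)),
    repressilator_asym = list(
      system = repressilator(beta = c(7, 6, 8), n = 2, gamma = 1),
      x0 = c(1, 1, 1.2),
      train_grid = sim_grid(0, 10, 0.2),
      test_grid = sim_grid(0, 30, 0.2)))
}

#' Uniform simulation grid
#'
#' Closed interval `[t_start, t_end]` sampled at step `dt`; the number of
#' points is `round((t_end - t_start)/dt) + 1` and both endpoints are
#' included.
#'
#' @param t_start,t_end interval endpoints, `t_end >= t_start`.
#' @param dt positive step size.
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(t_start, t_end, dt) {
  stopifnot(is.finite(t_start), is.finite(t_end), is.finite(dt), dt > 0)
  if (t_end < t_start) stop("t_end must be >= t_start")
  structure(list(t_start = t_start, t_end = t_end, dt = dt),
            class = "sim_grid")
}

#' Grid time points
#' @param grid a [sim_grid()].
#' @return numeric vector of times.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "sim_grid"))
  n <- round((grid$t_end - grid$t_start) / grid$dt)
  grid$t_start + (0:n) * grid$dt
}

#' Construct a trajectory
#'
#' @param times strictly increasing numeric vector.
#' @param states numeric matrix, `length(times)` rows, one column per species.
#' @param species optional species names used as column names.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, states, species = NULL) {
  states <- as.matrix(states)
  stopifnot(length(times) == nrow(states))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(states))) stop("states must be finite")
  if (!is.null(species)) colnames(states) <- species
  else if (is.null(colnames(states)))
    colnames(states) <- paste0("x", seq_len(ncol(states)))
  structure(list(times = as.numeric(times), states = states),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points x ",
      ncol(x$states), " species, t in [",
      x$times[1], ", ", x$times[length(x$times)], "]\n", sep = "")
  invisible(x)
}

#' Simulate an ODE system on a grid
#'
#' Integrates with the adaptive, stiffness-switching LSODA method
#' (via \pkg{deSolve}) and returns states sampled exactly on the grid
#' points. Default tolerances (1e-8) keep integration error far below the
#' smallest observation-noise level used in the benchmarks (0.1%).
#'
#' @param system an [ode_system()].
#' @param x0 finite numeric initial state of length `system$d`.
#' @param grid a [sim_grid()].
#' @param rtol,atol solver tolerances, in (0, 1).
#' @return A [trajectory()].
#' @export
simulate_ode <- function(system, x0, grid, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(system, "ode_system"), inherits(grid, "sim_grid"))
  stopifnot(length(x0) == system$d, all(is.finite(x0)))
  stopifnot(rtol > 0, rtol < 1, atol > 0, atol < 1)
  times <- grid_times(grid)
  if (length(times) == 1L)
    return(trajectory(times, matrix(x0, nrow = 1), system$species))
  fn <- function(t, y, parms) list(system$rhs(y, system$params))
  out <- deSolve::lsoda(y = x0, times = times, func = fn, parms = NULL,
                        rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || any(!is.finite(out[, -1, drop = FALSE]))) {
    last_t <- out[max(which(apply(is.finite(out[, -1, drop = FALSE]), 1, all))), 1]
    stop("integration failed; last valid time = ", last_t)
  }
  trajectory(out[, 1], out[, -1, drop = FALSE], system$species)
}

# canonical label for a Hill repression term 1/(1+x_i^n)
hill_label <- function(i, n) {
  if (n == 1) paste0("1/(1+x", i, ")") else paste0("1/(1+x", i, "^", n, ")")
}
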