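#' Cell-state proportion profile
#'
#' Median proportions and per-bin standard deviations for `n_states` cell
#' states over `n_bins` pseudotime bins; each row of medians must sum to 1.
#' Used as the base distribution for the truncated-Gaussian trajectory
#' sampler.
#'
#' @param medians `bins x states` matrix of median proportions in `[0, 1]`.
#' @param sds `bins x states` matrix of nonnegative standard deviations.
#' @param times optional pseudotime values (default integer bins `1..n`).
#' @return object of class `proportion_profile`.
#' @export
proportion_profile <- function(medians, sds, times = NULL) {
  medians <- as.matrix(medians); sds <- as.matrix(sds)
  stopifnot(all(dim(medians) == dim(sds)),
            all(medians >= 0), all(medians <= 1), all(sds >= 0))
  if (any(abs(rowSums(medians) - 1) > 1e-6))
    stop("each row of medians must sum to 1")
  if (is.null(times)) times <- seq_len(nrow(medians))
  structure(list(medians = medians, sds = sds, times = as.numeric(times),
                 n_bins = nrow(medians), n_states = ncol(medians)),
            class = "proportion_profile")
}

# draw from N(mu, sd) truncated to [lo, hi] by inverse-CDF
rtrunc_norm <- function(n, mu, sd, lo, hi) {
  if (sd == 0 || lo >= hi) return(rep(max(lo, min(hi, mu)), n))
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

#' Sample one compositional trajectory from a proportion profile
#'
#' At each pseudotime bin, the first `n_states - 1` states (by default the
#' epithelial and intermediate states) are drawn from Gaussians truncated
#' to within one standard deviation of the median and to `[0, 1]`; the
#' remaining state is closed to `1 -` the sum of the others. If the closed
#' state falls outside `[0, 1]` the whole bin is redrawn (up to
#' `max_attempts`), so every emitted row sums to 1 exactly with all entries
#' in `[0, 1]`.
#'
#' @param profile a [proportion_profile()].
#' @param seed integer seed.
#' @param draw_order which states are drawn (the remaining one is closed);
#'   default `1:(n_states-1)`.
#' @param max_attempts redraw cap per bin before erroring.
#' @return a [trajectory()] whose states are proportions.
#' @export
sample_proportion_trajectory <- function(profile, seed,
                                         draw_order = NULL,
                                         max_attempts = 1000) {
  stopifnot(inherits(profile, "proportion_profile"))
  ns <- profile$n_states
  if (is.null(draw_order)) draw_order <- seq_len(ns - 1)
  stopifnot(length(draw_order) == ns - 1, all(draw_order %in% seq_len(ns)))
  closed <- setdiff(seq_len(ns), draw_order)
  X <- withr_seed(seed, {
    out <- matrix(0, profile$n_bins, ns)
    for (j in seq_len(profile$n_bins)) {
      done <- FALSE
      for (att in seq_len(max_attempts)) {
        row <- numeric(ns)
        for (k in draw_order) {
          mu <- profile$medians[j, k]; sd <- profile$sds[j, k]
          row[k] <- rtrunc_norm(1, mu, sd,
                                lo = max(0, mu - sd), hi = min(1, mu + sd))
        }
        row[closed] <- 1 - sum(row[draw_order])
        if (row[closed] >= 0 && row[closed] <= 1) {
          out[j, ] <- row; done <- TRUE; break
        }
      }
      if (!done)
        stop("no feasible draw for pseudotime bin ", j, " after ",
             max_attempts, " attempts")
    }
    out
  })
  trajectory(profile$times, X,
             species = paste0("x", seq_len(ns)))
}

#' Synthetic epithelial-intermediate-mesenchymal median profile
#'
#' Builds logistic-shaped median curves emulating a progressive
#' E -> I -> M transition over pseudotime: the epithelial proportion falls,
#' the intermediate rises then falls, and the mesenchymal rises towards 1.
#' Rows sum to 1 by construction (I is the complement of E and M).
#'
#' @param n_bins number of pseudotime bins (integer grid `1..n_bins`).
#' @param transition_times length-2 vector: pseudotimes of the E-drop and
#'   M-rise midpoints.
#' @param sharpness length-2 vector of logistic steepness values; large
#'   values approach a step-function profile.
#' @param sd scalar or `bins x 3` matrix of sampling standard deviations.
#' @return a [proportion_profile()] with 3 states (E, I, M).
#' @export
synthetic_emt_profile <- function(n_bins = 9,
                                  transition_times = c(0.35, 0.65) *
                                    (n_bins + 1),
                                  sharpness = c(1.5, 1.5), sd = 0.05) {
  stopifnot(n_bins >= 3, transition_times[1] <= transition_times[2])
  t <- seq_len(n_bins)
  E <- 1 / (1 + exp(sharpness[1] * (t - transition_times[1])))
  M <- 1 / (1 + exp(-sharpness[2] * (t - transition_times[2])))
  # keep E + M <= 1 so the intermediate state is a valid complement
  over <- E + M
  scl <- ifelse(over > 1, 1 / over, 1)
  E <- E * scl; M <- M * scl
  I <- pmax(0, 1 - E - M)  # guard rounding at extreme sharpness
  tot <- E + I + M
  E <- E / tot; I <- I / tot; M <- M / tot
  medians <- cbind(E, I, M)
  colnames(medians) <- c("E", "I", "M")
  sds <- if (is.matrix(sd)) sd else matrix(sd, n_bins, 3)
  proportion_profile(medians, sds, times = t)
}

#' Generate a compositional cell-state dataset
#'
#' Train and validation trajectories are sampled on the profile's bins
#' (pseudotime `1..n_bins`); test trajectories are sampled on an extended
#' profile (`test_profile`, e.g. 13 bins from the same generating curves)
#' to probe extrapolation.
#'
#' @param profile a [proportion_profile()] for train/validation.
#' @param test_profile profile for the test split (default: `profile`).
#' @param n_train,n_val,n_test sample counts (defaults 200/50/50).
#' @param seed master seed.
#' @return a `trajectory_dataset` whose states are proportions (every row
#'   sums to 1); the `system` element is `NULL`.
#' @export
make_emt_dataset <- function(profile, test_profile = profile,
                             n_train = 200, n_val = 50, n_test = 50,
                             seed = 1) {
  draw <- function(prof, n, block)
    lapply(seq_len(n), function(i)
      sample_proportion_trajectory(prof,
        seed = substream_seed(seed, block * 1000003 + i)))
  structure(list(
    train = draw(profile, n_train, 1),
    validation = draw(profile, n_val, 2),
    test = draw(test_profile, n_test, 3),
    truth_train = trajectory(profile$times, profile$medians),
    truth_test = trajectory(test_profile$times, test_profile$medians),
    noise = NULL, seed = seed, system = NULL, x0 = profile$medians[1, ],
    proportions = TRUE),
    class = "trajectory_dataset")
}

#' Discover cell-state transition dynamics
#'
#' Runs the standard two-stage hybrid pipeline on a compositional dataset
#' with a known per-state loss term `g_i(x) = -loss_rates[i] * x_i`
#' (default unit loss for every state), then stage-2 selection over a
#' mixed polynomial / Hill basis grid.
#'
#' @param dataset a [make_emt_dataset()] result (or any
#'   `trajectory_dataset` with 3 proportion states).
#' @param loss_rates per-state known loss rates (default 1 each).
#' @param hidden hidden-layer widths for the residual network.
#' @param w,b,cfg stage-1 settings.
#' @param grid stage-2 [selection_grid()] (default:
#'   `default_selection_grid("emt")`).
#' @param truth optional truth term table for topology flags.
#' @return list with `fit` and `report`.
#' @export
discover_emt_model <- function(dataset, loss_rates = c(1, 1, 1),
                               hidden = c(8, 8), w = 5, b = 10,
                               cfg = train_config(),
                               grid = default_selection_grid("emt"),
                               truth = NULL) {
  d <- ncol(dataset$train[[1]]$states)
  stopifnot(length(loss_rates) == d)
  known <- known_part(-loss_rates)
  spec <- nn_spec(d, hidden = hidden, init_seed = cfg$seed)
  fit <- train_hybrid(dataset, known, spec, w, b, cfg)
  report <- select_models(fit, dataset, grid, truth = truth)
  list(fit = fit, report = report)
}
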