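#' Observation-noise specification
#'
#' Two extrinsic (measurement) noise models on a ground-truth trajectory
#' `X_true`. With *additive* noise, the observation of species `k` at time
#' `j` is `N(X_true[j,k], eps * mean_j(X_true[,k]))`: the noise scale is the
#' noise level times the time-average of that species, constant over time.
#' With *multiplicative* noise the scale is `eps * X_true[j,k]`,
#' proportional to the instantaneous true value. In both cases the second
#' Gaussian argument is interpreted as the standard deviation.
#'
#' @param kind `"additive"` or `"multiplicative"`.
#' @param level noise level `eps` in `[0, 1]`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("additive", "multiplicative"), level) {
  kind <- match.arg(kind)
  stopifnot(is.finite(level), level >= 0, level <= 1)
  structure(list(kind = kind, level = level), class = "noise_spec")
}

#' Apply observation noise to a trajectory
#'
#' Draws are independent across time points and species. Negative
#' observations are not clipped. `level = 0` returns the truth exactly.
#'
#' @param truth a [trajectory()].
#' @param noise a [noise_spec()].
#' @param seed integer RNG seed for this realization.
#' @return A [trajectory()] of noisy observations.
#' @export
apply_noise <- function(truth, noise, seed) {
  stopifnot(inherits(truth, "trajectory"), inherits(noise, "noise_spec"))
  if (noise$level == 0) return(truth)
  X <- truth$states
  sds <- if (noise$kind == "additive") {
    matrix(rep(noise$level * colMeans(X), each = nrow(X)), nrow = nrow(X))
  } else {
    noise$level * abs(X)
  }
  obs <- withr_seed(seed, {
    X + matrix(stats::rnorm(length(X), sd = 1), nrow = nrow(X)) * sds
  })
  trajectory(truth$times, obs, colnames(X))
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic substream seed derived from a master seed, bounded < 2^31
substream_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 31) %% 2147483629
}

#' Generate a noisy train/validation/test dataset
#'
#' Simulates the system once per grid (a single shared ground truth) and
#' draws independent noise realizations for each sample; variation across
#' samples is observation noise only. Training and validation samples live
#' on `train_grid`, test samples on `test_grid`. Fully deterministic given
#' `seed`.
#'
#' @param system an [ode_system()].
#' @param x0 initial state.
#' @param train_grid,test_grid [sim_grid()]s for train/validation and test.
#' @param noise a [noise_spec()].
#' @param n_train,n_val,n_test positive sample counts (defaults 200/50/50).
#' @param seed master integer seed.
#' @param rtol,atol ground-truth solver tolerances.
#' @return An object of class `trajectory_dataset` with elements `train`,
#'   `validation`, `test` (lists of trajectories), `truth_train`,
#'   `truth_test`, `noise`, `seed`, `system`, `x0`.
#' @export
make_dataset <- function(system, x0, train_grid, test_grid, noise,
                         n_train = 200, n_val = 50, n_test = 50, seed = 1,
                         rtol = 1e-8, atol = 1e-8) {
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1)
  truth_train <- simulate_ode(system, x0, train_grid, rtol, atol)
  truth_test <- simulate_ode(system, x0, test_grid, rtol, atol)
  noisy <- function(truth, n, block) {
    lapply(seq_len(n), function(i)
      apply_noise(truth, noise, substream_seed(seed, block * 1000003 + i)))
  }
  structure(list(
    train = noisy(truth_train, n_train, 1),
    validation = noisy(truth_train, n_val, 2),
    test = noisy(truth_test, n_test, 3),
    truth_train = truth_train, truth_test = truth_test,
    noise = noise, seed = seed, system = system, x0 = x0),
    class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat("<trajectory_dataset> ", length(x$train), " train / ",
      length(x$validation), " validation / ", length(x$test), " test\n",
      sep = "")
  cat("  noise: ", x$noise$kind, " ", x$noise$level * 100, "%",
      "  seed: ", x$seed, "\n", sep = "")
  cat("  train grid: ", length(x$truth_train$times), " points, test grid: ",
      length(x$truth_test$times), " points\n", sep = "")
  invisible(x)
}

#' Write / read a dataset as delimited text
#'
#' Each split is one CSV with columns `sample_id, t, <species...>`; a JSON
#' sidecar records the system name, parameters, noise spec and seed.
#'
#' @param dataset a `trajectory_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   list of splits (lists of trajectories) plus the sidecar metadata.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in c("train", "validation", "test")) {
    rows <- do.call(rbind, lapply(seq_along(dataset[[split]]), function(i) {
      tr <- dataset[[split]][[i]]
      data.frame(sample_id = i, t = tr$times, tr$states,
                 check.names = FALSE)
    }))
    utils::write.csv(rows, file.path(dir, paste0(split, ".csv")),
                     row.names = FALSE)
  }
  meta <- list(system = dataset$system$name,
               params = as.list(dataset$system$params),
               x0 = dataset$x0,
               noise = list(kind = dataset$noise$kind,
                            level = dataset$noise$level),
               seed = dataset$seed)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  splits <- lapply(c(train = "train", validation = "validation",
                     test = "test"), function(split) {
    f <- file.path(dir, paste0(split, ".csv"))
    if (!file.exists(f)) return(NULL)
    df <- utils::read.csv(f, check.names = FALSE)
    lapply(split(df, df$sample_id), function(s)
      trajectory(s$t, as.matrix(s[, -(1:2), drop = FALSE])))
  })
  meta_f <- file.path(dir, "dataset.json")
  splits$meta <- if (file.exists(meta_f)) jsonlite::read_json(meta_f) else NULL
  splits
}
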