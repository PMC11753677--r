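#' Declarative experiment configuration
#'
#' Encodes a full end-to-end run: benchmark preset, noise model, dataset
#' sizes, known-part selector, stage-1 and stage-2 grids, and seeds.
#' Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param system preset name (see [ode_preset()]).
#' @param noise_kind,noise_level observation-noise model.
#' @param n_train,n_val,n_test dataset sizes.
#' @param known known-part selector: `"benchmark"` (the preset's standard
#'   prior: growth/death terms for predator-prey, unit degradation for the
#'   repressilator) or `"zero"` (no prior; the pure-NN formulation).
#' @param hidden hidden-layer widths (default: preset-appropriate).
#' @param w_values,b_values,lr_values stage-1 grid.
#' @param epochs training epochs per combination.
#' @param selection stage-2 grid name (default: matches the preset).
#' @param seed master seed (dataset, init and shuffling derive from it).
#' @return object of class `experiment_config` (a named list).
#' @export
experiment_config <- function(system = "lotka_volterra",
                              noise_kind = "additive", noise_level = 0.01,
                              n_train = 200, n_val = 50, n_test = 50,
                              known = c("benchmark", "zero"),
                              hidden = NULL,
                              w_values = c(5, 10), b_values = c(5, 10, 20),
                              lr_values = c(0.001, 0.01, 0.1),
                              epochs = 10, selection = NULL, seed = 1) {
  known <- match.arg(known)
  if (is.null(hidden))
    hidden <- if (grepl("^lotka", system)) 8 else c(8, 8)
  if (is.null(selection))
    selection <- if (grepl("^lotka", system)) "lotka_volterra"
                 else "repressilator"
  structure(list(system = system, noise_kind = noise_kind,
                 noise_level = noise_level, n_train = n_train,
                 n_val = n_val, n_test = n_test, known = known,
                 hidden = hidden, w_values = w_values, b_values = b_values,
                 lr_values = lr_values, epochs = epochs,
                 selection = selection, seed = seed),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

# resolve the standard prior for a preset
benchmark_known <- function(config, system) {
  if (config$known == "zero") return(known_zero(system$d))
  if (grepl("^lotka", config$system)) {
    p <- system$params
    known_part(c(p[["alpha"]], -p[["delta"]]))
  } else {
    known_part(rep(-system$params[["gamma"]], 3))
  }
}

# dataset described by a config
config_dataset <- function(config) {
  preset <- ode_preset(config$system)
  make_dataset(preset$system, preset$x0, preset$train_grid,
               preset$test_grid,
               noise_spec(config$noise_kind, config$noise_level),
               n_train = config$n_train, n_val = config$n_val,
               n_test = config$n_test, seed = config$seed)
}

#' Run a full experiment: generate, fit, discover, select
#'
#' Executes the complete pipeline described by a config: synthetic dataset
#' generation, stage-1 grid search over the network hyperparameters,
#' stage-2 sparse-regression selection, and (optionally) artifact output.
#' Deterministic given the config's seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the dataset CSVs, stage-1
#'   search table, ranked report and config are written there.
#' @return list with `dataset`, `fit`, `search_table`, `report`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dataset <- config_dataset(config)
  known <- benchmark_known(config, dataset$system)
  spec <- nn_spec(dataset$system$d, hidden = config$hidden,
                  init_seed = config$seed)
  cfg <- train_config(epochs = config$epochs, seed = config$seed)
  search <- grid_search_nn(dataset, known, spec,
                           w_values = config$w_values,
                           b_values = config$b_values,
                           lr_values = config$lr_values, cfg = cfg)
  report <- select_models(search$fit, dataset,
                          default_selection_grid(config$selection))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset, file.path(out_dir, "dataset"))
    utils::write.csv(search$table,
                     file.path(out_dir, "stage1_search.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "ranked_models.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(format_equations(best_model(report)),
               file.path(out_dir, "best_model.txt"))
  }
  list(dataset = dataset, fit = search$fit, search_table = search$table,
       report = report)
}

#' Compare discovery methods on one dataset
#'
#' Runs any subset of the five methods (hybrid, base SINDy, base-known,
#' weak-form SINDy, pure NN) on the same dataset and summarizes each by
#' its best AICc, topology correctness, and best hyperparameters. Methods
#' for which no candidate simulates stably report `NA` AICc.
#'
#' @param config an [experiment_config()].
#' @param methods subset of
#'   `c("hybrid", "base", "base_known", "weak", "pure_nn")`.
#' @param w,b,lr single stage-1 setting used for the NN-based methods
#'   (keeps the comparison affordable; pass vectors of length one).
#' @return data frame: one row per method with columns `method`,
#'   `best_aicc`, `topology_correct`, `dt`, `library`, `alpha`; the full
#'   reports are attached as attribute `"reports"`.
#' @export
compare_methods <- function(config,
                            methods = c("hybrid", "base", "base_known",
                                        "weak", "pure_nn"),
                            w = 5, b = 5, lr = 0.01) {
  methods <- match.arg(methods, several.ok = TRUE)
  dataset <- config_dataset(config)
  known <- benchmark_known(config, dataset$system)
  sel <- default_selection_grid(config$selection)
  cfg <- train_config(lr = lr, epochs = config$epochs, seed = config$seed)
  spec <- nn_spec(dataset$system$d, hidden = config$hidden,
                  init_seed = config$seed)
  reports <- list()
  for (mth in methods) {
    reports[[mth]] <- switch(mth,
      hybrid = {
        fit <- train_hybrid(dataset, known, spec, w, b, cfg)
        select_models(fit, dataset, sel)
      },
      base = base_sindy(dataset, sel),
      base_known = base_known(dataset, known, sel),
      weak = weak_sindy(dataset, sel, seed = config$seed),
      pure_nn = pure_nn(dataset, spec, w, b, cfg, sel)$report)
  }
  rows <- lapply(methods, function(mth) {
    rep <- reports[[mth]]
    top <- rep[1, ]
    ok <- is.finite(top$aicc)
    data.frame(method = mth,
               best_aicc = if (ok) top$aicc else NA_real_,
               topology_correct = if (ok) top$topology_correct else NA,
               dt = top$dt, library = if (ok) top$library else NA_character_,
               alpha = if (ok) top$alpha else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
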