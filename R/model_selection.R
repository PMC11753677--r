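#' Corrected Akaike information criterion
#'
#' `AICc = n*log(RSS/n) + 2k + 2(k+1)(k+2)/(n-k-2)`, where `n` is the
#' number of validation samples and `k` the number of estimated (learned)
#' coefficients. Lower is better.
#'
#' @param rss residual sum of squares, `> 0` (`rss = 0` returns `-Inf` with
#'   a warning; `rss = Inf` returns `Inf`).
#' @param n number of validation samples; must exceed `k + 2`.
#' @param k number of estimated parameters.
#' @return the AICc value.
#' @export
aicc <- function(rss, n, k) {
  stopifnot(n >= 1, k >= 0)
  if (n <= k + 2)
    stop("AICc correction undefined: need n > k + 2 (n = ", n,
         ", k = ", k, ")")
  if (!is.finite(rss)) return(Inf)
  if (rss < 0) stop("rss must be nonnegative")
  if (rss == 0) {
    warning("rss = 0: AICc is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k + 2 * (k + 1) * (k + 2) / (n - k - 2)
}

#' Residual sum of squares of a model on validation trajectories
#'
#' Each validation sample is simulated from its own (noisy) first
#' observation over that sample's time grid; squared residuals are summed
#' over samples, time points and species. Simulation blow-up or failure on
#' any sample yields `Inf` (such candidates rank last).
#'
#' @param model a `sindy_model`.
#' @param validation list of [trajectory()] objects.
#' @return total RSS (possibly `Inf`).
#' @export
model_rss <- function(model, validation) {
  stopifnot(length(validation) >= 1)
  total <- 0
  for (tr in validation) {
    grid <- sim_grid(tr$times[1], tr$times[length(tr$times)],
                     tr$times[2] - tr$times[1])
    pred <- simulate(model, x0 = tr$states[1, ], grid = grid)
    if (is.null(pred)) return(Inf)
    total <- total + sum((tr$states - pred$states)^2)
  }
  total
}

#' Stage-2 hyperparameter grid
#'
#' @param dt_values step sizes for re-simulating the fitted hybrid model
#'   (use `NULL` for derivative-based methods, which cannot interpolate).
#' @param library_names basis library identifiers (see [build_library()]).
#' @param alpha_values STLSQ ridge parameters.
#' @param lambda fixed STLSQ threshold.
#' @return object of class `selection_grid`.
#' @export
selection_grid <- function(dt_values, library_names, alpha_values, lambda) {
  stopifnot(length(library_names) >= 1, length(alpha_values) >= 1,
            length(lambda) == 1)
  structure(list(dt_values = dt_values, library_names = library_names,
                 alpha_values = alpha_values, lambda = lambda),
            class = "selection_grid")
}

#' Default stage-2 grids for the benchmark systems
#'
#' The predator-prey grid searches 2 step sizes x 2 polynomial libraries x
#' 6 ridge values at threshold 0.1 (24 candidates); the repressilator grid
#' searches 2 step sizes x 4 Hill libraries x 6 ridge values at threshold
#' 1.0 (48 candidates); the cell-state grid mixes polynomial and
#' Hill/polynomial libraries at threshold 0.1.
#'
#' @param name one of `"lotka_volterra"`, `"repressilator"`, `"emt"`.
#' @return a [selection_grid()].
#' @export
default_selection_grid <- function(name = c("lotka_volterra",
                                            "repressilator", "emt")) {
  name <- match.arg(name)
  alphas <- c(0.05, 0.1, 0.5, 1, 5, 10)
  switch(name,
    lotka_volterra = selection_grid(c(0.05, 0.1),
                                    c("poly_max_2", "poly_2_3"),
                                    alphas, lambda = 0.1),
    repressilator = selection_grid(c(0.1, 0.2),
                                   c("hill_1", "hill_2", "hill_3",
                                     "hill_max_3"),
                                   alphas, lambda = 1.0),
    emt = selection_grid(c(0.5, 1),
                         c("poly_max_2", "poly_1_2", "hill_3_poly_1",
                           "hill_3_poly_xy", "hill_3_poly_1_2",
                           "hill_max_3_poly_1"),
                         alphas, lambda = 0.1))
}

# score a list of candidates (each: list(model, hyper)) on validation data
# and return the ranked report
rank_candidates <- function(candidates, validation, truth = NULL) {
  if (!length(candidates)) stop("no candidate models to rank")
  if (inherits(truth, "ode_system") && is.null(truth$terms)) truth <- NULL
  n <- length(validation)
  rows <- lapply(candidates, function(cand) {
    k <- n_learned(cand$model)
    rss <- if (n > k + 2) model_rss(cand$model, validation) else Inf
    a <- if (n > k + 2) suppressWarnings(aicc(rss, n, k)) else Inf
    data.frame(dt = cand$hyper$dt %||% NA_real_,
               library = cand$hyper$library %||% NA_character_,
               alpha = cand$hyper$alpha %||% NA_real_,
               k = k, rss = rss, aicc = a,
               simulated = is.finite(rss),
               topology_correct = if (is.null(truth)) NA
                 else topology_correct(cand$model, truth, strict = FALSE))
  })
  report <- do.call(rbind, rows)
  ord <- order(report$aicc)
  report <- report[ord, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  structure(report[, c("rank", "dt", "library", "alpha", "k", "rss",
                       "aicc", "simulated", "topology_correct")],
            models = lapply(candidates[ord], `[[`, "model"),
            class = c("ranked_models", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ranked_models <- function(x, n = 5, ...) {
  cat("<ranked_models> ", nrow(x), " candidates; top ", min(n, nrow(x)),
      ":\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  best <- best_model(x)
  if (!is.null(best)) {
    cat("best model (lowest AICc):\n")
    cat(paste0("  ", format_equations(best)), sep = "\n")
  }
  invisible(x)
}

#' Extract the i-th ranked model
#' @param report a `ranked_models` report.
#' @param rank rank index (1 = lowest AICc).
#' @return the corresponding `sindy_model`.
#' @export
best_model <- function(report, rank = 1) {
  attr(report, "models")[[rank]]
}

#' Topological correctness of a discovered model
#'
#' A candidate is topology-correct when its set of nonzero terms — known
#' plus learned, compared by canonical label and coefficient sign, per
#' equation — exactly matches the ground truth's term set, with no extra
#' terms. Coefficient values are not compared.
#'
#' @param candidate a `sindy_model`.
#' @param truth an [ode_system()] carrying a `terms` table, or such a table
#'   directly (columns `eq`, `label`, `sign`).
#' @param strict error when the truth's terms are not expressible in the
#'   candidate's basis vocabulary (default); with `strict = FALSE` such a
#'   candidate is simply incorrect (`FALSE`), the convention used when
#'   ranking mixed-library candidate sets.
#' @return logical.
#' @export
topology_correct <- function(candidate, truth, strict = TRUE) {
  tt <- if (inherits(truth, "ode_system")) truth$terms else truth
  if (is.null(tt)) stop("truth has no term table to compare against")
  ct <- model_terms(candidate)
  truth_keys <- sort(paste(tt$eq, tt$label, tt$sign))
  cand_keys <- sort(paste(ct$eq, ct$label, ct$sign))
  vocab <- unique(c(candidate$lib$labels, candidate$known$terms$label))
  if (!all(tt$label %in% vocab)) {
    if (strict)
      stop("truth terms not expressible in the candidate's basis ",
           "vocabulary: ", paste(setdiff(tt$label, vocab), collapse = ", "))
    return(FALSE)
  }
  identical(truth_keys, cand_keys)
}
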