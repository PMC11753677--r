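#' Known closed-form part of a hybrid system
#'
#' The prior knowledge g(x) in the hybrid formulation x' = g(x) + NN(x).
#' All supported priors are species-wise linear: `g_i(x) = coef_i * x_i`
#' (growth or decay of each species), which covers the benchmark setups —
#' e.g. `known_part(c(alpha, -delta))` for predator-prey growth/death
#' terms, `known_part(rep(-1, 3))` for unit degradation of each protein.
#' `known_zero(d)` is the no-prior case used by purely data-driven methods.
#'
#' @param coef numeric vector: per-species linear rate (may contain zeros).
#' @return object of class `known_part` with fields `coef`, `d`, `terms`.
#' @export
known_part <- function(coef) {
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  d <- length(coef)
  nz <- which(coef != 0)
  labs <- if (length(nz)) paste0("x", nz) else character(0)
  terms <- data.frame(eq = nz, label = labs,
                      sign = sign(coef[nz]), coef = coef[nz])
  structure(list(coef = as.numeric(coef), d = d, terms = terms),
            class = "known_part")
}

#' @rdname known_part
#' @param d state dimension.
#' @export
known_zero <- function(d) known_part(rep(0, d))

# g evaluated on an n x d state matrix
known_eval <- function(known, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(X, 2, known$coef, "*")
}

#' Sequentially thresholded least squares (STLSQ)
#'
#' The sparse-regression optimizer: per target dimension, iterate ridge
#' regression on the currently active basis columns, zero out coefficients
#' with magnitude below `lambda`, and shrink the active set, until the
#' active set is stable or `max_iter` is reached. Ridge regularization is
#' applied to the raw (unstandardized) columns; there is no implicit
#' intercept — a constant enters only through the library.
#'
#' @param Theta `n x m` matrix of basis-function values.
#' @param targets `n x d` matrix (or length-n vector) of regression targets.
#' @param alpha ridge regularization parameter, `>= 0`.
#' @param lambda hard threshold on coefficient magnitude, `>= 0`.
#' @param max_iter maximum sweeps (default 20).
#' @return `m x d` coefficient matrix (class `coefficient_matrix`), row
#'   names from `colnames(Theta)`. Every nonzero entry has magnitude
#'   `>= lambda`. An equation whose active set empties is returned as an
#'   all-zero column with a warning.
#' @export
stlsq <- function(Theta, targets, alpha = 0, lambda = 0, max_iter = 20) {
  Theta <- as.matrix(Theta)
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 1)
  stopifnot(nrow(Theta) == nrow(targets), alpha >= 0, lambda >= 0,
            max_iter >= 1)
  m <- ncol(Theta)
  d <- ncol(targets)
  ridge_solve <- function(X, y) {
    if (alpha == 0) {
      qr.coef(qr(X), y)
    } else {
      A <- crossprod(X) + diag(alpha, ncol(X))
      solve(A, crossprod(X, y))
    }
  }
  Xi <- matrix(0, m, d)
  for (j in seq_len(d)) {
    active <- rep(TRUE, m)
    for (it in seq_len(max_iter)) {
      co <- ridge_solve(Theta[, active, drop = FALSE], targets[, j])
      co[is.na(co)] <- 0  # rank-deficient columns contribute nothing
      keep <- abs(co) >= lambda
      full <- numeric(m)
      full[active] <- ifelse(keep, co, 0)
      changed <- !identical(which(active)[keep], which(active))
      active[active] <- keep
      if (!any(active)) {
        warning("STLSQ: active set empty for target dimension ", j)
        full <- numeric(m)
        break
      }
      if (!changed) break
    }
    Xi[, j] <- full
  }
  rownames(Xi) <- colnames(Theta)
  structure(Xi, class = c("coefficient_matrix", "matrix", "array"),
            alpha = alpha, lambda = lambda)
}

#' Assemble the full symbolic ODE model g(x) + Theta(x) Xi
#'
#' Combines the fixed known part with the learned sparse coefficients into
#' a printable, simulatable model object.
#'
#' @param known a [known_part()].
#' @param coefs an `m x d` coefficient matrix from [stlsq()].
#' @param lib the [build_library()] the coefficients refer to.
#' @return object of class `sindy_model`.
#' @export
assemble_model <- function(known, coefs, lib) {
  stopifnot(inherits(known, "known_part"), inherits(lib, "basis_library"))
  coefs <- unclass(coefs)
  stopifnot(nrow(coefs) == lib$size, ncol(coefs) == known$d)
  structure(list(known = known, coefs = coefs, lib = lib, d = known$d),
            class = "sindy_model")
}

#' Right-hand side of an assembled model
#'
#' @param model a [assemble_model()] result.
#' @return function of a state vector returning the d derivatives.
#' @export
model_rhs <- function(model) {
  force(model)
  function(x) {
    th <- eval_basis(model$lib, matrix(x, nrow = 1))
    as.numeric(known_eval(model$known, x) + th %*% model$coefs)
  }
}

#' Term table of a model
#'
#' One row per nonzero term: equation index, canonical label, coefficient,
#' sign, and whether the term is fixed (from the known part) or learned.
#'
#' @param model a `sindy_model`.
#' @return data frame with columns `eq`, `label`, `coef`, `sign`, `fixed`.
#' @export
model_terms <- function(model) {
  stopifnot(inherits(model, "sindy_model"))
  learned <- which(model$coefs != 0, arr.ind = TRUE)
  lt <- data.frame(eq = integer(), label = character(), coef = numeric())
  if (nrow(learned))
    lt <- data.frame(eq = learned[, 2], label = model$lib$labels[learned[, 1]],
                     coef = model$coefs[learned])
  kt <- model$known$terms[, c("eq", "label", "coef")]
  # a learned term on the same label as a known one merges (net coefficient)
  all_t <- rbind(kt, lt)
  if (!nrow(all_t))
    return(data.frame(eq = integer(), label = character(), coef = numeric(),
                      sign = numeric(), fixed = logical()))
  agg <- stats::aggregate(coef ~ eq + label, data = all_t, FUN = sum)
  fixed_lab <- paste(kt$eq, kt$label)
  learned_lab <- paste(lt$eq, lt$label)
  agg$fixed <- paste(agg$eq, agg$label) %in% fixed_lab &
    !(paste(agg$eq, agg$label) %in% learned_lab)
  agg <- agg[agg$coef != 0, , drop = FALSE]
  agg$sign <- sign(agg$coef)
  agg[order(agg$eq, !agg$fixed, agg$label),
      c("eq", "label", "coef", "sign", "fixed")]
}

#' Number of learned (estimated) coefficients
#' @param model a `sindy_model`.
#' @return integer count of nonzero entries of the learned matrix; known
#'   terms are free and do not count.
#' @export
n_learned <- function(model) sum(model$coefs != 0)

#' @export
print.sindy_model <- function(x, digits = 3, ...) {
  cat("<sindy_model> d =", x$d, " library:", x$lib$name, "\n")
  cat(format_equations(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Render model equations as text
#'
#' Known (fixed) terms are marked with square brackets to distinguish them
#' from learned terms.
#'
#' @param model a `sindy_model`.
#' @param digits significant digits for coefficients.
#' @return character vector, one equation per element.
#' @export
format_equations <- function(model, digits = 3) {
  tt <- model_terms(model)
  vapply(seq_len(model$d), function(i) {
    rows <- tt[tt$eq == i, , drop = FALSE]
    if (!nrow(rows)) return(paste0("x", i, "' = 0"))
    parts <- vapply(seq_len(nrow(rows)), function(r) {
      co <- signif(rows$coef[r], digits)
      lab <- rows$label[r]
      term <- if (lab == "1") format(abs(co))
              else paste0(format(abs(co)), "*", lab)
      if (rows$fixed[r]) term <- paste0("[", term, "]")
      paste0(if (co < 0) " - " else " + ", term)
    }, character(1))
    eq <- paste0("x", i, "' =", paste(parts, collapse = ""))
    sub("= \\+ ", "= ", eq)
  }, character(1))
}

#' Render a discovered model as JSON
#'
#' Per-equation list of `{label, coefficient, fixed}` terms, mirroring the
#' plain-text rendering of [format_equations()].
#'
#' @param model a `sindy_model`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return a JSON string (invisibly, when writing to a file).
#' @export
model_json <- function(model, path = NULL) {
  tt <- model_terms(model)
  eqs <- lapply(seq_len(model$d), function(i) {
    rows <- tt[tt$eq == i, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(r)
      list(label = rows$label[r], coefficient = rows$coef[r],
           fixed = rows$fixed[r]))
  })
  names(eqs) <- paste0("x", seq_len(model$d))
  out <- list(library = model$lib$name, equations = eqs)
  if (is.null(path))
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Coefficients of a discovered model
#' @param object a `sindy_model`.
#' @param ... unused.
#' @return the learned `m x d` coefficient matrix.
#' @export
coef.sindy_model <- function(object, ...) object$coefs

#' Simulate a discovered model
#'
#' @param object a `sindy_model`.
#' @param nsim unused (one deterministic trajectory).
#' @param seed unused.
#' @param x0 initial state.
#' @param grid a [sim_grid()].
#' @param rtol,atol solver tolerances.
#' @param ... unused.
#' @return a [trajectory()], or `NULL` if integration fails (unstable
#'   candidate models are common and callers treat failure as infinite
#'   error).
#' @export
simulate.sindy_model <- function(object, nsim = 1, seed = NULL, x0, grid,
                                 rtol = 1e-6, atol = 1e-6, ...) {
  rhs <- model_rhs(object)
  times <- grid_times(grid)
  if (length(times) == 1L)
    return(trajectory(times, matrix(x0, nrow = 1)))
  fn <- function(t, y, parms) list(rhs(y))
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(y = x0, times = times, func = fn,
                                    parms = NULL, rtol = rtol, atol = atol,
                                    maxsteps = 5000)),
    error = function(e) NULL)
  if (is.null(out) || nrow(out) < length(times) ||
      any(!is.finite(out[, -1])) || max(abs(out[, -1])) > 1e6)
    return(NULL)
  trajectory(out[, 1], out[, -1, drop = FALSE])
}
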