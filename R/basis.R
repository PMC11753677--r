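#' Build a named basis-function library
#'
#' Constructs the ordered candidate-function library Theta(x) used by the
#' sparse-regression stage. Recognized names:
#' \describe{
#'   \item{`poly_max_2`}{all monomials of degree <= 2, constant included.}
#'   \item{`poly_1_2`}{monomials of degrees 1 and 2 (no constant).}
#'   \item{`poly_2_3`}{monomials of degrees 2 and 3 only.}
#'   \item{`hill_<n>`}{repression Hill functions `1/(1+xi^n)` of a single
#'     order `n`, one per species.}
#'   \item{`hill_max_3`}{Hill functions of all orders 1..3.}
#'   \item{`hill_max_3_linear`}{Hill orders 1..3 plus the linear terms
#'     `xi` (12 functions for d = 3).}
#'   \item{`hill_<n>_poly_1`}{Hill order `n` plus linear terms.}
#'   \item{`hill_<n>_poly_xy`}{Hill order `n` plus linear terms and pairwise
#'     interactions `xi*xj`.}
#'   \item{`hill_<n>_poly_1_2`}{Hill order `n` plus monomials of degrees
#'     1 and 2.}
#'   \item{`hill_max_3_poly_1`}{Hill orders 1..3 plus linear terms.}
#' }
#' Function order is deterministic: Hill terms (by order, then species)
#' first, then monomials by total degree then lexicographically.
#'
#' @param name library identifier.
#' @param d state dimension.
#' @return object of class `basis_library`: list with `name`, `d`, `labels`,
#'   `funcs` (each a function of an `n x d` state matrix returning a column)
#'   and `size`.
#' @export
build_library <- function(name, d) {
  stopifnot(is.character(name), length(name) == 1L, d >= 1)
  hill_part <- function(orders) {
    labs <- c(); funs <- list()
    for (n in orders) for (i in seq_len(d)) {
      labs <- c(labs, hill_label(i, n))
      funs <- c(funs, local({
        i0 <- i; n0 <- n
        list(function(X) 1 / (1 + X[, i0]^n0))
      }))
    }
    list(labels = labs, funcs = funs)
  }
  poly_part <- function(degrees, include_const = FALSE) {
    ex <- monomial_exponents(d, degrees)
    labs <- vapply(ex, monomial_label, character(1))
    funs <- lapply(ex, function(e) {
      force(e)
      function(X) {
        v <- rep(1, nrow(X))
        for (i in which(e > 0)) v <- v * X[, i]^e[i]
        v
      }
    })
    if (include_const) {
      labs <- c("1", labs)
      funs <- c(list(function(X) rep(1, nrow(X))), funs)
    }
    list(labels = labs, funcs = funs)
  }
  parts <-
    if (name == "poly_max_2") list(poly_part(1:2, include_const = TRUE))
    else if (name == "poly_1_2") list(poly_part(1:2))
    else if (name == "poly_2_3") list(poly_part(2:3))
    else if (grepl("^hill_max_3_linear$", name))
      list(hill_part(1:3), poly_part(1))
    else if (grepl("^hill_max_3_poly_1$", name))
      list(hill_part(1:3), poly_part(1))
    else if (grepl("^hill_max_3$", name)) list(hill_part(1:3))
    else if (grepl("^hill_[0-9]+_poly_1_2$", name))
      list(hill_part(hill_order(name)), poly_part(1:2))
    else if (grepl("^hill_[0-9]+_poly_xy$", name))
      list(hill_part(hill_order(name)), poly_part(1),
           interaction_part(d))
    else if (grepl("^hill_[0-9]+_poly_1$", name))
      list(hill_part(hill_order(name)), poly_part(1))
    else if (grepl("^hill_[0-9]+$", name)) list(hill_part(hill_order(name)))
    else stop("unknown basis library name: ", name)
  labels <- unlist(lapply(parts, `[[`, "labels"))
  funcs <- unlist(lapply(parts, `[[`, "funcs"), recursive = FALSE)
  if (anyDuplicated(labels)) stop("internal: duplicate basis labels")
  structure(list(name = name, d = as.integer(d), labels = labels,
                 funcs = funcs, size = length(labels)),
            class = "basis_library")
}

hill_order <- function(name) as.integer(sub("^hill_([0-9]+).*$", "\\1", name))

# pure pairwise interactions xi*xj, i < j
interaction_part <- function(d) {
  labs <- c(); funs <- list()
  if (d >= 2) for (i in 1:(d - 1)) for (j in (i + 1):d) {
    labs <- c(labs, paste0("x", i, "*x", j))
    funs <- c(funs, local({
      i0 <- i; j0 <- j
      list(function(X) X[, i0] * X[, j0])
    }))
  }
  list(labels = labs, funcs = funs)
}

# exponent vectors of all monomials with total degree in `degrees`,
# ordered by degree then lexicographically (x1 before x2, higher power first)
monomial_exponents <- function(d, degrees) {
  res <- list()
  gen <- function(e, i, rem) {
    if (i > d) {
      if (rem == 0) res[[length(res) + 1L]] <<- e
      return(invisible())
    }
    for (k in rem:0) {
      e[i] <- k
      gen(e, i + 1L, rem - k)
    }
  }
  for (deg in sort(degrees)) gen(integer(d), 1L, deg)
  res
}

monomial_label <- function(e) {
  parts <- vapply(which(e > 0), function(i)
    if (e[i] == 1) paste0("x", i) else paste0("x", i, "^", e[i]),
    character(1))
  paste(parts, collapse = "*")
}

#' Evaluate a basis library on states
#'
#' @param lib a [build_library()] object.
#' @param X numeric matrix of states (`n x d`) or a single state vector.
#' @return `n x m` matrix with one column per basis function, labelled.
#' @export
eval_basis <- function(lib, X) {
  stopifnot(inherits(lib, "basis_library"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == lib$d)
  out <- vapply(lib$funcs, function(f) f(X), numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1)
  colnames(out) <- lib$labels
  out
}

#' @export
print.basis_library <- function(x, ...) {
  cat("<basis_library> ", x$name, " (d = ", x$d, ", ", x$size,
      " functions)\n  ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
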