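#' Matrix-free linear operators
#'
#' A `linop` bundles an `apply` function, an `adjoint` function and the
#' operator shape `(m, n)`.  All solvers in this package interact with the
#' forward map only through this contract, so dense matrices, sparse
#' matrices and matrix-free maps are interchangeable.
#'
#' @param apply function taking a length-`n` numeric vector, returning length `m`.
#' @param adjoint function taking a length-`m` numeric vector, returning length `n`.
#' @param m,n operator dimensions.
#' @param desc short description string.
#' @return an object of class `linop`.
#' @export
linop <- function(apply, adjoint, m, n, desc = "linear operator") {
  stopifnot(is.function(apply), is.function(adjoint), m >= 1, n >= 1)
  structure(list(apply = apply, adjoint = adjoint,
                 m = as.integer(m), n = as.integer(n), desc = desc),
            class = "linop")
}

#' @export
print.linop <- function(x, ...) {
  cat(sprintf("<linop %d x %d: %s>\n", x$m, x$n, x$desc))
  invisible(x)
}

#' Wrap a (dense or sparse) matrix as a linear operator
#'
#' @param A a base matrix or any `Matrix` class.
#' @param desc description string.
#' @return a `linop`.
#' @export
linop_from_matrix <- function(A, desc = "matrix operator") {
  At <- Matrix::t(A)
  linop(apply   = function(x) as.numeric(A %*% x),
        adjoint = function(y) as.numeric(At %*% y),
        m = nrow(A), n = ncol(A), desc = desc)
}

#' Identity operator
#' @param n dimension.
#' @return a `linop`.
#' @export
linop_identity <- function(n) {
  linop(function(x) x, function(y) y, n, n, "identity")
}

#' Compose two linear operators
#'
#' Returns the operator `outer %*% inner`; the adjoint is the reversed
#' adjoint chain.  Used, e.g., to chain undersampling after blurring.
#'
#' @param outer,inner `linop` objects with `inner$m == outer$n`.
#' @return a `linop` of shape `outer$m` x `inner$n`.
#' @export
compose_operators <- function(outer, inner) {
  stopifnot(inherits(outer, "linop"), inherits(inner, "linop"))
  if (inner$m != outer$n)
    stop("shape mismatch in composition: inner is ", inner$m, " x ", inner$n,
         ", outer is ", outer$m, " x ", outer$n)
  linop(apply   = function(x) outer$apply(inner$apply(x)),
        adjoint = function(y) inner$adjoint(outer$adjoint(y)),
        m = outer$m, n = inner$n,
        desc = paste0(outer$desc, " o ", inner$desc))
}

#' Materialize a linear operator as a dense matrix
#'
#' Applies the operator to every canonical basis vector; intended for
#' small-scale oracle checks only.
#'
#' @param op a `linop`.
#' @return an `m` x `n` base matrix.
#' @export
as_dense_matrix <- function(op) {
  stopifnot(inherits(op, "linop"))
  vapply(seq_len(op$n), function(j) {
    e <- numeric(op$n); e[j] <- 1
    op$apply(e)
  }, numeric(op$m))
}
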