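#' Discrete gradient operators for square images
#'
#' Images of side `N` are stored as length `n = N^2` vectors obtained by
#' stacking the columns of the `N x N` array (column-major `vec`
#' convention; `matrix(x, N, N)` inverts it).  The scaled first-difference
#' operator
#' \deqn{D_{1d} \in R^{(N-1) \times N}, \quad [D_{1d}]_{j,j} = 1,\
#'   [D_{1d}]_{j,j+1} = -1,}
#' induces the stacked 2D gradient
#' \deqn{D_{2d} = [D_v; D_h] = [I \otimes D_{1d};\; D_{1d} \otimes I]
#'   \in R^{2\tilde n \times n}, \quad \tilde n = N(N-1),}
#' whose null space is spanned by the constant image.  Kronecker products
#' are never materialized: applications use the reshape identity
#' `(A %x% B) x = vec(B X t(A))`.
#'
#' @name gradients
NULL

#' First-difference matrix
#'
#' @param N image side, `N >= 2`.
#' @return sparse `(N-1) x N` matrix with rows `(…, 1, -1, …)`.
#' @export
first_difference_matrix <- function(N) {
  if (N < 2) stop("N must be at least 2")
  j <- seq_len(N - 1)
  Matrix::sparseMatrix(i = c(j, j), j = c(j, j + 1),
                       x = rep(c(1, -1), each = N - 1),
                       dims = c(N - 1, N))
}

#' Stacked 2D gradient matrix (sparse)
#'
#' Explicit `2*N*(N-1) x N^2` sparse matrix `[I %x% D1d; D1d %x% I]`.
#' Mostly useful for oracle checks and MatrixMarket export; the solvers use
#' the matrix-free [apply_gradient()].
#'
#' @param N image side.
#' @return a sparse `Matrix`.
#' @export
gradient_matrix_2d <- function(N) {
  D1 <- first_difference_matrix(N)
  I  <- Matrix::Diagonal(N)
  rbind(I %x% D1, D1 %x% I)
}

#' Apply the 2D gradient and its adjoint
#'
#' `apply_gradient` maps an image vector to the stacked gradient
#' `[vertical; horizontal]` (each block of length `N*(N-1)`): vertical =
#' differences down each column, horizontal = differences across each row.
#' `apply_gradient_adjoint` is the exact transpose.
#'
#' @param x image vector of length `N^2`.
#' @param g stacked gradient vector of length `2*N*(N-1)`.
#' @param N image side.
#' @return numeric vector (gradient of length `2*N*(N-1)`, or image of
#'   length `N^2` for the adjoint).
#' @export
apply_gradient <- function(x, N) {
  stopifnot(length(x) == N * N)
  X  <- matrix(x, N, N)
  gv <- X[seq_len(N - 1), , drop = FALSE] - X[2:N, , drop = FALSE]
  gh <- X[, seq_len(N - 1), drop = FALSE] - X[, 2:N, drop = FALSE]
  c(as.vector(gv), as.vector(gh))
}

#' @rdname apply_gradient
#' @export
apply_gradient_adjoint <- function(g, N) {
  nt <- N * (N - 1)
  if (length(g) != 2 * nt) stop("gradient vector has wrong length")
  Gv <- matrix(g[seq_len(nt)], N - 1, N)
  Gh <- matrix(g[nt + seq_len(nt)], N, N - 1)
  zr <- matrix(0, 1, N)
  zc <- matrix(0, N, 1)
  Yv <- rbind(Gv, zr) - rbind(zr, Gv)
  Yh <- cbind(Gh, zc) - cbind(zc, Gh)
  as.vector(Yv + Yh)
}

#' Spectral factors of the 2D gradient
#'
#' Builds the pieces of the Kronecker-structured SVD of `D2d`: the dense
#' SVD of the 1D operator `D1d = U1 S V1'`, the `N x N` array of paired
#' singular values \eqn{d_{a,b} = \sqrt{\sigma_a^2 + \sigma_b^2}} (exactly
#' one of which — the constant mode — is zero), and the Givens rotation
#' coefficients that pair the two entries each right-basis mode carries in
#' the stacked block structure.  The zero mode is identified analytically
#' (the pair of zero 1D singular values at index `N`), never by
#' thresholding.  Cost is polynomial in `N`; no `n x n` matrix is formed.
#'
#' @param N image side, `N >= 2`.
#' @return an object of class `spectral_factors` with fields `N`, `sv_1d`
#'   (the `N-1` positive 1D singular values), `U1`, `V1` (orthonormal 1D
#'   bases, `V1` completed with the constant null vector), `paired`
#'   (`N x N` paired-value array indexed `[vertical mode, horizontal
#'   mode]`), and Givens coefficients `cos_v`, `cos_h` with
#'   `cos_v^2 + cos_h^2 = 1` off the zero mode.
#' @export
build_spectral_factors <- function(N) {
  if (N < 2) stop("N must be at least 2")
  D1 <- as.matrix(first_difference_matrix(N))
  sv <- svd(D1, nu = N - 1, nv = N)
  sig <- c(sv$d, 0)                     # analytic zero mode at index N
  D  <- sqrt(outer(sig^2, sig^2, `+`)) # D[b, a] pairs sigma_b (vert), sigma_a (horz)
  cv <- matrix(0, N, N)
  ch <- matrix(0, N, N)
  nz <- D > 0
  cv[nz] <- outer(sig, rep(1, N))[nz] / D[nz]
  ch[nz] <- outer(rep(1, N), sig)[nz] / D[nz]
  structure(list(N = N, sv_1d = sv$d, U1 = sv$u, V1 = sv$v,
                 paired = D, cos_v = cv, cos_h = ch),
            class = "spectral_factors")
}

#' @export
print.spectral_factors <- function(x, ...) {
  cat(sprintf("<spectral_factors N=%d: %d paired values, 1 zero mode>\n",
              x$N, x$N^2))
  invisible(x)
}

#' Pseudoinverse of the 2D gradient and its adjoint
#'
#' Applies the Moore-Penrose pseudoinverse of `D2d` (and its transpose)
#' through the Kronecker-structured SVD in `O(n^{3/2})` flops: transform to
#' the 1D singular bases, solve the 2x1 least-squares problem each paired
#' mode decouples into, transform back.  The constant zero mode is
#' annihilated, so `apply_gradient_pinv(apply_gradient(x)) = x - mean(x)`.
#'
#' @param g stacked gradient vector of length `2*N*(N-1)`.
#' @param x image vector of length `N^2`.
#' @param sf factors from [build_spectral_factors()].
#' @return image vector (pinv) or stacked gradient vector (adjoint).
#' @export
apply_gradient_pinv <- function(g, sf) {
  N  <- sf$N
  nt <- N * (N - 1)
  if (length(g) != 2 * nt) stop("gradient vector has wrong length")
  Gv <- matrix(g[seq_len(nt)], N - 1, N)
  Gh <- matrix(g[nt + seq_len(nt)], N, N - 1)
  Cv <- rbind(crossprod(sf$U1, Gv) %*% sf$V1, rep(0, N))   # pad zero row N
  Ch <- cbind(crossprod(sf$V1, Gh) %*% sf$U1, rep(0, N))   # pad zero col N
  M  <- matrix(0, N, N)
  nz <- sf$paired > 0
  M[nz] <- (sf$cos_v[nz] * Cv[nz] + sf$cos_h[nz] * Ch[nz]) / sf$paired[nz]
  as.vector(sf$V1 %*% M %*% t(sf$V1))
}

#' @rdname apply_gradient_pinv
#' @export
apply_gradient_pinv_adjoint <- function(x, sf) {
  N <- sf$N
  if (length(x) != N * N) stop("image vector has wrong length")
  M  <- crossprod(sf$V1, matrix(x, N, N)) %*% sf$V1
  Cv <- matrix(0, N, N)
  Ch <- matrix(0, N, N)
  nz <- sf$paired > 0
  Cv[nz] <- sf$cos_v[nz] * M[nz] / sf$paired[nz]
  Ch[nz] <- sf$cos_h[nz] * M[nz] / sf$paired[nz]
  gv <- sf$U1 %*% Cv[seq_len(N - 1), , drop = FALSE] %*% t(sf$V1)
  gh <- sf$V1 %*% Ch[, seq_len(N - 1), drop = FALSE] %*% t(sf$U1)
  c(as.vector(gv), as.vector(gh))
}

#' Orthonormal basis of the gradient null space
#'
#' The null space of `D2d` (and of any positively weighted `W D2d`) is
#' spanned by the constant image; its unit representative has entries
#' `n^{-1/2} = 1/N`.
#'
#' @param N image side, `N >= 2`.
#' @return image vector with constant entries `1/N` and unit 2-norm.
#' @export
nullspace_basis <- function(N) {
  if (N < 2) stop("N must be at least 2")
  rep(1 / N, N * N)
}

#' Export a gradient matrix in MatrixMarket coordinate format
#'
#' @param N image side.
#' @param file output path.
#' @param which `"2d"` (stacked 2D gradient) or `"1d"` (first differences).
#' @return the file path, invisibly.
#' @export
export_gradient_mtx <- function(N, file, which = c("2d", "1d")) {
  which <- match.arg(which)
  M <- if (which == "2d") gradient_matrix_2d(N) else first_difference_matrix(N)
  Matrix::writeMM(methods::as(M, "CsparseMatrix"), file)
  invisible(file)
}
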