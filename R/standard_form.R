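#' Standard-form transformation data
#'
#' The regularizer `W D2d` has the constant image in its null space, so
#' general-form Tikhonov is transformed to standard form by splitting the
#' solution as `x = x_bar + x0`, where `x0 = K (A K)^+ b` is the
#' null-space component (`K = n^{-1/2} 1` is the unit constant image) and
#' `x_bar` lies in the range of the A-weighted pseudoinverse
#' `(W D2d)_A^+ = E (W D2d)^+` with oblique projector
#' `E = I - K (A K)^+ A`.  All of this is independent of the weights and
#' is built once, ahead of the iterations.
#'
#' @param A forward operator (`linop`).
#' @param b data vector of length `A$m`.
#' @param N image side (`A$n = N^2`).
#' @return an object of class `standard_form` with fields `x0`, `v = A K`,
#'   `Atv = A' v`, `vnorm2`, `bbar = b - A x0`, `beta = ||bbar||`, `N`.
#' @export
build_standard_form <- function(A, b, N) {
  stopifnot(inherits(A, "linop"), length(b) == A$m, A$n == N * N)
  K <- nullspace_basis(N)
  v <- A$apply(K)
  vnorm2 <- sum(v^2)
  # degenerate if A annihilates constants; scale tolerance by a cheap
  # norm estimate of A (norm of A K is itself the natural scale here)
  scale_est <- sqrt(sum(A$apply(rnorm_unit_seeded(A$n))^2))
  if (sqrt(vnorm2) <= 1e-12 * max(scale_est, 1))
    stop("operator (numerically) annihilates constant images; the ",
         "standard-form transformation assumes null(A) excludes constants")
  x0 <- (sum(v * b) / vnorm2) * K
  bbar <- b - A$apply(x0)
  structure(list(x0 = x0, v = v, Atv = A$adjoint(v), vnorm2 = vnorm2,
                 bbar = bbar, beta = sqrt(sum(bbar^2)), N = N),
            class = "standard_form")
}

# deterministic pseudo-random unit vector used only for the degeneracy
# scale estimate (must not consume the user's RNG stream)
rnorm_unit_seeded <- function(n) {
  u <- sin(seq_len(n) * 12.9898) * 43758.5453
  u <- u - floor(u)
  u <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  u / sqrt(sum(u^2))
}

#' Oblique projector of the standard-form split
#'
#' `apply_E` computes `E y = y - K (A K)^+ (A y)`; its adjoint uses the
#' cached vector `A' v`.  `E` projects onto the complement of the constant
#' image along the preimage of `span(A K)`, so `E K = 0` and `E E = E`.
#'
#' @param sf a [build_standard_form()] object.
#' @param A the forward operator the transformation was built for.
#' @param y image vector of length `N^2`.
#' @return image vector.
#' @export
apply_E <- function(sf, A, y) {
  coef <- sum(sf$v * A$apply(y)) / sf$vnorm2
  y - coef / sf$N * rep(1, length(y))
}

#' @rdname apply_E
#' @export
apply_E_adjoint <- function(sf, y) {
  y - (sum(y) / (sf$N * sf$vnorm2)) * sf$Atv
}

#' Dense pseudoinverse of the weighted gradient (oracle mode)
#'
#' Forms `pinv(W D2d)` densely via the SVD.  Intended for small problems
#' (guarded at `N <= 64`) where the exact pseudoinverse variant of the
#' solver, or an oracle check, is wanted.
#'
#' @param wstate a `weight_state`.
#' @param N image side.
#' @return dense `N^2 x (2 N (N-1))` matrix.
#' @export
dense_weighted_pinv <- function(wstate, N) {
  if (N > 64) stop("exact pseudoinverse is limited to N <= 64")
  L <- as.matrix(gradient_matrix_2d(N)) * wstate$w
  sv <- svd(L)
  tol <- max(dim(L)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Apply the (approximate) standard-form preconditioner
#'
#' Computes the symmetric positive-semidefinite map
#' \deqn{v \mapsto E\, L^+ (L^+)^T E^T v,}
#' where, by default, `L^+` is the structured approximation
#' `D2d^+ W^{-1}` of `pinv(W D2d)` (the pseudoinverse of `W D2d` in the
#' `W^{-2}` norm; exact when the weights are scalar).  This is the
#' expansion map of the flexible Golub-Kahan solver: each new basis
#' vector is preconditioned with the current weights.
#'
#' @param sf a [build_standard_form()] object.
#' @param A forward operator.
#' @param sfac spectral factors from [build_spectral_factors()].
#' @param wstate current `weight_state`.
#' @param v_in image-space vector of length `N^2`.
#' @param include_E include the `E`/`E'` wrappers (default `TRUE`,
#'   preserving the null-space split; disable to precondition with the
#'   plain pseudoinverse product).
#' @param exact_pinv use the dense pseudoinverse of `W D2d` instead of the
#'   structured approximation (test/oracle mode, `N <= 64`).
#' @return image-space vector of length `N^2`.
#' @export
apply_preconditioner <- function(sf, A, sfac, wstate, v_in,
                                 include_E = TRUE, exact_pinv = FALSE) {
  y <- if (include_E) apply_E_adjoint(sf, v_in) else v_in
  if (exact_pinv) {
    Lp <- dense_weighted_pinv(wstate, sfac$N)
    z <- as.numeric(Lp %*% (t(Lp) %*% y))
  } else {
    g <- apply_gradient_pinv_adjoint(y, sfac)
    g <- apply_inverse_weights(wstate, apply_inverse_weights(wstate, g))
    z <- apply_gradient_pinv(g, sfac)
  }
  if (include_E) apply_E(sf, A, z) else z
}
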