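#' Edge-enhancing weight configuration
#'
#' Configures the diagonal weighting scheme used to express
#' total-variation-type regularizers as iteratively reweighted 2-norms,
#' \eqn{\Omega(x) \approx \| W(D_{2d} x)\, D_{2d} x \|_2^2}.
#'
#' @param kind one of `"tv"` (isotropic total variation: both gradient
#'   blocks share the weight of the pointwise gradient magnitude), `"atv"`
#'   (anisotropic: componentwise weights per block), `"diag"` (cumulative
#'   heuristic edge-enhancing weights carried across iterations; not
#'   associated with a variational objective) or `"none"` (all-ones,
#'   i.e., plain gradient penalty).
#' @param q norm exponent; only `q = 1` is supported (the regularizers in
#'   scope are l1-type) and the argument is validated accordingly.
#' @param tau smoothing parameter `> 0` preventing division by zero in the
#'   weights; default `1e-10`.
#' @param a exponent of the cumulative `"diag"` damping term, `> 0`;
#'   larger values penalize presumed-smooth regions more strongly.
#' @return an object of class `weight_config`.
#' @export
weight_config <- function(kind = c("tv", "atv", "diag", "none"),
                          q = 1, tau = 1e-10, a = 1) {
  kind <- match.arg(kind)
  if (!isTRUE(all.equal(q, 1))) stop("only q = 1 is supported")
  if (tau <= 0) stop("tau must be positive")
  if (a <= 0) stop("a must be positive")
  structure(list(kind = kind, q = 1, tau = tau, a = a),
            class = "weight_config")
}

#' Smoothed inverse-magnitude factor
#'
#' Evaluates \eqn{f_{q,\tau}(v) = (\|v\|_2^2 + \tau^2)^{(q-2)/4}}, the
#' smoothed factor whose square turns `|.|^q` into a weighted square:
#' for `q = 1`, `f^2 * |v|^2` approximates `|v|` away from zero.
#'
#' @param v2 squared magnitude(s) `||v||^2` (vectorized).
#' @param q norm exponent.
#' @param tau smoothing parameter `> 0`.
#' @return positive numeric vector.
#' @export
smooth_magnitude <- function(v2, q = 1, tau = 1e-10) {
  if (tau <= 0) stop("tau must be positive")
  (v2 + tau^2)^((q - 2) / 4)
}

#' Compute diagonal edge-enhancing weights
#'
#' Builds the `weight_state` for a gradient vector `g = D2d x`:
#' \itemize{
#'   \item `tv`: both blocks equal \eqn{f_{1,\tau}} of the pointwise
#'     gradient magnitude \eqn{\sqrt{(D_v x)_j^2 + (D_h x)_j^2}};
#'   \item `atv`: componentwise \eqn{f_{1,\tau}} of each block;
#'   \item `diag`: cumulative update
#'     \eqn{w_k = [(1 - |w_{k-1} g| / \|w_{k-1} g\|_\infty)^a + \tau]
#'     \circ w_{k-1}}, seeded from `prev` (identity when `prev` is `NULL`);
#'     if \eqn{\|w_{k-1} g\|_\infty = 0} the previous state is returned
#'     unchanged (degenerate-gradient guard);
#'   \item `none`: all ones.
#' }
#'
#' @param cfg a [weight_config()].
#' @param g stacked gradient vector of length `2*N*(N-1)`.
#' @param prev previous `weight_state` (required context only for
#'   `"diag"`, where it defaults to the identity).
#' @return an object of class `weight_state` with positive diagonal `w`.
#' @export
compute_weights <- function(cfg, g, prev = NULL) {
  stopifnot(inherits(cfg, "weight_config"))
  nt2 <- length(g)
  if (nt2 %% 2 != 0) stop("gradient vector must stack two equal blocks")
  nt <- nt2 / 2
  w <- switch(cfg$kind,
    none = rep(1, nt2),
    tv = {
      m2 <- g[seq_len(nt)]^2 + g[nt + seq_len(nt)]^2
      rep(smooth_magnitude(m2, 1, cfg$tau), 2)
    },
    atv = smooth_magnitude(g^2, 1, cfg$tau),
    diag = {
      w_prev <- if (is.null(prev)) rep(1, nt2) else prev$w
      if (length(w_prev) != nt2) stop("previous weight state has wrong length")
      wg <- abs(w_prev * g)
      mx <- max(wg)
      if (mx == 0) w_prev else ((1 - wg / mx)^cfg$a + cfg$tau) * w_prev
    })
  structure(list(w = w, kind = cfg$kind, cfg = cfg), class = "weight_state")
}

#' @export
print.weight_state <- function(x, ...) {
  cat(sprintf("<weight_state kind=%s, length %d, range [%.3g, %.3g]>\n",
              x$kind, length(x$w), min(x$w), max(x$w)))
  invisible(x)
}

#' Apply the inverse of the weighting matrix
#'
#' For `tv`, `atv` and `none` weights the inverse is the exact entrywise
#' reciprocal.  For the cumulative `diag` weights the exact reciprocal is
#' known to behave poorly (the weights are products over all previous
#' iterations), so the first-order approximation around zero,
#' \eqn{W^{-1} \approx \mathrm{diag}(1 + w)}, is used instead.
#'
#' @param state a `weight_state`.
#' @param g stacked gradient vector.
#' @return numeric vector of the same length as `g`.
#' @export
apply_inverse_weights <- function(state, g) {
  stopifnot(inherits(state, "weight_state"), length(g) == length(state$w))
  if (state$kind == "diag") g * (1 + state$w) else g / state$w
}
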