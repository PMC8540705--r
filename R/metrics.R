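#' Relative restoration error
#'
#' `||x - x_true||_2 / ||x_true||_2`.
#'
#' @param x reconstruction vector.
#' @param x_true ground truth (nonzero).
#' @return nonnegative scalar.
#' @export
rre <- function(x, x_true) {
  tn <- sqrt(sum(x_true^2))
  if (tn == 0) stop("ground truth has zero norm")
  sqrt(sum((x - x_true)^2)) / tn
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window (standard constants: 11x11
#' window, sigma 1.5, K1 = 0.01, K2 = 0.03); the dynamic range is taken
#' from the ground truth.  Local statistics are computed on the interior
#' ('valid') region, as in the original reference implementation.
#'
#' @param X reconstruction (matrix, or image vector).
#' @param X_true ground truth of the same shape.
#' @param window window side (odd; shrunk automatically for tiny images).
#' @param sigma Gaussian window width.
#' @param K1,K2 stabilization constants.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(X, X_true, window = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (is.null(dim(X))) {
    N <- as.integer(round(sqrt(length(X))))
    X <- matrix(X, N, N); X_true <- matrix(X_true, N, N)
  }
  if (!all(dim(X) == dim(X_true))) stop("images must have the same shape")
  N <- nrow(X)
  if (window > N) window <- if (N %% 2 == 1) N else N - 1
  half <- (window - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  g <- g / sum(g)
  # valid-region separable filtering matrix: (N - window + 1) x N
  Tm <- matrix(0, N - window + 1, N)
  for (j in seq_len(window)) Tm[cbind(seq_len(nrow(Tm)), seq_len(nrow(Tm)) + j - 1)] <-
      Tm[cbind(seq_len(nrow(Tm)), seq_len(nrow(Tm)) + j - 1)] + g[j]
  filt <- function(M) Tm %*% M %*% t(Tm)
  L <- diff(range(X_true))
  if (L == 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- filt(X); mu2 <- filt(X_true)
  s11 <- filt(X * X) - mu1^2
  s22 <- filt(X_true * X_true) - mu2^2
  s12 <- filt(X * X_true) - mu1 * mu2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
}

#' Total-variation values of an image
#'
#' `tv_value` is the unsmoothed isotropic total variation
#' \eqn{\sum_j \sqrt{(D_v x)_j^2 + (D_h x)_j^2}}; `atv_value` the
#' anisotropic variant \eqn{\|[D_v x; D_h x]\|_1}.  Neither is invariant
#' under image flips or quarter rotations in general (the gradient
#' stencils are one-sided).
#'
#' @param x image vector.
#' @param N image side (inferred from `length(x)` when omitted).
#' @return nonnegative scalar.
#' @export
tv_value <- function(x, N = as.integer(round(sqrt(length(x))))) {
  g <- apply_gradient(x, N)
  nt <- N * (N - 1)
  sum(sqrt(g[seq_len(nt)]^2 + g[nt + seq_len(nt)]^2))
}

#' @rdname tv_value
#' @export
atv_value <- function(x, N = as.integer(round(sqrt(length(x))))) {
  sum(abs(apply_gradient(x, N)))
}
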