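# Dense oracle utilities shared across the suite.  Everything here is an
# independent construction (explicit Kronecker/stacked matrices, SVD-based
# pseudoinverses) against which the structured implementations are checked.

# dense stacked 2D gradient built from explicit Kronecker products
dense_gradient <- function(N) {
  D1 <- as.matrix(flexgk::first_difference_matrix(N))
  I <- diag(N)
  rbind(kronecker(I, D1), kronecker(D1, I))
}

# SVD-based Moore-Penrose pseudoinverse
dense_pinv <- function(M, tol = NULL) {
  sv <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# a small seeded dense forward operator that does not annihilate constants
random_operator <- function(m, n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(m * n), m, n)
  flexgk::linop_from_matrix(A)
}

# inner-product adjoint-consistency defect for a linop
adjoint_defect <- function(op, seed = 1) {
  set.seed(seed)
  x <- rnorm(op$n); y <- rnorm(op$m)
  abs(sum(op$apply(x) * y) - sum(x * op$adjoint(y))) /
    max(1, sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

# small deblurring fixture reused by the solver tests; below the geometric
# phantom's minimum size a Voronoi phantom stands in
small_deblur <- function(N = 16, sigma = 1.5, seed = 2, noise = 0.01) {
  xt <- if (N >= 16) NULL else flexgk::grains_phantom(N, ncells = 5, seed = seed)
  flexgk::deblur_problem(N, sigma = sigma, noise_level = noise, seed = seed,
                         x_true = xt)
}
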