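#' Forward problems
#'
#' Container pairing a forward operator with (noisy) data, the exact
#' data, the noise realization and an optional ground truth, as produced
#' by the synthetic problem generators.
#'
#' @param A a `linop`.
#' @param b data vector (length `A$m`).
#' @param b_true noiseless data.
#' @param e noise vector (`b = b_true + e`).
#' @param x_true ground-truth image vector, or `NULL`.
#' @param desc description string.
#' @return an object of class `forward_problem`; `noise_norm` holds
#'   `||e||_2` when the noise is known.
#' @export
forward_problem <- function(A, b, b_true = NULL, e = NULL, x_true = NULL,
                            desc = "forward problem") {
  stopifnot(inherits(A, "linop"), length(b) == A$m)
  structure(list(A = A, b = b, b_true = b_true, e = e, x_true = x_true,
                 noise_norm = if (!is.null(e)) sqrt(sum(e^2)) else NULL,
                 N = as.integer(round(sqrt(A$n))), desc = desc),
            class = "forward_problem")
}

#' @export
print.forward_problem <- function(x, ...) {
  cat(sprintf("<forward_problem %d x %d: %s>\n", x$A$m, x$A$n, x$desc))
  invisible(x)
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Piecewise-constant geometric phantom
#'
#' Deterministic test image on `[0,1]` with a rectangle (intensity 1), a
#' disc (0.8) and a right triangle (0.6) on a zero background: a
#' low-total-variation, piecewise-constant scene of simple geometric
#' shapes.  Shape positions scale with `N`; the background covers well
#' over half the pixels.
#'
#' @param N image side, `N >= 16`.
#' @return image vector of length `N^2`.
#' @export
pattern_phantom <- function(N) {
  if (N < 16) stop("the geometric phantom needs N >= 16")
  r <- matrix(seq_len(N), N, N)          # row index (vertical)
  c <- matrix(seq_len(N), N, N, byrow = TRUE)
  X <- matrix(0, N, N)
  X[r >= 0.15 * N & r <= 0.45 * N & c >= 0.10 * N & c <= 0.40 * N] <- 1
  X[(r - 0.68 * N)^2 + (c - 0.30 * N)^2 <= (0.15 * N)^2] <- 0.8
  tri <- r >= 0.55 * N & c >= 0.55 * N & (r - 0.55 * N) + (c - 0.55 * N) <= 0.35 * N
  X[tri] <- 0.6
  as.vector(X)
}

#' Voronoi grains phantom
#'
#' Random Voronoi tessellation with constant per-cell intensities in
#' `[0,1]`, emulating grains in a crystalline material.  Fully seeded:
#' the same `(N, ncells, seed)` always reproduces the same image.
#'
#' @param N image side.
#' @param ncells number of Voronoi cells (`>= 1`).
#' @param seed RNG seed.
#' @return image vector of length `N^2`.
#' @export
grains_phantom <- function(N, ncells = 60, seed = 1) {
  stopifnot(ncells >= 1)
  with_seed(seed, {
    cx <- stats::runif(ncells, 0.5, N + 0.5)
    cy <- stats::runif(ncells, 0.5, N + 0.5)
    val <- stats::runif(ncells)
    r <- matrix(seq_len(N), N, N)
    c <- matrix(seq_len(N), N, N, byrow = TRUE)
    d2 <- outer(as.vector(r), cy, function(a, b) (a - b)^2) +
      outer(as.vector(c), cx, function(a, b) (a - b)^2)
    val[max.col(-d2, ties.method = "first")]
  })
}

# reflect an out-of-range 1-based index back into 1..N (whole-sample
# symmetric boundary: 0 -> 1, -1 -> 2, N+1 -> N, ...)
reflect_index <- function(idx, N) {
  idx <- ((idx - 1) %% (2 * N))
  idx <- ifelse(idx >= N, 2 * N - 1 - idx, idx)
  idx + 1
}

#' Blurring operators
#'
#' Convolution with a normalized point-spread function under reflexive
#' boundary conditions; the adjoint is correlation under the same
#' boundary rule.
#'
#' `kind = "gaussian"` uses a separable Gaussian PSF of width `sigma`
#' (applied matrix-free through 1D blur matrices); `kind = "shake"`
#' rasterizes a seeded 2D random-walk trajectory into a small
#' non-separable kernel, emulating camera-shake blur of mild intensity,
#' and materializes the sparse convolution matrix.
#'
#' @param N image side.
#' @param kind `"gaussian"` or `"shake"`.
#' @param sigma Gaussian standard deviation in pixels (`> 0`); values
#'   well below one pixel make the operator approach the identity.
#' @param trajectory_len number of random-walk steps for `"shake"`.
#' @param seed RNG seed (used by `"shake"` only).
#' @return a `linop` with an extra `psf` field (the normalized kernel).
#' @export
blur_operator <- function(N, kind = c("gaussian", "shake"), sigma = 1,
                          trajectory_len = 30, seed = 1) {
  kind <- match.arg(kind)
  n <- N * N
  if (kind == "gaussian") {
    if (sigma <= 0) stop("sigma must be positive")
    r <- max(1, ceiling(4 * sigma))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- k / sum(k)
    A1 <- matrix(0, N, N)
    for (o in seq(-r, r)) {
      tgt <- reflect_index(seq_len(N) + o, N)
      A1[cbind(seq_len(N), tgt)] <- A1[cbind(seq_len(N), tgt)] + k[o + r + 1]
    }
    op <- linop(
      apply   = function(x) as.vector(A1 %*% matrix(x, N, N) %*% t(A1)),
      adjoint = function(y) as.vector(crossprod(A1, matrix(y, N, N)) %*% A1),
      m = n, n = n,
      desc = sprintf("gaussian blur sigma=%.2g (reflexive BC)", sigma))
    op$psf <- outer(k, k)
    return(op)
  }
  # shake: seeded random-walk PSF
  psf <- with_seed(seed, {
    steps <- matrix(sample(c(-1L, 0L, 1L), 2 * trajectory_len, replace = TRUE),
                    ncol = 2)
    pos <- apply(steps, 2, cumsum)
    pos <- rbind(c(0L, 0L), pos)
    r <- max(abs(pos))
    Km <- matrix(0, 2 * r + 1, 2 * r + 1)
    for (s in seq_len(nrow(pos)))
      Km[pos[s, 1] + r + 1, pos[s, 2] + r + 1] <-
        Km[pos[s, 1] + r + 1, pos[s, 2] + r + 1] + 1
    Km / sum(Km)
  })
  r <- (nrow(psf) - 1) / 2
  nz <- which(psf != 0, arr.ind = TRUE)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  pix_r <- rep(seq_len(N), times = N)
  pix_c <- rep(seq_len(N), each = N)
  for (t in seq_len(nrow(nz))) {
    dr <- nz[t, 1] - r - 1; dc <- nz[t, 2] - r - 1
    tr <- reflect_index(pix_r + dr, N)
    tc <- reflect_index(pix_c + dc, N)
    rows <- c(rows, seq_len(n))
    cols <- c(cols, (tc - 1) * N + tr)
    vals <- c(vals, rep(psf[nz[t, 1], nz[t, 2]], n))
  }
  As <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  op <- linop_from_matrix(As, desc = sprintf("shake blur (%d steps, reflexive BC)",
                                             trajectory_len))
  op$psf <- psf
  op
}

#' Cluster undersampling (inpainting) operator
#'
#' Selection operator retaining a target fraction of the pixels as a
#' union of seeded random discs; the last disc is trimmed
#' (deterministically, given the seed) so the retained count equals
#' `round(retain_fraction * N^2)` exactly.  Each row of the matrix is a
#' canonical unit vector.
#'
#' @param N image side.
#' @param retain_fraction fraction of pixels to keep, in `(0, 1)`.
#' @param cluster_radius disc radius in pixels.
#' @param seed RNG seed.
#' @return a `linop` with an extra `kept` field (sorted retained indices).
#' @export
mask_operator <- function(N, retain_fraction = 0.4, cluster_radius = 3,
                          seed = 1) {
  if (retain_fraction <= 0 || retain_fraction >= 1)
    stop("retain_fraction must be strictly between 0 and 1")
  n <- N * N
  target <- round(retain_fraction * n)
  if (target < 1) stop("retain_fraction infeasible for this image size")
  kept <- with_seed(seed, {
    keep <- logical(n)
    pix_r <- rep(seq_len(N), times = N)
    pix_c <- rep(seq_len(N), each = N)
    while (sum(keep) < target) {
      ctr_r <- stats::runif(1, 1, N)
      ctr_c <- stats::runif(1, 1, N)
      d2 <- (pix_r - ctr_r)^2 + (pix_c - ctr_c)^2
      disc <- which(d2 <= cluster_radius^2 & !keep)
      need <- target - sum(keep)
      if (length(disc) > need)
        disc <- disc[order(d2[disc])][seq_len(need)]   # trim outermost pixels
      keep[disc] <- TRUE
    }
    which(keep)
  })
  linop_sel <- linop(
    apply   = function(x) x[kept],
    adjoint = function(y) { out <- numeric(n); out[kept] <- y; out },
    m = length(kept), n = n,
    desc = sprintf("cluster mask (%.0f%% retained)", 100 * retain_fraction))
  linop_sel$kept <- kept
  linop_sel
}

#' Parallel-beam tomography geometry
#'
#' @param angles projection angles in degrees.
#' @param nrays detector elements per angle (defaults to
#'   `round(sqrt(2) * N)` in [ct_operator()]).
#' @return an object of class `ct_geometry`.
#' @export
ct_geometry <- function(angles, nrays = NULL) {
  structure(list(angles = angles, nrays = nrays), class = "ct_geometry")
}

#' Parallel-beam tomography system matrix (line model)
#'
#' Sparse system matrix for a 2D equidistant parallel X-ray beam: entry
#' `(ray, pixel)` is the intersection length of the ray with the pixel
#' (pixel size 1, image square `[-N/2, N/2]^2`).  For angle `theta`
#' (degrees) the rays travel along `(-sin t, cos t)` — orthogonal to the
#' detector axis `(cos t, sin t)` — with unit detector spacing centered
#' on the image; a fixed offset of `1e-6` pixels guards against rays
#' running exactly along pixel boundaries.  Rows are ordered angle-major:
#' `m = length(angles) * nrays`.
#'
#' @param N image side.
#' @param geometry a [ct_geometry()]; `nrays = NULL` uses
#'   `round(sqrt(2) * N)`.
#' @return a sparse `Matrix` of dimension `m x N^2` (wrap with
#'   [linop_from_matrix()] for the solvers).
#' @export
ct_operator <- function(N, geometry = ct_geometry(seq(0, 179, by = 2))) {
  stopifnot(inherits(geometry, "ct_geometry"))
  nrays <- if (is.null(geometry$nrays)) round(sqrt(2) * N) else geometry$nrays
  angles <- geometry$angles
  n <- N * N
  offs <- seq_len(nrays) - (nrays + 1) / 2 + 1e-6
  lines <- -N / 2 + 0:N
  tri_i <- vector("list", length(angles))
  tri_j <- vector("list", length(angles))
  tri_x <- vector("list", length(angles))
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    dx <- cos(th); dy <- sin(th)        # detector axis
    ux <- -sin(th); uy <- cos(th)       # ray direction
    ox <- offs * dx; oy <- offs * dy    # ray origins
    Tx <- if (abs(ux) > 1e-12) outer(-ox, lines, `+`) / ux else
      matrix(Inf, nrays, N + 1)
    Ty <- if (abs(uy) > 1e-12) outer(-oy, lines, `+`) / uy else
      matrix(Inf, nrays, N + 1)
    Tall <- cbind(Tx, Ty)
    Ts <- t(apply(Tall, 1, sort))       # nrays x (2N+2), Inf sorted last
    K <- ncol(Ts)
    dt <- Ts[, -1, drop = FALSE] - Ts[, -K, drop = FALSE]
    tm <- (Ts[, -1, drop = FALSE] + Ts[, -K, drop = FALSE]) / 2
    px <- ox + tm * ux
    py <- oy + tm * uy
    ic <- floor(px + N / 2) + 1         # column from x
    ir <- floor(py + N / 2) + 1         # row from y
    ok <- is.finite(dt) & dt > 1e-12 &
      ic >= 1 & ic <= N & ir >= 1 & ir <= N
    ray <- matrix(seq_len(nrays), nrays, K - 1)
    tri_i[[a]] <- (a - 1) * nrays + ray[ok]
    tri_j[[a]] <- (ic[ok] - 1) * N + ir[ok]
    tri_x[[a]] <- dt[ok]
  }
  Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j), x = unlist(tri_x),
                       dims = c(length(angles) * nrays, n))
}

#' Additive Gaussian noise at an exact relative level
#'
#' Draws seeded white Gaussian noise and rescales it so that
#' `||e||_2 / ||b_true||_2` equals `level` exactly.
#'
#' @param b_true noiseless data vector.
#' @param level relative noise level `>= 0`.
#' @param seed RNG seed.
#' @return list with elements `b` (noisy data) and `e` (noise).
#' @export
add_noise <- function(b_true, level, seed = 1) {
  stopifnot(level >= 0)
  if (level == 0) return(list(b = b_true, e = numeric(length(b_true))))
  bnorm <- sqrt(sum(b_true^2))
  if (bnorm == 0) stop("cannot scale noise relative to zero data")
  w <- with_seed(seed, stats::rnorm(length(b_true)))
  e <- level * bnorm * w / sqrt(sum(w^2))
  list(b = b_true + e, e = e)
}

#' Synthetic deblurring problem
#'
#' Geometric-pattern phantom corrupted by Gaussian blur and additive
#' Gaussian white noise at an exact relative level.  Blur levels `"mild"`
#' and `"medium"` map to Gaussian widths 1.0 and 2.0 pixels.
#'
#' @param N image side (`>= 16`).
#' @param blur_level `"mild"` or `"medium"`, or bypass with `sigma`.
#' @param sigma Gaussian width; overrides `blur_level` when given.
#' @param noise_level relative noise level (default 0.01).
#' @param seed RNG seed for the noise.
#' @param x_true ground-truth image vector (defaults to the geometric
#'   phantom).
#' @return a `forward_problem`.
#' @export
deblur_problem <- function(N = 32, blur_level = c("mild", "medium"),
                           sigma = NULL, noise_level = 0.01, seed = 1,
                           x_true = NULL) {
  blur_level <- match.arg(blur_level)
  if (is.null(sigma)) sigma <- c(mild = 1, medium = 2)[[blur_level]]
  x <- if (is.null(x_true)) pattern_phantom(N) else x_true
  A <- blur_operator(N, "gaussian", sigma = sigma)
  b_true <- A$apply(x)
  nz <- add_noise(b_true, noise_level, seed)
  forward_problem(A, nz$b, b_true, nz$e, x,
                  desc = sprintf("deblurring %dx%d (sigma=%.2g, noise %.2g)",
                                 N, N, sigma, noise_level))
}

#' Synthetic inpainting-plus-deblurring problem
#'
#' Shake blur followed by cluster undersampling: `A = S A_blur`.
#'
#' @param N image side.
#' @param retain_fraction fraction of pixels retained by the mask.
#' @param trajectory_len shake random-walk length.
#' @param noise_level relative noise level.
#' @param seed RNG seed (blur trajectory, mask and noise draw from
#'   derived seeds).
#' @param x_true ground-truth image vector (defaults to the geometric
#'   phantom).
#' @return a `forward_problem`.
#' @export
inpaint_problem <- function(N = 32, retain_fraction = 0.4,
                            trajectory_len = 20, noise_level = 0.01,
                            seed = 1, x_true = NULL) {
  if (is.null(x_true)) x_true <- pattern_phantom(N)
  Ab <- blur_operator(N, "shake", trajectory_len = trajectory_len, seed = seed)
  S <- mask_operator(N, retain_fraction, seed = seed + 1)
  A <- compose_operators(S, Ab)
  b_true <- A$apply(x_true)
  nz <- add_noise(b_true, noise_level, seed + 2)
  forward_problem(A, nz$b, b_true, nz$e, x_true,
                  desc = sprintf("inpainting+deblurring %dx%d (%.0f%% kept)",
                                 N, N, 100 * retain_fraction))
}

#' Synthetic undersampled tomography problem
#'
#' Voronoi-grains phantom observed through the parallel-beam line-model
#' matrix, with noise at an exact relative level.
#'
#' @param N image side.
#' @param angles projection angles in degrees (default 0 to 179 in steps
#'   of 2).
#' @param ncells Voronoi cell count for the phantom.
#' @param noise_level relative noise level.
#' @param seed RNG seed (phantom and noise draw from derived seeds).
#' @return a `forward_problem`.
#' @export
ct_problem <- function(N = 32, angles = seq(0, 179, by = 2), ncells = 60,
                       noise_level = 0.01, seed = 1) {
  x <- grains_phantom(N, ncells = ncells, seed = seed)
  As <- ct_operator(N, ct_geometry(angles))
  A <- linop_from_matrix(As, desc = sprintf("parallel-beam CT (%d angles)",
                                            length(angles)))
  b_true <- A$apply(x)
  nz <- add_noise(b_true, noise_level, seed + 1)
  forward_problem(A, nz$b, b_true, nz$e, x,
                  desc = sprintf("tomography %dx%d (%d angles)", N, N,
                                 length(angles)))
}
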