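test_that("geometric phantom is deterministic, sparse-valued, mostly background", {
  x <- pattern_phantom(32)
  expect_identical(x, pattern_phantom(32))
  expect_lte(length(unique(x)), 5)
  expect_gte(mean(x == 0), 0.5)
  expect_true(all(x >= 0 & x <= 1))
  expect_error(pattern_phantom(8), "N >= 16")
  expect_equal(tv_value(pattern_phantom(32)), tv_value(pattern_phantom(32)))
})

test_that("grains phantom is a seeded Voronoi labeling", {
  x <- grains_phantom(24, ncells = 10, seed = 4)
  expect_identical(x, grains_phantom(24, ncells = 10, seed = 4))
  expect_false(identical(x, grains_phantom(24, ncells = 10, seed = 5)))
  expect_lte(length(unique(x)), 10)
  expect_equal(grains_phantom(16, ncells = 1, seed = 1),
               rep(grains_phantom(16, ncells = 1, seed = 1)[1], 256))
})

test_that("blur operators conserve constants and pass the adjoint test", {
  for (op in list(blur_operator(12, "gaussian", sigma = 1.3),
                  blur_operator(12, "shake", trajectory_len = 12, seed = 3))) {
    expect_lt(adjoint_defect(op), 1e-8)
    expect_equal(op$apply(rep(1, 144)), rep(1, 144), tolerance = 1e-12)
    expect_equal(sum(op$psf), 1, tolerance = 1e-12)
  }
  # sub-pixel width approaches the identity
  Ai <- blur_operator(10, "gaussian", sigma = 1e-3)
  set.seed(2); x <- rnorm(100)
  expect_equal(Ai$apply(x), x, tolerance = 1e-6)
  expect_error(blur_operator(8, "gaussian", sigma = 0), "positive")
})

test_that("cluster mask retains the exact target count with unit rows", {
  S <- mask_operator(16, 0.4, 3, seed = 2)
  expect_identical(S$m, as.integer(round(0.4 * 256)))
  Sd <- as_dense_matrix(S)
  expect_true(all(rowSums(Sd) == 1) && all(Sd %in% c(0, 1)))
  expect_lt(adjoint_defect(S), 1e-12)
  # count stays within 5% of target at larger sizes (here it is exact)
  S64 <- mask_operator(64, 0.35, 4, seed = 8)
  expect_lt(abs(S64$m - 0.35 * 64^2) / (0.35 * 64^2), 0.05)
  expect_error(mask_operator(16, 1.2), "between 0 and 1")
})

test_that("tomography matrix matches the independent chord oracle", {
  N <- 16
  geom <- ct_geometry(seq(0, 179, by = 11))
  A <- ct_operator(N, geom)
  nrays <- round(sqrt(2) * N)
  expect_equal(dim(A), c(length(geom$angles) * nrays, N^2))
  expect_true(all(A@x > 0))
  expect_lte(max(tabulate(A@i + 1, nrow(A))), 2 * N)
  expect_lte(max(Matrix::rowSums(A)), N * sqrt(2) + 1e-9)
  sino <- as.numeric(A %*% rep(1, N^2))
  # exact line-square intersection by slab clipping (independent oracle)
  chord <- function(th_deg, off) {
    th <- th_deg * pi / 180
    u <- c(-sin(th), cos(th)); o <- off * c(cos(th), sin(th))
    tmin <- -Inf; tmax <- Inf
    for (d in 1:2) {
      if (abs(u[d]) < 1e-15) {
        if (o[d] < -N / 2 || o[d] > N / 2) return(0)
      } else {
        t1 <- (-N / 2 - o[d]) / u[d]; t2 <- (N / 2 - o[d]) / u[d]
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      }
    }
    max(0, tmax - tmin)
  }
  set.seed(1)
  for (k in sample(length(sino), 10)) {
    a <- (k - 1) %/% nrays + 1
    r <- (k - 1) %% nrays + 1
    expect_equal(sino[k], chord(geom$angles[a], r - (nrays + 1) / 2 + 1e-6),
                 tolerance = 1e-10)
  }
})

test_that("noise model achieves the requested relative level exactly", {
  set.seed(10); b <- rnorm(200) + 2
  nz <- add_noise(b, 0.01, seed = 6)
  expect_equal(sqrt(sum(nz$e^2)) / sqrt(sum(b^2)), 0.01, tolerance = 1e-12)
  expect_identical(add_noise(b, 0.01, seed = 6)$e, nz$e)
  expect_false(identical(add_noise(b, 0.01, seed = 7)$e, nz$e))
  z <- add_noise(b, 0)
  expect_identical(z$b, b)
  expect_error(add_noise(numeric(5), 0.1), "zero data")
})

test_that("operator composition chains applies and adjoints correctly", {
  N <- 8
  blur <- blur_operator(N, "gaussian", sigma = 1)
  mask <- mask_operator(N, 0.5, 2, seed = 4)
  expect_error(compose_operators(blur, mask), "shape mismatch")
  C <- compose_operators(mask, blur)
  expect_equal(as_dense_matrix(C),
               as_dense_matrix(mask) %*% as_dense_matrix(blur),
               tolerance = 1e-12)
  expect_lt(adjoint_defect(C), 1e-8)
  I <- linop_identity(N^2)
  CI <- compose_operators(I, blur)
  set.seed(3); x <- rnorm(N^2)
  expect_equal(CI$apply(x), blur$apply(x))
})

test_that("generated problems are seeded, consistent and adjoint-correct", {
  pr <- deblur_problem(16, "mild", seed = 4)
  pr2 <- deblur_problem(16, "mild", seed = 4)
  expect_identical(pr$b, pr2$b)
  expect_equal(pr$noise_norm / sqrt(sum(pr$b_true^2)), 0.01, tolerance = 1e-12)
  expect_equal(pr$b, pr$b_true + pr$e)
  expect_lt(adjoint_defect(pr$A), 1e-8)
  pi2 <- inpaint_problem(16, seed = 5)
  expect_lt(adjoint_defect(pi2$A), 1e-8)
  expect_identical(pi2$A$m, mask_operator(16, 0.4, seed = 6)$m)
  pc <- ct_problem(16, angles = seq(0, 179, by = 17), seed = 3)
  expect_lt(adjoint_defect(pc$A), 1e-8)
  expect_identical(pc$b, ct_problem(16, angles = seq(0, 179, by = 17), seed = 3)$b)
})
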