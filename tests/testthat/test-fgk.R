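test_that("projected Tikhonov solves match the dense normal-equations oracle", {
  # forced 1D case: H=[[1],[0]], R=[1], beta=1, lam=1 -> s=1/2
  expect_equal(solve_projected(matrix(c(1, 0), 2, 1), matrix(1), 1, 1), 0.5)
  set.seed(4)
  for (k in 1:5) {
    i <- sample(2:6, 1)
    H <- matrix(rnorm((i + 1) * i), i + 1, i)
    R <- qr.R(qr(matrix(rnorm(2 * i * i), 2 * i, i)))
    beta <- runif(1, 0.5, 2); lam <- runif(1, 0.01, 5)
    s <- solve_projected(H, R, beta, lam)
    rhs <- beta * crossprod(H, c(1, numeric(i)))
    expect_equal(as.numeric((crossprod(H) + lam * crossprod(R)) %*% s),
                 as.numeric(rhs), tolerance = 1e-8)
    # lam = 0 gives the least-squares minimizer
    s0 <- solve_projected(H, R, beta, 0)
    expect_equal(as.numeric(crossprod(H, H %*% s0 - beta * c(1, numeric(i)))),
                 numeric(i), tolerance = 1e-8)
  }
})

test_that("discrepancy selection hits the target residual or the guards", {
  # residual of s(1) for H=[[1],[0]], R=[1], beta=1 is 1/2 at lambda=1
  lam <- discrepancy_select(matrix(c(1, 0), 2, 1), matrix(1), 1, 0.5)
  expect_equal(lam, 1, tolerance = 1e-4)
  # unattainable target -> 0 (early-iteration behavior): the minimal
  # projected residual of H=[0.1; 0.3] is ~0.95, above delta
  expect_identical(discrepancy_select(matrix(c(0.1, 0.3), 2, 1), matrix(1),
                                      1, 0.5), 0)
  # target above beta -> lambda_max
  expect_identical(discrepancy_select(matrix(c(1, 0), 2, 1), matrix(1), 1, 2),
                   1e12)
  # random solvable instances against a reference bisection on phi itself
  set.seed(7)
  for (k in 1:4) {
    i <- 4
    H <- matrix(rnorm((i + 1) * i), i + 1, i)
    R <- diag(i)
    beta <- 1
    phi <- function(l) {
      s <- solve(crossprod(H) + l * diag(i), crossprod(H, c(beta, numeric(i))))
      sqrt(sum((H %*% s - c(beta, numeric(i)))^2))
    }
    delta <- (phi(1e-10) + beta) / 2
    lam <- discrepancy_select(H, R, beta, delta)
    expect_lt(abs(phi(lam) - delta), 1e-5 * delta)
    # independent oracle: plain bisection on lambda
    lo <- 1e-10; hi <- 1e10
    for (it in 1:200) {
      mid <- sqrt(lo * hi)
      if (phi(mid) < delta) lo <- mid else hi <- mid
    }
    expect_equal(phi(lam), phi(sqrt(lo * hi)), tolerance = 1e-5)
  }
})

test_that("stabilization stopping rule fires as specified", {
  expect_true(stopping_check(c(0, 0, 1.0, 1.0, 1.0), 0.9))
  expect_false(stopping_check(c(0, 0, 0), 0.9))              # zero guard
  expect_false(stopping_check(c(0, 0, 1.0, 1.0), 0.9))       # |1-0|/1 >= xi
  expect_false(stopping_check(c(1.0, 1.0), 0.9))             # needs k > 2
  expect_true(stopping_check(c(0, 1.0, 3.0, 3.1), 0.9))
  expect_false(stopping_check(c(1, 1, 0), 0.9))              # zero current
})

test_that("flexible factorization satisfies its defining identities", {
  pr <- small_deblur(16)
  cfg <- flex_config(weights = weight_config("tv"), maxit = 12,
                     stop_at_criterion = FALSE, keep_basis = TRUE,
                     compute_ssim = FALSE)
  tr <- run_flexible(pr, cfg)
  st <- attr(tr, "state")
  i <- st$i
  Ad <- as_dense_matrix(pr$A)
  expect_lt(norm(Ad %*% st$Z - st$U %*% st$H, "F"), 1e-8 * norm(st$H, "F"))
  expect_lt(max(abs(crossprod(st$U) - diag(i + 1))), 1e-8)
  expect_lt(max(abs(crossprod(st$V) - diag(i))), 1e-8)
  # H upper Hessenberg, T upper triangular
  expect_lt(max(abs(st$H[row(st$H) > col(st$H) + 1])), 1e-14)
  expect_lt(max(abs(st$Tm[row(st$Tm) > col(st$Tm)])), 1e-14)
  # residual identity: projected residual equals the true one
  x <- attr(tr, "x")
  expect_equal(sqrt(sum((pr$b - pr$A$apply(x))^2)), tr$residual[nrow(tr)],
               tolerance = 1e-8)
  # u1 is bbar-normalized: no span(v) component
  sf <- build_standard_form(pr$A, pr$b, 16)
  expect_lt(abs(sum(st$U[, 1] * sf$v)) / sqrt(sf$vnorm2), 1e-8)
})

test_that("projected regularizer is the QR factor of the weighted gradients", {
  N <- 6
  set.seed(13)
  Z <- matrix(rnorm(N^2 * 3), N^2, 3)
  wst <- compute_weights(weight_config("atv"), apply_gradient(rnorm(N^2), N))
  R <- project_regularizer(wst, Z, N)
  D <- dense_gradient(N)
  for (k in 1:3) {
    s <- rnorm(3)
    expect_equal(sqrt(sum((R %*% s)^2)),
                 sqrt(sum((wst$w * (D %*% Z %*% s))^2)), tolerance = 1e-8)
  }
  # single column: R is the norm of the weighted gradient
  R1 <- project_regularizer(wst, Z[, 1, drop = FALSE], N)
  expect_equal(abs(R1[1, 1]), sqrt(sum((wst$w * (D %*% Z[, 1]))^2)))
  # constant columns lie in the null space: R = 0
  R0 <- project_regularizer(wst, matrix(1, N^2, 2), N)
  expect_lt(max(abs(R0)), 1e-12)
})

test_that("solver restricted to the growing subspace equals dense brute force", {
  pr <- small_deblur(8, sigma = 1, seed = 21)
  N <- 8
  lam <- 0.05
  cfg <- flex_config(weights = weight_config("tv"), maxit = 5,
                     lambda_mode = "fixed", lambda_fixed = lam,
                     stop_at_criterion = FALSE, keep_basis = TRUE,
                     compute_ssim = FALSE)
  tr <- run_flexible(pr, cfg)
  st <- attr(tr, "state"); sols <- attr(tr, "solutions")
  Ad <- as_dense_matrix(pr$A)
  D <- dense_gradient(N)
  sf <- build_standard_form(pr$A, pr$b, N)
  wcfg <- weight_config("tv")
  xprev <- sf$x0
  for (i in seq_len(st$i)) {
    w <- compute_weights(wcfg, apply_gradient(xprev, N))$w
    Z <- st$Z[, seq_len(i), drop = FALSE]
    lhs <- crossprod(Ad %*% Z) + lam * crossprod((D * w) %*% Z)
    s <- solve(lhs, crossprod(Ad %*% Z, sf$bbar))
    xi <- sf$x0 + as.numeric(Z %*% sols[[i]])
    expect_equal(sf$x0 + as.numeric(Z %*% s), xi, tolerance = 1e-8)
    xprev <- xi
  }
})

test_that("frozen weights reproduce the preconditioned Krylov subspace", {
  pr <- small_deblur(8, sigma = 1, seed = 3)
  N <- 8
  wst <- compute_weights(weight_config("atv"), apply_gradient(pr$x_true, N))
  cfg <- flex_config(weights = weight_config("atv"), maxit = 5,
                     lambda_mode = "fixed", lambda_fixed = 0,
                     stop_at_criterion = FALSE, freeze_weights = TRUE,
                     keep_basis = TRUE, compute_ssim = FALSE)
  tr <- run_flexible(pr, cfg, wstate = wst)
  Z <- attr(tr, "state")$Z
  sf <- build_standard_form(pr$A, pr$b, N)
  sfac <- build_spectral_factors(N)
  P <- function(v) apply_preconditioner(sf, pr$A, sfac, wst, v)
  Kr <- matrix(P(pr$A$adjoint(sf$bbar)), ncol = 1)
  for (j in 2:ncol(Z))
    Kr <- cbind(Kr, P(pr$A$adjoint(pr$A$apply(Kr[, j - 1]))))
  qz <- qr.Q(qr(Z)); qk <- qr.Q(qr(Kr))
  angles <- acos(pmin(1, svd(crossprod(qz, qk))$d))
  expect_lt(max(angles), 1e-6)
})

test_that("variational objective is tangent and consistent with TV", {
  N <- 6
  set.seed(31)
  A <- random_operator(20, N^2, seed = 31)
  b <- rnorm(20)
  x <- rnorm(N^2)
  wcfg <- weight_config("tv", tau = 1e-12)
  lam <- 0.3
  ov <- objective_value(A, b, x, 2 * lam, wcfg)
  # tangency: Q(x; x) = F(x) because Omega(x) = ||W(x) D x||^2 by definition
  w <- compute_weights(wcfg, apply_gradient(x, N))$w
  Q_xx <- sum((A$apply(x) - b)^2) + lam * sum((w * apply_gradient(x, N))^2) +
    lam * ov$omega
  expect_equal(Q_xx, ov$F, tolerance = 1e-10)
  # smoothed regularizer approaches the unsmoothed TV as tau -> 0
  expect_equal(ov$omega, tv_value(x, N), tolerance = 1e-4)
  # step image on [0,1]^2: TV of [0,0,1,1] is 2
  ov2 <- objective_value(linop_identity(4), numeric(4), c(0, 0, 1, 1), 1,
                         weight_config("tv", tau = 1e-12))
  expect_equal(ov2$omega, 2, tolerance = 1e-6)
  expect_error(objective_value(A, b, x, 1, weight_config("diag")), "tv")
})

test_that("majorant inequality holds for random pairs", {
  N <- 6
  set.seed(41)
  A <- random_operator(20, N^2, seed = 41)
  b <- rnorm(20)
  wcfg <- weight_config("tv", tau = 1e-9)
  lam <- 0.7
  for (k in 1:5) {
    x <- rnorm(N^2); xl <- rnorm(N^2)
    wl <- compute_weights(wcfg, apply_gradient(xl, N))$w
    Fx <- objective_value(A, b, x, 2 * lam, wcfg)$F
    Q <- sum((A$apply(x) - b)^2) + lam * sum((wl * apply_gradient(x, N))^2) +
      lam * objective_value(A, b, xl, 2 * lam, wcfg)$omega
    expect_gte(Q - Fx, -1e-6 * abs(Fx))
  }
})

test_that("lambda history starts at zero, meets the discrepancy, then stabilizes", {
  pr <- deblur_problem(32, "mild", seed = 11)
  tr <- run_flexible(pr, flex_config(maxit = 100, stop_at_criterion = FALSE,
                                     compute_ssim = FALSE))
  pos <- which(tr$lambda > 0 & tr$lambda < 1e12)
  expect_gt(min(pos), 3)                       # an initial run of zeros
  expect_true(all(tr$lambda[seq_len(min(pos) - 1)] == 0))
  delta <- 1.01 * pr$noise_norm
  expect_lt(max(abs(tr$residual[pos] - delta) / delta), 1e-4)
  expect_lt(attr(tr, "stop_iteration"), 100)   # rule fires before maxit
  # final error far below the error of the constant start
  expect_lt(tr$rre[nrow(tr)], 0.5 * rre(attr(tr, "x0"), pr$x_true))
})
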