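test_that("identity-preconditioned flexible process reduces to bidiagonalization", {
  pr <- small_deblur(16, seed = 3)
  cfg <- flex_config(weights = weight_config("none"), maxit = 10,
                     precond = "identity", lambda_mode = "fixed",
                     lambda_fixed = 0, stop_at_criterion = FALSE,
                     keep_basis = TRUE, compute_ssim = FALSE)
  tr <- run_flexible(pr, cfg)
  H <- attr(tr, "state")$H
  expect_lt(max(abs(H[row(H) < col(H)])), 1e-8 * max(abs(H)))
  # and its lambda=0 iterates are the classical bidiagonalization-LS
  # solutions of the standard-form system: residual minimal over the
  # Krylov space of Abar'Abar (checked against a dense normal solve)
  sf <- build_standard_form(pr$A, pr$b, 16)
  Ad <- as_dense_matrix(pr$A)
  Z <- attr(tr, "state")$Z
  s <- qr.solve(Ad %*% Z, sf$bbar)
  expect_equal(attr(tr, "x"), sf$x0 + as.numeric(Z %*% s), tolerance = 1e-6)
})

test_that("frozen-weight flexible solver coincides with the GKB hybrid at lambda zero", {
  pr <- small_deblur(16, seed = 3)
  N <- 16
  for (kind in c("none", "atv")) {
    wst <- if (kind == "none") identity_weights(N) else
      compute_weights(weight_config("atv"), apply_gradient(pr$x_true, N))
    cfg <- flex_config(weights = weight_config(kind), maxit = 8,
                       lambda_mode = "fixed", lambda_fixed = 0,
                       stop_at_criterion = FALSE, freeze_weights = TRUE,
                       compute_ssim = FALSE)
    trF <- run_flexible(pr, cfg, wstate = wst)
    trG <- gkb_hybrid(pr, wst, cfg)
    expect_equal(attr(trF, "x"), attr(trG, "x"), tolerance = 1e-6)
    expect_equal(trF$rre, trG$rre, tolerance = 1e-6)
  }
})

test_that("GKB hybrid produces a lower-bidiagonal projected matrix", {
  pr <- small_deblur(16, seed = 5)
  cfg <- flex_config(maxit = 8, lambda_mode = "fixed", lambda_fixed = 0.01,
                     stop_at_criterion = FALSE, keep_basis = TRUE,
                     compute_ssim = FALSE)
  tr <- gkb_hybrid(pr, NULL, cfg)
  B <- attr(tr, "B")
  expect_identical(dim(B), c(9L, 8L))
  off <- B[row(B) < col(B) | row(B) > col(B) + 1]
  expect_true(all(off == 0))
  expect_true(all(diag(B[1:8, ]) > 0))
})

test_that("inner-outer scheme nests the GKB hybrid and respects its budget", {
  pr <- small_deblur(16, seed = 9)
  # a single outer cycle with identity weights is exactly the GKB hybrid
  c1 <- irn_config(weights = weight_config("tv"), budget = 12, outer_max = 1,
                   compute_ssim = FALSE)
  tri <- irn(pr, c1)
  trg <- gkb_hybrid(pr, identity_weights(16),
                    flex_config(maxit = 12, stop_at_criterion = TRUE,
                                compute_ssim = FALSE))
  expect_equal(tri$lambda, trg$lambda, tolerance = 1e-10)
  expect_equal(tri$rre, trg$rre, tolerance = 1e-10)
  # multi-cycle run (inner cycles capped at 10): budget conservation and
  # outer bookkeeping
  c2 <- irn_config(weights = weight_config("tv"), budget = 30, outer_max = 6,
                   maxit = 10, compute_ssim = FALSE)
  tr2 <- irn(pr, c2)
  expect_lte(nrow(tr2), 30)
  df <- as.data.frame(tr2)
  expect_true(all(diff(df$outer) >= 0))
  expect_gt(max(df$outer), 1)
  # second-cycle weights equal the scheme weights of the first-cycle solution
  first_end <- max(which(df$outer == 1))
  x1_cfg <- flex_config(maxit = max(3, first_end), stop_at_criterion = FALSE,
                        compute_ssim = FALSE)
  x1 <- attr(gkb_hybrid(pr, identity_weights(16), x1_cfg), "x")
  w2 <- compute_weights(weight_config("tv"), apply_gradient(x1, 16))
  # replay cycle 2 with those weights and compare its first iterations
  len2 <- sum(df$outer == 2)
  trg2 <- gkb_hybrid(pr, w2, flex_config(maxit = max(3, len2),
                                         stop_at_criterion = TRUE,
                                         compute_ssim = FALSE))
  cmp_len <- min(len2, nrow(trg2))
  expect_gte(cmp_len, 1)
  expect_equal(df$rre[first_end + seq_len(cmp_len)],
               trg2$rre[seq_len(cmp_len)], tolerance = 1e-10)
})

test_that("cold restarts produce error jumps at cycle boundaries", {
  pr <- deblur_problem(32, "mild", seed = 13)
  tr <- irn(pr, irn_config(weights = weight_config("tv"), budget = 80,
                           outer_max = 4, compute_ssim = FALSE))
  df <- as.data.frame(tr)
  expect_gt(max(df$outer), 1)
  bnd <- which(diff(df$outer) > 0) + 1
  # the first iterate of a restarted cycle is worse than the last of the
  # previous cycle (the inner solve restarts from scratch)
  expect_true(all(df$rre[bnd] > df$rre[bnd - 1]))
})
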