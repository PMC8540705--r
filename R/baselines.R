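#' Priorconditioned Golub-Kahan hybrid solver with frozen weights
#'
#' Golub-Kahan bidiagonalization applied to the standard-form-transformed
#' problem `Abar = A L_A^+`, `bbar = b - A x0`, with the weights held
#' fixed for all iterations: the classical hybrid scheme the flexible
#' solver generalizes.  With identity weights this is the
#' "priorconditioned LSQR" baseline with regularization operator `D2d`
#' (LSQR-L).  The projected problem carries a plain 2-norm penalty,
#' `min_s ||Bhat s - beta e1||^2 + lambda ||s||^2`; `lambda` is selected
#' per iteration by the discrepancy principle and the stabilization rule
#' is monitored exactly as in [run_flexible()].
#'
#' @param problem a `forward_problem`.
#' @param wstate fixed `weight_state` (use [identity_weights()] for
#'   LSQR-L); `NULL` means identity.
#' @param cfg a [flex_config()]; the `weights` field is ignored except for
#'   trace-objective bookkeeping.
#' @return an `fgk_trace` (attribute `B` holds the bidiagonal projected
#'   matrix when `keep_basis` is set).
#' @export
gkb_hybrid <- function(problem, wstate = NULL, cfg = flex_config()) {
  A <- problem$A
  N <- as.integer(round(sqrt(A$n)))
  stopifnot(N * N == A$n)
  sfac <- build_spectral_factors(N)
  sf <- build_standard_form(A, problem$b, N)
  if (is.null(wstate)) wstate <- identity_weights(N)
  noise_norm <- if (!is.null(cfg$noise_norm)) cfg$noise_norm else problem$noise_norm
  if (cfg$lambda_mode == "discrepancy" && is.null(noise_norm))
    stop("discrepancy-principle mode needs a noise-norm estimate")
  if (sf$beta <= 1e-14 * max(sqrt(sum(problem$b^2)), 1))
    return(fgk_trace(data.frame(), x = sf$x0, x_stop = sf$x0,
                     stop_iteration = 0L, x0 = sf$x0, N = N,
                     breakdown = "data explained by the constant component"))

  # transformed operator Abar = A E D2d^+ W^-1 and its adjoint
  ab_apply <- function(y)
    A$apply(apply_E(sf, A,
                    apply_gradient_pinv(apply_inverse_weights(wstate, y), sfac)))
  ab_adjoint <- function(u)
    apply_inverse_weights(wstate,
                          apply_gradient_pinv_adjoint(apply_E_adjoint(sf, A$adjoint(u)),
                                                      sfac))

  U <- matrix(sf$bbar / sf$beta, ncol = 1)
  V <- NULL
  alphas <- numeric(0); betas <- numeric(0)
  rows <- vector("list", cfg$maxit)
  lamhist <- numeric(0)
  stop_iter <- NA_integer_
  x <- sf$x0; x_stop <- NULL
  breakdown <- NULL

  for (i in seq_len(cfg$maxit)) {
    vbar <- ab_adjoint(U[, i])
    nrm0 <- sqrt(sum(vbar^2))
    og <- mgs_against(vbar, V, cfg$reorth)
    alpha <- sqrt(sum(og$x^2))
    if (alpha <= 1e-12 * nrm0) { breakdown <- "new V direction vanished"; break }
    V <- cbind(V, og$x / alpha)
    ubar <- ab_apply(V[, i])
    nrm0u <- sqrt(sum(ubar^2))
    ogu <- mgs_against(ubar, U, cfg$reorth)
    beta_i <- sqrt(sum(ogu$x^2))
    broke_u <- beta_i <= 1e-12 * nrm0u
    U <- cbind(U, if (broke_u) rep(0, nrow(U)) else ogu$x / beta_i)
    alphas <- c(alphas, alpha); betas <- c(betas, beta_i)

    # lower-bidiagonal projected matrix Bhat, (i+1) x i
    B <- matrix(0, i + 1, i)
    B[cbind(seq_len(i), seq_len(i))] <- alphas
    B[cbind(seq_len(i) + 1, seq_len(i))] <- betas
    R <- diag(i)
    lam <- if (cfg$lambda_mode == "fixed") cfg$lambda_fixed else
      discrepancy_select(B, R, sf$beta, cfg$eta * noise_norm)
    s <- solve_projected(B, R, sf$beta, lam)
    y <- as.numeric(V %*% s)
    x <- sf$x0 + apply_E(sf, A,
                         apply_gradient_pinv(apply_inverse_weights(wstate, y), sfac))
    res <- sqrt(sum((as.numeric(B %*% s) - c(sf$beta, numeric(i)))^2))

    obj <- if (cfg$weights$kind %in% c("tv", "atv"))
      objective_value(A, problem$b, x, 2 * lam, cfg$weights)$F else NA_real_
    rows[[i]] <- trace_row(i, lam, res, obj, x, problem, N, cfg$compute_ssim)

    lamhist <- c(lamhist, lam)
    if (is.na(stop_iter) && stopping_check(lamhist, cfg$xi)) {
      stop_iter <- i
      x_stop <- x
      if (cfg$stop_at_criterion) break
    }
    if (broke_u) { breakdown <- "new U direction vanished"; break }
  }

  tr <- fgk_trace(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                  x = x, x_stop = if (is.null(x_stop)) x else x_stop,
                  stop_iteration = stop_iter, x0 = sf$x0, N = N,
                  breakdown = breakdown)
  if (cfg$keep_basis) {
    B <- matrix(0, length(alphas) + 1, length(alphas))
    B[cbind(seq_along(alphas), seq_along(alphas))] <- alphas
    B[cbind(seq_along(alphas) + 1, seq_along(alphas))] <- betas
    attr(tr, "B") <- B
    attr(tr, "V") <- V
    attr(tr, "U") <- U
  }
  tr
}

#' Identity weight state
#'
#' All-ones diagonal weights (the unweighted gradient penalty), used for
#' the LSQR-L baseline and for the first cycle of the inner-outer scheme.
#'
#' @param N image side.
#' @return a `weight_state` of kind `"none"`.
#' @export
identity_weights <- function(N) {
  compute_weights(weight_config("none"), numeric(2 * N * (N - 1)))
}

#' Configuration for the inner-outer reweighted scheme
#'
#' @param weights a [weight_config()] for the outer weight updates.
#' @param eta,xi,maxit,noise_norm,compute_ssim as in [flex_config()];
#'   `maxit` caps each inner cycle.
#' @param budget total inner-iteration budget across all cycles.
#' @param outer_max maximum number of outer cycles.
#' @param cold_restart restart each inner solve from scratch (default
#'   `TRUE`, the standard practice; the trace then shows jumps in the
#'   error at cycle boundaries).
#' @return an object of class `irn_config`.
#' @export
irn_config <- function(weights = weight_config("tv"), eta = 1.01, xi = 0.9,
                       budget = 200, outer_max = 20, maxit = 200,
                       noise_norm = NULL, cold_restart = TRUE,
                       compute_ssim = TRUE) {
  stopifnot(inherits(weights, "weight_config"), budget >= 1, outer_max >= 1)
  structure(list(weights = weights, eta = eta, xi = xi, budget = budget,
                 outer_max = outer_max, maxit = maxit,
                 noise_norm = noise_norm, cold_restart = cold_restart,
                 compute_ssim = compute_ssim),
            class = "irn_config")
}

#' Inner-outer iteratively reweighted solver
#'
#' The classical scheme the flexible methods are designed to replace: the
#' outer loop updates the diagonal weights from the latest outer solution
#' (first cycle: identity weights) and each inner cycle runs the
#' priorconditioned Golub-Kahan hybrid [gkb_hybrid()] with those frozen
#' weights until its own stabilization rule fires or the remaining budget
#' is spent.  Cold restarts discard the inner subspace between cycles.
#' There is no outer convergence test (the budget and `outer_max` are the
#' only caps).
#'
#' @param problem a `forward_problem`.
#' @param cfg an [irn_config()].
#' @return an `fgk_trace` with an `outer` column marking cycle boundaries.
#' @export
irn <- function(problem, cfg = irn_config()) {
  N <- as.integer(round(sqrt(problem$A$n)))
  wcfg <- cfg$weights
  wstate <- identity_weights(N)
  used <- 0L
  pieces <- list()
  x <- NULL; x_stop <- NULL; stop_iter <- NA_integer_
  for (k in seq_len(cfg$outer_max)) {
    left <- cfg$budget - used
    if (left <= 0) break
    inner_cfg <- flex_config(weights = wcfg, eta = cfg$eta, xi = cfg$xi,
                             maxit = max(3, min(cfg$maxit, left)),
                             noise_norm = cfg$noise_norm,
                             stop_at_criterion = TRUE,
                             compute_ssim = cfg$compute_ssim)
    tr <- gkb_hybrid(problem, wstate, inner_cfg)
    ni <- nrow(tr)
    if (ni == 0) break
    df <- as.data.frame(tr)
    if (ni > left) {               # enforce the budget cap exactly
      df <- df[seq_len(left), , drop = FALSE]
      ni <- left
    }
    used <- used + ni
    df$outer <- k
    pieces[[k]] <- df
    x <- attr(tr, "x")
    if (is.na(stop_iter) && !is.na(attr(tr, "stop_iteration"))) {
      # record the global iteration index at which the last cycle's rule fired
      stop_iter <- used - ni + attr(tr, "stop_iteration")
      x_stop <- attr(tr, "x_stop")
    }
    wstate <- compute_weights(wcfg, apply_gradient(x, N),
                              prev = if (wcfg$kind == "diag") wstate else NULL)
  }
  df <- do.call(rbind, pieces)
  outer <- df$outer
  df$outer <- NULL
  df$iteration <- seq_len(nrow(df))
  fgk_trace(df, x = x, x_stop = if (is.null(x_stop)) x else x_stop,
            stop_iteration = stop_iter, x0 = rep(NA_real_, length(x)),
            N = N, outer = outer)
}
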