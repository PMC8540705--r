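#' Solver configuration for the flexible Golub-Kahan hybrid methods
#'
#' @param weights a [weight_config()] selecting the edge-enhancing scheme
#'   (`"tv"`, `"atv"`, `"diag"`) or `"none"` for a plain gradient penalty.
#' @param eta discrepancy-principle safety factor (>= 1); the target
#'   residual is `eta * ||e||_2`.
#' @param xi stopping threshold on the relative stabilization of the
#'   regularization parameter over two consecutive iterations.
#' @param maxit maximum number of iterations (>= 3).
#' @param noise_norm estimate of `||e||_2`; synthetic problems carry the
#'   exact value and it is used when this is `NULL`.
#' @param lambda_mode `"discrepancy"` (adaptive, per iteration) or
#'   `"fixed"`.
#' @param lambda_fixed the value of lambda in `"fixed"` mode.
#' @param include_E keep the oblique projector `E` inside the
#'   preconditioner (default `TRUE`).
#' @param exact_pinv use the dense pseudoinverse of `W D2d` in the
#'   preconditioner (small problems only, `N <= 64`).
#' @param precond `"transform"` for the standard-form preconditioner
#'   (default); `"identity"` replaces the preconditioning step by the
#'   identity map, in which case the process reduces exactly to
#'   Golub-Kahan bidiagonalization (test mode).
#' @param stop_at_criterion stop iterating once the stabilization rule
#'   fires (default); if `FALSE`, run to `maxit` and only record the
#'   stopping iteration.
#' @param compute_ssim record SSIM in the trace (needs a ground truth).
#' @param keep_basis retain the factorization and per-iteration projected
#'   solutions in the returned trace (oracle checks; memory-heavy).
#' @param freeze_weights never update the weights after the first
#'   iteration; with a supplied initial weight state this makes the
#'   flexible solver coincide with the priorconditioned Golub-Kahan
#'   hybrid on the same subspace.
#' @param reorth number of Gram-Schmidt passes (default 2: one pass plus
#'   one refinement).
#' @return an object of class `flex_config`.
#' @export
flex_config <- function(weights = weight_config("tv"), eta = 1.01, xi = 0.9,
                        maxit = 200, noise_norm = NULL,
                        lambda_mode = c("discrepancy", "fixed"),
                        lambda_fixed = 0, include_E = TRUE,
                        exact_pinv = FALSE,
                        precond = c("transform", "identity"),
                        stop_at_criterion = TRUE, compute_ssim = TRUE,
                        keep_basis = FALSE, freeze_weights = FALSE,
                        reorth = 2) {
  lambda_mode <- match.arg(lambda_mode)
  precond <- match.arg(precond)
  stopifnot(inherits(weights, "weight_config"), eta >= 1, xi > 0, maxit >= 3,
            lambda_fixed >= 0, reorth >= 1)
  structure(list(weights = weights, eta = eta, xi = xi, maxit = maxit,
                 noise_norm = noise_norm, lambda_mode = lambda_mode,
                 lambda_fixed = lambda_fixed, include_E = include_E,
                 exact_pinv = exact_pinv, precond = precond,
                 stop_at_criterion = stop_at_criterion,
                 compute_ssim = compute_ssim, keep_basis = keep_basis,
                 freeze_weights = freeze_weights, reorth = reorth),
            class = "flex_config")
}

#' Initialize the flexible Golub-Kahan factorization
#'
#' Starts the factorization from the standard-form residual:
#' `u1 = bbar / ||bbar||` with empty `V`, `Z`, `H`.
#'
#' @param A forward operator.
#' @param sf a [build_standard_form()] object with `beta > 0`.
#' @return an object of class `fgk_state`.
#' @export
fgk_initialize <- function(A, sf) {
  if (sf$beta <= 0) stop("bbar is zero: the solution is x0 (trivial case)")
  structure(list(U = matrix(sf$bbar / sf$beta, ncol = 1),
                 V = NULL, Z = NULL, G = NULL,
                 H = matrix(0, 1, 0), Tm = matrix(0, 0, 0),
                 i = 0L, breakdown = NULL),
            class = "fgk_state")
}

# one or more modified Gram-Schmidt passes of x against the columns of B;
# returns the orthogonalized vector and accumulated coefficients
mgs_against <- function(x, B, passes) {
  coef <- numeric(if (is.null(B)) 0 else ncol(B))
  if (!is.null(B) && ncol(B) > 0) {
    for (p in seq_len(passes)) {
      cf <- as.numeric(crossprod(B, x))
      x <- x - as.numeric(B %*% cf)
      coef <- coef + cf
    }
  }
  list(x = x, coef = coef)
}

#' Expand the flexible Golub-Kahan factorization by one step
#'
#' One step of the flexible process: `vbar = A' u_i` is orthogonalized
#' against `V`; the new direction is preconditioned with the current
#' weights, `z_i = E L^+ (L^+)' E' v_i` (normalized); `A z_i` is
#' orthogonalized against `U`, filling column `i` of the upper-Hessenberg
#' `H`.  Breakdown (a new vector whose norm falls below `1e-12` times its
#' pre-orthogonalization norm) is flagged on the returned state and the
#' caller is expected to stop expanding.
#'
#' @param state an `fgk_state`.
#' @param A forward operator.
#' @param sf a [build_standard_form()] object.
#' @param sfac spectral factors of the gradient.
#' @param wstate current `weight_state`.
#' @param cfg a [flex_config()].
#' @return the updated `fgk_state`.
#' @export
fgk_expand <- function(state, A, sf, sfac, wstate, cfg) {
  if (!is.null(state$breakdown)) stop("cannot expand after breakdown")
  i <- state$i + 1L
  u_i <- state$U[, i]

  vbar <- A$adjoint(u_i)
  nrm0 <- sqrt(sum(vbar^2))
  og <- mgs_against(vbar, state$V, cfg$reorth)
  tii <- sqrt(sum(og$x^2))
  if (tii <= 1e-12 * nrm0) {
    state$breakdown <- "new V direction vanished"
    return(state)
  }
  v_i <- og$x / tii

  z <- if (cfg$precond == "identity") v_i else
    apply_preconditioner(sf, A, sfac, wstate, v_i,
                         include_E = cfg$include_E,
                         exact_pinv = cfg$exact_pinv)
  znrm <- sqrt(sum(z^2))
  if (znrm == 0) {
    state$breakdown <- "preconditioned direction vanished"
    return(state)
  }
  z_i <- z / znrm

  ubar <- A$apply(z_i)
  nrm0u <- sqrt(sum(ubar^2))
  ogu <- mgs_against(ubar, state$U, cfg$reorth)
  hnew <- sqrt(sum(ogu$x^2))
  broke_u <- hnew <= 1e-12 * nrm0u
  u_new <- if (broke_u) rep(0, length(ubar)) else ogu$x / hnew

  state$V <- cbind(state$V, v_i)
  state$Z <- cbind(state$Z, z_i)
  state$G <- cbind(state$G, apply_gradient(z_i, sfac$N))
  state$U <- cbind(state$U, u_new)
  H <- rbind(state$H, rep(0, ncol(state$H)))
  state$H <- cbind(H, c(ogu$coef, hnew))
  Tm <- rbind(state$Tm, rep(0, ncol(state$Tm)))
  state$Tm <- cbind(Tm, c(og$coef, tii))
  state$i <- i
  if (broke_u) state$breakdown <- "new U direction vanished"
  state
}

#' Projected regularization matrix
#'
#' Triangular factor `R` from the economy-size QR factorization of
#' `W D2d Z`, so that `||R s|| = ||W D2d Z s||` for all `s`: the exact
#' projection of the current reweighted gradient penalty onto the
#' approximation subspace.
#'
#' @param wstate a `weight_state`.
#' @param Z basis matrix (`n x i`), or `NULL` when `GZ` is supplied.
#' @param N image side (needed with `Z`).
#' @param GZ optionally, the precomputed gradients `D2d Z` (`2*ntilde x i`).
#' @return upper-triangular `i x i` matrix.
#' @export
project_regularizer <- function(wstate, Z = NULL, N = NULL, GZ = NULL) {
  if (is.null(GZ)) {
    stopifnot(!is.null(Z), !is.null(N))
    GZ <- apply(Z, 2, apply_gradient, N = N)
    if (is.null(dim(GZ))) GZ <- matrix(GZ, ncol = ncol(Z))
  }
  qr.R(qr(GZ * wstate$w))
}

# minimum-norm least-squares solve via the SVD
ls_minnorm <- function(M, rhs) {
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(numeric(ncol(M)))
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos]))
}

#' Solve the projected Tikhonov problem
#'
#' Minimum-norm solution of
#' \deqn{\min_s \|H s - \beta e_1\|_2^2 + \lambda \|R s\|_2^2}
#' via the stacked least-squares system `[H; sqrt(lambda) R] s = [beta e1; 0]`.
#'
#' @param H `(i+1) x i` projected operator (upper Hessenberg).
#' @param R `i x i` projected regularizer.
#' @param beta norm of the transformed data `bbar`.
#' @param lam regularization parameter `>= 0`.
#' @return the projected solution `s` (length `i`).
#' @export
solve_projected <- function(H, R, beta, lam) {
  stopifnot(lam >= 0)
  i <- ncol(H)
  e1 <- c(beta, numeric(nrow(H) - 1))
  if (lam > 0) {
    M <- rbind(H, sqrt(lam) * R)
    rhs <- c(e1, numeric(nrow(R)))
  } else {
    M <- H
    rhs <- e1
  }
  ls_minnorm(M, rhs)
}

# projected residual norm ||H s(lambda) - beta e1||
projected_residual <- function(H, R, beta, lam) {
  s <- solve_projected(H, R, beta, lam)
  sqrt(sum((as.numeric(H %*% s) - c(beta, numeric(nrow(H) - 1)))^2))
}

#' Select lambda by the discrepancy principle on the projected problem
#'
#' Finds `lambda` with `||H s(lambda) - beta e1|| = delta`, where
#' `delta = eta * ||e||_2`.  The residual `phi(lambda)` is monotone
#' non-decreasing; a bracketed bisection on `log10(lambda)` over
#' `[1e-12, 1e12]` is run to relative tolerance `1e-6` on the residual.
#' Returns `0` when even the unregularized projected residual exceeds
#' `delta` (the discrepancy is not yet attainable, typical for early
#' iterations), and `1e12` when `beta < delta` (any large `lambda`
#' over-satisfies it).
#'
#' @param H,R,beta as in [solve_projected()].
#' @param delta discrepancy target `> 0`.
#' @return the selected `lambda`.
#' @export
discrepancy_select <- function(H, R, beta, delta) {
  stopifnot(delta > 0)
  phi0 <- projected_residual(H, R, beta, 0)
  if (phi0 > delta) return(0)
  if (beta < delta) return(1e12)
  lo <- -12; hi <- 12
  phi_hi <- projected_residual(H, R, beta, 10^hi)
  if (phi_hi < delta) return(10^hi)
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    ph <- projected_residual(H, R, beta, 10^mid)
    if (abs(ph - delta) <= 1e-6 * delta) return(10^mid)
    if (ph < delta) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

#' Stabilization-based stopping rule
#'
#' Fires at the first iteration `k > 2` such that both relative changes
#' `|l_k - l_{k-1}|/l_k` and `|l_{k-1} - l_{k-2}|/l_{k-1}` fall below
#' `xi`, with both denominators strictly positive (iterations where the
#' selected parameter is zero can never satisfy the rule).
#'
#' @param lambda_history numeric vector of selected parameters so far.
#' @param xi threshold `> 0`.
#' @return logical.
#' @export
stopping_check <- function(lambda_history, xi) {
  k <- length(lambda_history)
  if (k <= 2) return(FALSE)
  lk <- lambda_history[k]; lk1 <- lambda_history[k - 1]
  lk2 <- lambda_history[k - 2]
  if (lk <= 0 || lk1 <= 0) return(FALSE)
  abs(lk - lk1) / lk < xi && abs(lk1 - lk2) / lk1 < xi
}

#' Edge-enhancing objective and regularizer value
#'
#' For the variational schemes (`tv`, `atv`) evaluates the smoothed
#' regularizer \eqn{\Omega(x) = \|W(D_{2d}x)\,D_{2d}x\|_2^2} (the weights
#' are the scheme's own, evaluated at `x`) and the objective
#' `F = ||A x - b||^2 + lam_hat * Omega`.  The cumulative `diag` scheme
#' has no variational objective and is rejected.
#'
#' @param A forward operator.
#' @param b data vector.
#' @param x image vector.
#' @param lam_hat objective-scale regularization parameter (`lam_hat = 2
#'   lambda` relative to the reweighted least-squares parameter).
#' @param wcfg a [weight_config()] with kind `tv` or `atv`.
#' @return list with elements `F` and `omega`.
#' @export
objective_value <- function(A, b, x, lam_hat, wcfg) {
  stopifnot(inherits(wcfg, "weight_config"))
  if (!wcfg$kind %in% c("tv", "atv"))
    stop("objective is defined for the tv and atv schemes only")
  N <- as.integer(round(sqrt(length(x))))
  g <- apply_gradient(x, N)
  w <- compute_weights(wcfg, g)$w
  omega <- sum((w * g)^2)
  r <- A$apply(x) - b
  list(F = sum(r^2) + lam_hat * omega, omega = omega)
}

#' Run a flexible Golub-Kahan edge-enhancing solver
#'
#' The main driver: builds the standard-form transformation once, then
#' iterates the flexible factorization, recomputing the diagonal weights
#' from the current iterate at every step, projecting the reweighted
#' gradient penalty by QR, selecting `lambda` on the projected problem
#' (discrepancy principle by default) and monitoring the stabilization
#' stopping rule.  With `weights = weight_config("tv")` this is the F-TV
#' solver; `"atv"` gives F-aTV, `"diag"` gives F-diag; adding
#' `exact_pinv = TRUE` gives the exact-pseudoinverse variants.
#'
#' @param problem a `forward_problem` (see [deblur_problem()] and
#'   friends), or any list with fields `A` (`linop`), `b`, and optionally
#'   `x_true` and `noise_norm`.
#' @param cfg a [flex_config()].
#' @param wstate optional initial `weight_state` (default: computed from
#'   the constant start `x0`); combined with `freeze_weights` this runs
#'   the solver with a fixed weighting.
#' @return an object of class `fgk_trace`: a data frame with one row per
#'   iteration (`iteration`, `lambda`, `residual`, `objective`, `rre`,
#'   `ssim`, `tv`) and attributes `x` (final iterate), `x_stop` (iterate
#'   at the stopping iteration), `stop_iteration`, `first_positive_lambda`,
#'   `x0`, `breakdown`, `N`, and (with `keep_basis`) `state` and
#'   `solutions`.
#' @export
run_flexible <- function(problem, cfg = flex_config(), wstate = NULL) {
  A <- problem$A
  N <- as.integer(round(sqrt(A$n)))
  stopifnot(N * N == A$n)
  sfac <- build_spectral_factors(N)
  sf <- build_standard_form(A, problem$b, N)
  noise_norm <- if (!is.null(cfg$noise_norm)) cfg$noise_norm else problem$noise_norm
  if (cfg$lambda_mode == "discrepancy" && is.null(noise_norm))
    stop("discrepancy-principle mode needs a noise-norm estimate")

  trivial <- sf$beta <= 1e-14 * max(sqrt(sum(problem$b^2)), 1)
  if (trivial)
    return(fgk_trace(data.frame(), x = sf$x0, x_stop = sf$x0,
                     stop_iteration = 0L, x0 = sf$x0, N = N,
                     breakdown = "data explained by the constant component"))

  wcfg <- cfg$weights
  if (is.null(wstate)) wstate <- compute_weights(wcfg, apply_gradient(sf$x0, N))
  state <- fgk_initialize(A, sf)

  rows <- vector("list", cfg$maxit)
  lamhist <- numeric(0)
  stop_iter <- NA_integer_
  x <- sf$x0; x_stop <- NULL
  sols <- if (cfg$keep_basis) list() else NULL

  for (i in seq_len(cfg$maxit)) {
    state <- fgk_expand(state, A, sf, sfac, wstate, cfg)
    if (state$i < i) break                       # breakdown before commit
    R <- project_regularizer(wstate, GZ = state$G)
    lam <- if (cfg$lambda_mode == "fixed") cfg$lambda_fixed else
      discrepancy_select(state$H, R, sf$beta, cfg$eta * noise_norm)
    s <- solve_projected(state$H, R, sf$beta, lam)
    x <- sf$x0 + as.numeric(state$Z %*% s)
    res <- sqrt(sum((as.numeric(state$H %*% s) -
                       c(sf$beta, numeric(nrow(state$H) - 1)))^2))
    if (cfg$keep_basis) sols[[i]] <- s

    obj <- if (wcfg$kind %in% c("tv", "atv"))
      objective_value(A, problem$b, x, 2 * lam, wcfg)$F else NA_real_
    rows[[i]] <- trace_row(i, lam, res, obj, x, problem, N, cfg$compute_ssim)

    lamhist <- c(lamhist, lam)
    if (is.na(stop_iter) && stopping_check(lamhist, cfg$xi)) {
      stop_iter <- i
      x_stop <- x
      if (cfg$stop_at_criterion) break
    }
    if (!is.null(state$breakdown)) break
    if (!cfg$freeze_weights)
      wstate <- compute_weights(wcfg, apply_gradient(x, N), prev = wstate)
  }

  tr <- fgk_trace(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                  x = x, x_stop = if (is.null(x_stop)) x else x_stop,
                  stop_iteration = stop_iter, x0 = sf$x0, N = N,
                  breakdown = state$breakdown)
  if (cfg$keep_basis) {
    attr(tr, "state") <- state
    attr(tr, "solutions") <- sols
  }
  tr
}

# single trace row with quality metrics
trace_row <- function(i, lam, res, obj, x, problem, N, do_ssim) {
  xt <- problem$x_true
  data.frame(iteration = i, lambda = lam, residual = res, objective = obj,
             rre  = if (!is.null(xt)) rre(x, xt) else NA_real_,
             ssim = if (!is.null(xt) && do_ssim)
               ssim(matrix(x, N, N), matrix(xt, N, N)) else NA_real_,
             tv   = tv_value(x, N))
}

# construct the trace object
fgk_trace <- function(df, x, x_stop, stop_iteration, x0, N,
                      breakdown = NULL, outer = NULL) {
  if (!is.null(outer) && nrow(df) > 0) df$outer <- outer
  structure(df, class = c("fgk_trace", "data.frame"),
            x = x, x_stop = x_stop, stop_iteration = stop_iteration,
            first_positive_lambda =
              if (nrow(df) > 0 && any(df$lambda > 0)) min(which(df$lambda > 0))
              else NA_integer_,
            x0 = x0, N = N, breakdown = breakdown)
}

#' @export
print.fgk_trace <- function(x, ...) {
  k <- nrow(x)
  cat(sprintf("<fgk_trace: %d iterations%s>\n", k,
              if (!is.na(attr(x, "stop_iteration")))
                sprintf(", stopping rule fired at %d", attr(x, "stop_iteration"))
              else ""))
  if (k > 0) {
    last <- x[k, ]
    cat(sprintf("  final: lambda=%.4g residual=%.4g rre=%s ssim=%s tv=%.4g\n",
                last$lambda, last$residual,
                formatC(last$rre, digits = 4), formatC(last$ssim, digits = 4),
                last$tv))
  }
  invisible(x)
}

#' Write a solver trace to CSV
#'
#' @param trace an `fgk_trace`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  invisible(file)
}
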