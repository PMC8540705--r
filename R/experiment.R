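#' Write an image vector as a grayscale PNG preview and a lossless CSV
#'
#' The PNG is min-max scaled for viewing; the CSV stores the raw values.
#'
#' @param x image vector.
#' @param N image side.
#' @param path_png,path_csv output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_image <- function(x, N, path_png = NULL, path_csv = NULL) {
  X <- matrix(x, N, N)
  if (!is.null(path_png)) {
    rng <- range(X)
    Xs <- if (diff(rng) > 0) (X - rng[1]) / diff(rng) else X * 0
    png::writePNG(Xs, path_png)
  }
  if (!is.null(path_csv))
    utils::write.table(X, path_csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(c(path_png, path_csv))
}

solver_menu <- c("ftv", "fatv", "fdiag", "lsqr_l", "irn_tv", "irn_atv", "irn_diag")

# fill configuration defaults and validate
normalize_run_config <- function(cfg) {
  defaults <- list(problem = "deblur", solver = "ftv", N = 32,
                   blur_level = "mild", sigma = NULL, retain_fraction = 0.4,
                   trajectory_len = 20, angles = seq(0, 179, by = 2),
                   ncells = 60, noise_level = 0.01, seed = 1,
                   eta = 1.01, xi = 0.9, tau = 1e-10, a = 1, maxit = 200,
                   lambda_mode = "discrepancy", lambda_fixed = 0,
                   include_E = TRUE, exact_pinv = FALSE,
                   stop_at_criterion = TRUE, budget = 200, outer_max = 20,
                   noise_norm = NULL, compute_ssim = TRUE, outdir = NULL,
                   operator_mtx = NULL, data_csv = NULL, truth_csv = NULL,
                   truth_png = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$problem %in% c("deblur", "inpaint", "ct", "custom"))
    stop("unknown problem kind: ", cfg$problem)
  if (!cfg$solver %in% solver_menu)
    stop("unknown solver '", cfg$solver, "'; choose one of: ",
         paste(solver_menu, collapse = ", "))
  cfg
}

build_problem_from_config <- function(cfg) {
  switch(cfg$problem,
    deblur = deblur_problem(cfg$N, blur_level = cfg$blur_level,
                            sigma = cfg$sigma, noise_level = cfg$noise_level,
                            seed = cfg$seed),
    inpaint = inpaint_problem(cfg$N, retain_fraction = cfg$retain_fraction,
                              trajectory_len = cfg$trajectory_len,
                              noise_level = cfg$noise_level, seed = cfg$seed),
    ct = ct_problem(cfg$N, angles = cfg$angles, ncells = cfg$ncells,
                    noise_level = cfg$noise_level, seed = cfg$seed),
    custom = {
      if (is.null(cfg$operator_mtx) || is.null(cfg$data_csv))
        stop("custom problems need operator_mtx and data_csv")
      A <- linop_from_matrix(Matrix::readMM(cfg$operator_mtx),
                             desc = "user operator")
      b <- as.numeric(utils::read.csv(cfg$data_csv, header = FALSE)[[1]])
      xt <- NULL
      if (!is.null(cfg$truth_csv))
        xt <- as.numeric(as.matrix(utils::read.table(cfg$truth_csv, sep = ",")))
      else if (!is.null(cfg$truth_png)) {
        img <- png::readPNG(cfg$truth_png)
        if (length(dim(img)) == 3) img <- img[, , 1]
        xt <- as.vector(img)
      }
      pr <- forward_problem(A, b, x_true = xt, desc = "custom problem")
      pr$noise_norm <- cfg$noise_norm
      pr
    })
}

dispatch_solver <- function(cfg, problem) {
  kind <- switch(cfg$solver,
                 ftv = "tv", fatv = "atv", fdiag = "diag", lsqr_l = "none",
                 irn_tv = "tv", irn_atv = "atv", irn_diag = "diag")
  wcfg <- weight_config(kind, tau = cfg$tau, a = cfg$a)
  if (cfg$solver %in% c("ftv", "fatv", "fdiag")) {
    run_flexible(problem, flex_config(
      weights = wcfg, eta = cfg$eta, xi = cfg$xi, maxit = cfg$maxit,
      noise_norm = cfg$noise_norm, lambda_mode = cfg$lambda_mode,
      lambda_fixed = cfg$lambda_fixed, include_E = cfg$include_E,
      exact_pinv = cfg$exact_pinv, stop_at_criterion = cfg$stop_at_criterion,
      compute_ssim = cfg$compute_ssim))
  } else if (cfg$solver == "lsqr_l") {
    gkb_hybrid(problem, NULL, flex_config(
      weights = wcfg, eta = cfg$eta, xi = cfg$xi, maxit = cfg$maxit,
      noise_norm = cfg$noise_norm, lambda_mode = cfg$lambda_mode,
      lambda_fixed = cfg$lambda_fixed,
      stop_at_criterion = cfg$stop_at_criterion,
      compute_ssim = cfg$compute_ssim))
  } else {
    irn(problem, irn_config(
      weights = wcfg, eta = cfg$eta, xi = cfg$xi, budget = cfg$budget,
      outer_max = cfg$outer_max, maxit = cfg$maxit,
      noise_norm = cfg$noise_norm, compute_ssim = cfg$compute_ssim))
  }
}

#' Run a reproducible reconstruction experiment
#'
#' Builds a synthetic (or user-supplied) forward problem, runs the
#' requested solver and writes a self-describing artifact directory:
#' the configuration as YAML, the per-iteration trace as CSV, phantom /
#' data / reconstruction images (PNG preview plus lossless CSV) and a log
#' recording the seed and the stopping iteration.  The configuration and
#' seed suffice to regenerate every number.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized fields: `problem` (`deblur`, `inpaint`, `ct`, `custom`),
#'   `solver` (`ftv`, `fatv`, `fdiag`, `lsqr_l`, `irn_tv`, `irn_atv`,
#'   `irn_diag`), phantom/operator parameters (`N`, `blur_level`,
#'   `sigma`, `retain_fraction`, `trajectory_len`, `angles`, `ncells`),
#'   `noise_level`, `seed`, solver parameters (`eta`, `xi`, `tau`, `a`,
#'   `maxit`, `lambda_mode`, `lambda_fixed`, `budget`, `outer_max`,
#'   `exact_pinv`, `include_E`, `stop_at_criterion`), and `outdir`.
#' @param quiet suppress the one-line progress message.
#' @return invisibly, a list with `trace`, `problem`, `config`, `outdir`.
#' @export
run_experiment <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- normalize_run_config(config)
  problem <- build_problem_from_config(cfg)
  trace <- dispatch_solver(cfg, problem)
  outdir <- cfg$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                     file.path(outdir, "config.yaml"))
    write_trace_csv(trace, file.path(outdir, "trace.csv"))
    N <- attr(trace, "N")
    if (!is.null(problem$x_true))
      write_image(problem$x_true, N, file.path(outdir, "truth.png"),
                  file.path(outdir, "truth.csv"))
    write_image(attr(trace, "x"), N, file.path(outdir, "reconstruction.png"),
                file.path(outdir, "reconstruction.csv"))
    if (problem$A$m == N * N)
      write_image(problem$b, N, file.path(outdir, "data.png"),
                  file.path(outdir, "data.csv"))
    writeLines(c(sprintf("problem: %s", problem$desc),
                 sprintf("solver: %s", cfg$solver),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("iterations: %d", nrow(trace)),
                 sprintf("stop_iteration: %s", attr(trace, "stop_iteration")),
                 sprintf("first_positive_lambda: %s",
                         attr(trace, "first_positive_lambda"))),
               file.path(outdir, "log.txt"))
  }
  if (!quiet)
    message(sprintf("%s / %s: %d iterations (stopping rule at %s)",
                    cfg$problem, cfg$solver, nrow(trace),
                    attr(trace, "stop_iteration")))
  invisible(list(trace = trace, problem = problem, config = cfg,
                 outdir = outdir))
}

#' Compare several solvers on one shared problem
#'
#' Runs two or more configurations that must describe the same problem
#' and seed, merges their traces (wide CSV keyed by iteration) and, when
#' an output directory is given, draws overlay plots of the RRE, SSIM,
#' total-variation and lambda histories.
#'
#' @param configs list of configuration lists (or YAML paths).
#' @param outdir optional output directory for `merged.csv` and
#'   `overlay.png`.
#' @return invisibly, a list with `merged` (data frame) and `runs`.
#' @export
compare_experiments <- function(configs, outdir = NULL) {
  if (length(configs) < 2)
    warning("comparison of fewer than two configurations is degenerate")
  cfgs <- lapply(configs, function(cc)
    normalize_run_config(if (is.character(cc)) yaml::read_yaml(cc) else cc))
  key <- function(cc) cc[c("problem", "N", "blur_level", "sigma",
                           "retain_fraction", "trajectory_len", "angles",
                           "ncells", "noise_level", "seed")]
  if (length(cfgs) > 1)
    for (k in 2:length(cfgs))
      if (!identical(key(cfgs[[1]]), key(cfgs[[k]])))
        stop("all configurations must share the same problem and seed")
  runs <- lapply(cfgs, function(cc) run_experiment(cc, quiet = TRUE))
  labels <- vapply(cfgs, `[[`, "", "solver")
  merged <- NULL
  for (k in seq_along(runs)) {
    df <- as.data.frame(runs[[k]]$trace)
    keep <- intersect(c("iteration", "lambda", "residual", "rre", "ssim",
                        "tv", "outer"), names(df))
    df <- df[, keep]
    names(df)[-1] <- paste(names(df)[-1], labels[k], sep = ".")
    merged <- if (is.null(merged)) df else
      merge(merged, df, by = "iteration", all = TRUE)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(merged, file.path(outdir, "merged.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(outdir, "overlay.png"), width = 1200,
                   height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(2, 2))
    for (metric in c("rre", "ssim", "tv", "lambda")) {
      cols <- grep(paste0("^", metric, "\\."), names(merged))
      if (!length(cols)) next
      graphics::matplot(merged$iteration, as.matrix(merged[, cols]),
                        type = "l", lty = 1, lwd = 2, xlab = "iteration",
                        ylab = metric, main = metric,
                        log = if (metric == "lambda") "" else "")
      graphics::legend("topright", legend = labels, col = seq_along(cols),
                       lty = 1, lwd = 2, bty = "n")
    }
  }
  invisible(list(merged = merged, runs = runs))
}
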