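# Multistart bound-constrained least-squares fitting of a model to an MMTT
# dataset, with asymptotic uncertainty quantification (CV%, 95% CI) from the
# finite-difference residual Jacobian at the optimum.

#' Multistart configuration
#'
#' The multistart grid takes `n_per_param` initial values per parameter and
#' runs a local bound-constrained least-squares solve from every point of
#' their Cartesian product (`n_per_param^npar` starts). Positive-bounded
#' parameters start from log-spaced values in `positive_grid`; sign-free
#' parameters from linearly spaced values in `signed_grid`. The default
#' ranges bracket all parameter magnitudes this class of model produces on
#' MMTT data by at least an order of magnitude.
#'
#' @param n_per_param initial values per parameter (default 10).
#' @param positive_grid `(low, high)` of the log-spaced grid for positive
#'   parameters (default `c(1e-4, 1)`).
#' @param signed_grid `(low, high)` of the linear grid for sign-free
#'   parameters (default `c(-0.1, 0.1)`).
#' @param function_tol objective tolerance passed to the local solver
#'   (default 1e-20).
#' @param step_tol step-size tolerance of the local solver (default 1e-12).
#' @param max_iterations per-start iteration cap (default 100).
#' @param seed integer seed recorded for provenance (the grid itself is
#'   deterministic).
#' @return an object of class `multistart_config`.
#' @export
multistart_config <- function(n_per_param = 10,
                              positive_grid = c(1e-4, 1),
                              signed_grid = c(-0.1, 0.1),
                              function_tol = 1e-20,
                              step_tol = 1e-12,
                              max_iterations = 100,
                              seed = 1L) {
  if (n_per_param < 1) stop("n_per_param must be >= 1")
  if (positive_grid[1] >= positive_grid[2] || positive_grid[1] <= 0)
    stop("positive_grid must satisfy 0 < low < high")
  if (signed_grid[1] >= signed_grid[2])
    stop("signed_grid must satisfy low < high")
  structure(list(n_per_param = as.integer(n_per_param),
                 positive_grid = positive_grid, signed_grid = signed_grid,
                 function_tol = function_tol, step_tol = step_tol,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "multistart_config")
}

# Cartesian multistart grid: rows are start vectors in parameter-spec order.
multistart_grid <- function(pspec, ms) {
  per_param <- lapply(seq_len(nrow(pspec)), function(i) {
    if (pspec$lower[i] >= 0) {
      exp(seq(log(ms$positive_grid[1]), log(ms$positive_grid[2]),
              length.out = ms$n_per_param))
    } else {
      seq(ms$signed_grid[1], ms$signed_grid[2], length.out = ms$n_per_param)
    }
  })
  as.matrix(expand.grid(per_param, KEEP.OUT.ATTRS = FALSE))
}

theta_to_params <- function(model, theta, pspec) {
  if (model == "M4") list(k_gl = theta[1], k_aa_nodes = theta[-1])
  else stats::setNames(as.list(theta), pspec$name)
}

# Forward finite-difference Jacobian of a residual function, relative step
# 1e-6 with an absolute floor of 1e-8 for near-zero parameters.
fd_jacobian <- function(resid_fn, theta, rel_step = 1e-6) {
  r0 <- resid_fn(theta)
  J <- matrix(NA_real_, nrow = length(r0), ncol = length(theta))
  for (k in seq_along(theta)) {
    h <- max(rel_step * abs(theta[k]), 1e-8)
    th <- theta
    th[k] <- th[k] + h
    J[, k] <- (resid_fn(th) - r0) / h
  }
  J
}

# Asymptotic parameter covariance s^2 (J'J)^-1 with s^2 = RSS/(n - p).
# Returns NULL (non-identifiable) when J'J is numerically singular.
fd_covariance <- function(resid_fn, theta, rss, n) {
  p <- length(theta)
  J <- fd_jacobian(resid_fn, theta)
  jtj <- crossprod(J)
  s2 <- rss / (n - p)
  inv <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  s2 * inv
}

#' Fit a model to an MMTT dataset by multistart least squares
#'
#' Minimises the unweighted residual sum of squares between observed and
#' predicted insulin over all sampling times (pre-meal predictions equal
#' I_b by construction) with a bound-constrained Levenberg-Marquardt solver
#' run from the full multistart grid; the lowest-RSS converged solution is
#' retained. Positive-bounded parameters are constrained to `[0, 1e3]` and
#' sign-free parameters to `[-1e3, 1e3]` (a numerical box standing in for
#' the conceptual infinite bounds; a solution touching the box raises a
#' warning). Uncertainty (CV%, 95% CI) and AICc are attached via
#' [estimate_uncertainty()] and [aicc()].
#'
#' The whole procedure is deterministic given its configuration.
#'
#' @param model one of [model_ids()].
#' @param dataset an [mmtt_dataset()].
#' @param ms a [multistart_config()].
#' @param cfg a [solver_config()].
#' @param aa_node_times,m5_elimination passed to [simulate_insulin()].
#' @return an object of class `model_fit` with elements `model`, `params`,
#'   `estimates` (named vector), `rss`, `n_points`, `predicted` (dense
#'   trajectory), `residuals`, `cv_percent`, `ci95` (2-column matrix),
#'   `aicc`, `n_starts`, `n_converged`, `best_start_index`, `notes`,
#'   `dataset_label`, `observed`.
#' @export
fit_model <- function(model, dataset, ms = multistart_config(),
                      cfg = solver_config(), aa_node_times = c(0, 60, 180),
                      m5_elimination = "as_printed") {
  model <- match.arg(model, model_ids())
  stopifnot(inherits(dataset, "mmtt_dataset"))
  pspec <- model_parameter_spec(model, n_aa_nodes = length(aa_node_times))
  obs_t <- dataset$insulin$times
  obs <- dataset$insulin$values
  notes <- character(0)
  if (stats::sd(obs) == 0) {
    warning("insulin curve carries no information (all samples identical); ",
            "expect a degenerate fit")
    notes <- c(notes, "degenerate fit: flat insulin curve")
  }

  # a failed integration (e.g. overflow during an exploratory step of the
  # local solver) is penalised with large finite residuals so the step is
  # rejected and the search retreats, rather than aborting the start
  resid_fn <- function(theta) {
    tryCatch(
      obs - simulate_insulin(model, theta_to_params(model, theta, pspec),
                             dataset, out_times = obs_t, cfg = cfg,
                             aa_node_times = aa_node_times,
                             m5_elimination = m5_elimination)$insulin,
      error = function(e) rep(1e6, length(obs)))
  }

  starts <- multistart_grid(pspec, ms)
  lower <- ifelse(is.finite(pspec$lower), pspec$lower, -PRACTICAL_BOX)
  upper <- pmin(pspec$upper, PRACTICAL_BOX)
  # epsfcn sets the solver's internal finite-difference step to ~1e-4
  # relative: large enough to dominate the ODE integration noise (~rel_tol),
  # small enough for accurate curvature at these parameter scales
  ctrl <- minpack.lm::nls.lm.control(ftol = ms$function_tol,
                                     ptol = ms$step_tol,
                                     maxiter = ms$max_iterations,
                                     maxfev = ms$max_iterations *
                                       (nrow(pspec) + 2L),
                                     epsfcn = 1e-8)

  # minpack info codes 1-4 are regular convergence; 6-8 mean the requested
  # tolerance is below what the arithmetic supports, i.e. the iterate
  # cannot be improved -- also a converged outcome. Budget-exhausted starts
  # (info 5 = maxfev, -1 = maxiter) are retained as flagged fallbacks, as
  # trust-region least-squares solvers return their current iterate there.
  best <- NULL
  best_idx <- NA_integer_
  best_fallback <- NULL
  fallback_idx <- NA_integer_
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    # the solver's own per-start termination warnings are redundant here:
    # info codes are inspected below and surfaced once, consolidated
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                           fn = resid_fn, control = ctrl)),
      error = function(e) NULL)
    if (is.null(res) || res$deviance >= 1e10) next
    if (res$info %in% c(1:4, 6:8)) {
      n_conv <- n_conv + 1L
      if (is.null(best) || res$deviance < best$deviance) {
        best <- res
        best_idx <- i
      }
    } else if (is.null(best_fallback) ||
               res$deviance < best_fallback$deviance) {
      best_fallback <- res
      fallback_idx <- i
    }
  }
  if (is.null(best) && !is.null(best_fallback)) {
    warning("no multistart attempt met the convergence tolerances for ",
            "model ", model, "; keeping the lowest-RSS iterate from an ",
            "iteration-capped start")
    notes <- c(notes, "best solution reached the iteration budget")
    best <- best_fallback
    best_idx <- fallback_idx
  }
  if (is.null(best))
    stop("estimation failed: no multistart attempt converged for model ",
         model, " on dataset '", dataset$label, "'")

  theta <- stats::setNames(as.numeric(best$par), pspec$name)
  if (any(abs(theta) >= PRACTICAL_BOX * (1 - 1e-8))) {
    warning("fitted parameter(s) at the practical-unboundedness box (1e3); ",
            "the optimum may lie outside the searched region")
    notes <- c(notes, "parameter at practical bound 1e3")
  }

  params <- theta_to_params(model, theta, pspec)
  params$k_i <- K_I_DEFAULT
  residuals <- resid_fn(as.numeric(theta))
  rss <- sum(residuals^2)

  dense_t <- sort(unique(c(obs_t, seq(min(obs_t), max(obs_t),
                                      by = cfg$dense_grid_step))))
  predicted <- simulate_insulin(model, params, dataset, out_times = dense_t,
                                cfg = cfg, aa_node_times = aa_node_times,
                                m5_elimination = m5_elimination)

  fit <- structure(
    list(model = model, params = params, estimates = theta,
         rss = rss, n_points = length(obs), predicted = predicted,
         residuals = residuals, cv_percent = NULL, ci95 = NULL,
         aicc = NA_real_, n_starts = nrow(starts), n_converged = n_conv,
         best_start_index = best_idx, notes = notes,
         dataset_label = dataset$label, observed = obs,
         param_spec = pspec, aa_node_times = aa_node_times,
         m5_elimination = m5_elimination, solver = cfg),
    class = "model_fit")
  fit <- estimate_uncertainty(fit, dataset)
  fit$aicc <- aicc(max(fit$rss, .Machine$double.xmin), fit$n_points,
                   length(theta))
  fit
}

#' Asymptotic uncertainty of a fitted model
#'
#' Computes the parameter covariance as `s^2 (J'J)^-1`, where `J` is the
#' residual Jacobian at the optimum (forward finite differences, relative
#' step 1e-6) and `s^2 = RSS/(n - p)`. Reports per-parameter CV%
#' (`100 * SD / |estimate|`) and 95% confidence intervals
#' (`estimate +/- t(0.975, n - p) * SD`, Student-t quantile). A perfect fit
#' (RSS = 0) gives CV% = 0; a numerically singular `J'J` raises a
#' non-identifiability warning and reports infinite CV%.
#'
#' @param fit a `model_fit` from [fit_model()].
#' @param dataset the [mmtt_dataset()] the model was fitted to.
#' @return the updated `model_fit` with `cv_percent` (named numeric) and
#'   `ci95` (matrix with columns `low`, `high`) filled in.
#' @export
estimate_uncertainty <- function(fit, dataset) {
  stopifnot(inherits(fit, "model_fit"), inherits(dataset, "mmtt_dataset"))
  theta <- fit$estimates
  p <- length(theta)
  n <- fit$n_points
  if (n <= p + 1)
    stop("too few data points (n = ", n, ") for ", p,
         " parameters: need n > p + 1")
  pspec <- fit$param_spec
  obs <- dataset$insulin$values
  resid_fn <- function(th) {
    obs - simulate_insulin(fit$model, theta_to_params(fit$model, th, pspec),
                           dataset, out_times = dataset$insulin$times,
                           cfg = fit$solver,
                           aa_node_times = fit$aa_node_times,
                           m5_elimination = fit$m5_elimination)$insulin
  }
  covm <- fd_covariance(resid_fn, as.numeric(theta), fit$rss, n)
  if (is.null(covm)) {
    warning("J'J is numerically singular at the optimum: model not ",
            "practically identifiable from these data; CV% set to Inf")
    fit$notes <- c(fit$notes, "non-identifiable: singular J'J")
    sds <- rep(Inf, p)
  } else {
    sds <- sqrt(pmax(diag(covm), 0))
  }
  cv <- ifelse(sds == 0, 0, 100 * sds / abs(theta))
  tq <- stats::qt(0.975, df = n - p)
  ci <- cbind(low = as.numeric(theta) - tq * sds,
              high = as.numeric(theta) + tq * sds)
  rownames(ci) <- names(theta)
  fit$cv_percent <- stats::setNames(cv, names(theta))
  fit$ci95 <- ci
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s on '%s': RSS = %.6g (uU/ml)^2, AICc = %.4f\n",
              x$model, x$dataset_label, x$rss, x$aicc))
  cat(sprintf("  %d/%d multistart attempts converged (best: #%d)\n",
              x$n_converged, x$n_starts, x$best_start_index))
  tab <- data.frame(estimate = signif(x$estimates, 6),
                    cv_percent = signif(x$cv_percent, 4),
                    ci95_low = signif(x$ci95[, "low"], 6),
                    ci95_high = signif(x$ci95[, "high"], 6))
  print(tab)
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write a fit report to JSON
#'
#' Serialises a `model_fit` (parameters with units, CV%, 95% CI, RSS, AICc,
#' BR_I, multistart diagnostics) to a JSON file that
#' [read_fit_json()] can load back for population-level analysis.
#'
#' @param fit a `model_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  obj <- list(
    model = fit$model,
    dataset_label = fit$dataset_label,
    estimates = as.list(fit$estimates),
    units = stats::setNames(as.list(fit$param_spec$units),
                            fit$param_spec$name),
    k_i = fit$params$k_i,
    br_i = fit$predicted$br_i,
    rss = fit$rss,
    n_points = fit$n_points,
    aicc = fit$aicc,
    cv_percent = as.list(fit$cv_percent),
    ci95 = stats::setNames(
      lapply(seq_len(nrow(fit$ci95)), function(i) unname(fit$ci95[i, ])),
      rownames(fit$ci95)),
    multistart = list(n_starts = fit$n_starts,
                      n_converged = fit$n_converged,
                      best_start_index = fit$best_start_index),
    notes = fit$notes,
    package_version = as.character(utils::packageVersion("insukin")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit report written by [write_fit_json()]
#'
#' @param path path to a fit-report JSON.
#' @return a list with (at least) `model`, `estimates`, `ci95`, `aicc`,
#'   `rss`, `dataset_label`.
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
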