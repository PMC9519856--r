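# Five candidate models of plasma insulin kinetics during an MMTT.
#
# All models share: insulin appearance driven by plasma glucose (main term)
# and by plasma amino acids (smaller term, sign-free), first-order insulin
# disappearance with fractional rate k_I fixed at 0.14 /min, and a constant
# basal appearance rate BR_I closed from the pre-meal steady state.
#
#   M1: dI/dt = k_GL*G(t)        + k_AA*AA(t)    - k_I*I + BR_I
#   M2: dI/dt = k_GL1*G + k_GL2*dG/dt + k_AA*AA  - k_I*I + BR_I
#   M3: dI/dt = k_GL1*G^k_GL2    + k_AA*AA       - k_I*I + BR_I
#   M4: dI/dt = k_GL*G           + k_AA(t)*AA    - k_I*I + BR_I
#   M5: dI/dt = k_GL*G_rem       + k_AA*AA       - k_I*I + BR_I
#       dG_rem/dt = -k_GL*G_rem + k_GLrem*(G - G_b),  G_rem(0) = 0
#
# G(t) and AA(t) are forcing inputs (piecewise-linear through the samples,
# flat outside); I(0) = I_b at meal start t = 0.

K_I_DEFAULT <- 0.14   # fractional insulin disappearance rate, /min
PRACTICAL_BOX <- 1e3  # numerical stand-in for infinite parameter bounds

#' Admissible model identifiers
#'
#' @return the character vector `c("M1","M2","M3","M4","M5")`.
#' @export
model_ids <- function() c("M1", "M2", "M3", "M4", "M5")

#' Estimated-parameter layout of a model
#'
#' Ordered list of the kinetic parameters estimated for each model, with
#' their conceptual bounds and units. k_I is fixed (not estimated) and BR_I
#' is derived from the steady-state closure, so neither appears here.
#'
#' Model 4's time-varying amino-acid sensitivity k_AA(t) is parameterised as
#' a piecewise-linear function through `n_aa_nodes` free node values (first
#' node = the basal value k_AAb used in its BR_I closure).
#'
#' @param model one of [model_ids()].
#' @param n_aa_nodes number of k_AA(t) nodes for model M4 (default 3).
#' @return a data.frame with columns `name`, `lower`, `upper`, `units`.
#' @export
model_parameter_spec <- function(model, n_aa_nodes = 3) {
  model <- match.arg(model, model_ids())
  u_gl <- "uU/ml per (mg/dl x min)"
  u_aa <- "uU/ml per (umol/l x min)"
  switch(model,
    M1 = data.frame(name = c("k_gl", "k_aa"),
                    lower = c(0, -Inf), upper = c(Inf, Inf),
                    units = c(u_gl, u_aa)),
    M2 = data.frame(name = c("k_gl1", "k_gl2", "k_aa"),
                    lower = c(0, 0, -Inf), upper = c(Inf, Inf, Inf),
                    units = c(u_gl, "uU/ml per (mg/dl)", u_aa)),
    M3 = data.frame(name = c("k_gl1", "k_gl2", "k_aa"),
                    lower = c(0, 0, -Inf), upper = c(Inf, Inf, Inf),
                    units = c("model-dependent (depends on k_gl2)",
                              "dimensionless", u_aa)),
    M4 = data.frame(name = c("k_gl", paste0("k_aa_node", seq_len(n_aa_nodes))),
                    lower = c(0, rep(-Inf, n_aa_nodes)),
                    upper = rep(Inf, n_aa_nodes + 1),
                    units = c(u_gl, rep(u_aa, n_aa_nodes))),
    M5 = data.frame(name = c("k_gl", "k_glrem", "k_aa"),
                    lower = c(0, 0, -Inf), upper = c(Inf, Inf, Inf),
                    units = c(u_gl, "/min", u_aa))
  )
}

required_param_fields <- function(model, n_aa_nodes = 3) {
  switch(model,
    M1 = c("k_gl", "k_aa"),
    M2 = c("k_gl1", "k_gl2", "k_aa"),
    M3 = c("k_gl1", "k_gl2", "k_aa"),
    M4 = c("k_gl", "k_aa_nodes"),
    M5 = c("k_gl", "k_glrem", "k_aa"))
}

validate_params <- function(model, params, n_aa_nodes = 3) {
  model <- match.arg(model, model_ids())
  if (!is.list(params)) stop("params must be a named list")
  req <- required_param_fields(model)
  miss <- setdiff(req, names(params))
  if (length(miss) > 0)
    stop("model ", model, " requires parameter(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(params), c(req, "k_i"))
  if (length(extra) > 0)
    stop("parameter(s) not used by model ", model, ": ",
         paste(extra, collapse = ", "))
  for (nm in req) {
    v <- params[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("parameter ", nm, " must be finite numeric")
  }
  if (model == "M4" && length(params$k_aa_nodes) != n_aa_nodes)
    stop("k_aa_nodes has length ", length(params$k_aa_nodes),
         " but ", n_aa_nodes, " node times are configured")
  pos <- intersect(names(params), c("k_gl", "k_gl1", "k_gl2", "k_glrem"))
  for (nm in pos) {
    if (params[[nm]] < 0)
      stop("parameter ", nm, " must be non-negative")
  }
  ki <- params$k_i %||% K_I_DEFAULT
  if (!is.numeric(ki) || !is.finite(ki) || ki <= 0)
    stop("k_i must be a positive rate (/min)")
  invisible(TRUE)
}

#' Basal insulin appearance rate from the steady-state closure
#'
#' At the pre-meal steady state (I = I_b, G = G_b, AA = AA_b, all derivatives
#' zero) the constant appearance term BR_I is fully determined by the other
#' parameters; it is derived, never estimated. For M5 the remote glucose
#' compartment is empty at basal (G_rem = 0), so glucose drops out of its
#' closure.
#'
#' @param model one of [model_ids()].
#' @param params named list of model parameters (see
#'   [model_parameter_spec()]); may include `k_i` to override the fixed
#'   0.14 /min disappearance rate.
#' @param g_b,i_b,aa_b basal glucose (mg/dl), insulin (uU/ml) and amino
#'   acids (umol/l).
#' @return BR_I in uU/ml/min (may be negative).
#' @examples
#' compute_bri("M1", list(k_gl = 0.1, k_aa = 0.02), 90, 10, 400) # -15.6
#' @export
compute_bri <- function(model, params, g_b, i_b, aa_b) {
  model <- match.arg(model, model_ids())
  n_nodes <- if (model == "M4") length(params$k_aa_nodes) else 3
  validate_params(model, params, n_aa_nodes = n_nodes)
  if (any(c(g_b, i_b, aa_b) <= 0)) stop("basal values must be positive")
  ki <- params$k_i %||% K_I_DEFAULT
  switch(model,
    M1 = -params$k_gl * g_b - params$k_aa * aa_b + ki * i_b,
    M2 = -params$k_gl1 * g_b - params$k_aa * aa_b + ki * i_b,
    M3 = -params$k_gl1 * g_b^params$k_gl2 - params$k_aa * aa_b + ki * i_b,
    M4 = -params$k_gl * g_b - params$k_aa_nodes[1] * aa_b + ki * i_b,
    M5 = -params$k_aa * aa_b + ki * i_b)
}

# Derivative of the piecewise-linear glucose interpolant, used as the dG/dt
# forcing of model M2. It is piecewise constant (left-continuous at knots:
# the derivative at a knot is the slope of the segment ending there);
# encoded as a two-column time/value series whose linear interpolation
# reproduces the step function up to transition windows of width `eps`
# (1e-7 min, far below the solver step).
step_encoding <- function(times, values, eps = 1e-7) {
  slopes <- diff(values) / diff(times)
  n <- length(slopes)
  if (n == 1) return(cbind(range(times), rep(slopes, 2)))
  tt <- c(times[1], rep(times[2:n], each = 2) + rep(c(0, eps), n - 1),
          times[n + 1])
  vv <- c(rep(slopes, each = 2))
  cbind(tt, vv)
}

#' Forward-simulate plasma insulin for one model
#'
#' Integrates the model ODE(s) from meal start (t = 0, I(0) = I_b; also
#' G_rem(0) = 0 for M5) with the dataset's glucose and AA curves as
#' piecewise-linear forcing inputs, using a stiff-capable integrator.
#' Predictions requested at pre-meal times (t < 0) are defined as I_b.
#'
#' For M2 the dG/dt term is the derivative of the piecewise-linear glucose
#' interpolant (piecewise constant, left-continuous at the knots). For M4,
#' k_AA(t) is piecewise-linear through `params$k_aa_nodes` placed at
#' `aa_node_times` (flat outside). For M5 the remote-compartment elimination
#' term defaults to `-k_gl * G_rem` (`m5_elimination = "as_printed"`); set
#' `m5_elimination = "k_glrem"` for the alternative reading in which k_GLrem
#' is the elimination rate from the remote compartment.
#'
#' @param model one of [model_ids()].
#' @param params named list of model parameters.
#' @param dataset an [mmtt_dataset()] providing forcing curves and basal
#'   values.
#' @param out_times times (min) at which to report insulin; defaults to the
#'   dataset sampling schedule.
#' @param cfg a [solver_config()].
#' @param aa_node_times node times for M4's k_AA(t) (default `c(0, 60, 180)`).
#' @param m5_elimination `"as_printed"` or `"k_glrem"` (M5 only, see above).
#' @return an object of class `trajectory`: list with `times`, `insulin`,
#'   `g_rem` (M5 only, else `NULL`), `br_i`, `model`.
#' @export
simulate_insulin <- function(model, params, dataset,
                             out_times = dataset$glucose$times,
                             cfg = solver_config(),
                             aa_node_times = c(0, 60, 180),
                             m5_elimination = c("as_printed", "k_glrem")) {
  model <- match.arg(model, model_ids())
  m5_elimination <- match.arg(m5_elimination)
  stopifnot(inherits(dataset, "mmtt_dataset"))
  validate_params(model, params, n_aa_nodes = length(aa_node_times))
  if (length(out_times) == 0 || any(!is.finite(out_times)))
    stop("out_times must be finite and non-empty")

  gt <- dataset$glucose$times
  gv <- dataset$glucose$values
  ki <- params$k_i %||% K_I_DEFAULT
  bri <- compute_bri(model, params, dataset$g_b, dataset$i_b, dataset$aa_b)

  # parameter slots of the compiled right-hand side (src/insukin_models.c)
  p <- switch(model,
    M1 = c(params$k_gl, params$k_aa, 0, 0),
    M2 = c(params$k_gl1, params$k_gl2, params$k_aa, 0),
    M3 = c(params$k_gl1, params$k_gl2, params$k_aa, 0),
    M4 = c(params$k_gl, 0, 0, 0),
    M5 = c(params$k_gl, params$k_glrem, params$k_aa,
           if (m5_elimination == "as_printed") params$k_gl
           else params$k_glrem))
  parms <- c(match(model, model_ids()), ki, bri, dataset$g_b, p)

  # forcing series: glucose, AA, and a model-specific third signal, all
  # interpolated linearly with flat extrapolation at C level
  trange <- range(gt)
  aux <- switch(model,
    M2 = step_encoding(gt, gv),                      # left-continuous dG/dt
    M4 = if (length(aa_node_times) > 1)
           cbind(aa_node_times, params$k_aa_nodes)
         else cbind(trange, rep(params$k_aa_nodes, 2)),
    cbind(trange, c(0, 0)))
  forcings <- list(cbind(gt, gv),
                   cbind(dataset$aa$times, dataset$aa$values),
                   aux)

  y0 <- if (model == "M5") c(I = dataset$i_b, Grem = 0) else c(I = dataset$i_b)
  t_pos <- sort(unique(c(0, out_times[out_times >= 0])))
  if (length(t_pos) > 1) {
    sol <- tryCatch(
      deSolve::ode(y = y0, times = t_pos, func = "insukin_deriv",
                   parms = parms, dllname = "insukin",
                   initfunc = "insukin_initmod",
                   initforc = "insukin_initforc", forcings = forcings,
                   fcontrol = list(method = "linear", rule = 2),
                   method = "lsoda", rtol = cfg$rel_tol, atol = cfg$abs_tol,
                   hmax = cfg$max_step),
      warning = function(w) stop("integration failed for model ", model,
                                 " with parameters [",
                                 paste(signif(unlist(params), 6),
                                       collapse = ", "),
                                 "]: ", conditionMessage(w)),
      error = function(e) stop("integration failed for model ", model,
                               " with parameters [",
                               paste(signif(unlist(params), 6),
                                     collapse = ", "),
                               "]: ", conditionMessage(e)))
    if (nrow(sol) != length(t_pos) || any(!is.finite(sol[, "I"])))
      stop("integration failed for model ", model,
           ": non-finite or truncated solution")
    ins_pos <- sol[, "I"]
    grem_pos <- if (model == "M5") sol[, "Grem"] else NULL
  } else {
    ins_pos <- dataset$i_b
    grem_pos <- if (model == "M5") 0 else NULL
  }

  idx <- match(pmax(out_times, 0), t_pos)
  insulin <- ifelse(out_times < 0, dataset$i_b, ins_pos[idx])
  g_rem <- if (model == "M5") ifelse(out_times < 0, 0, grem_pos[idx]) else NULL

  structure(list(times = out_times, insulin = insulin, g_rem = g_rem,
                 br_i = bri, model = model),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> model %s, %d time points, BR_I = %.4g uU/ml/min\n",
              x$model, length(x$times), x$br_i))
  invisible(x)
}

#' Export a simulated trajectory to CSV
#'
#' Columns `time`, `insulin_pred` and, for M5, `g_rem`.
#'
#' @param traj a `trajectory` from [simulate_insulin()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time = traj$times, insulin_pred = traj$insulin)
  if (!is.null(traj$g_rem)) df$g_rem <- traj$g_rem
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
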