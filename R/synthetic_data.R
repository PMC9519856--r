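# Synthetic MMTT curve generator.
#
# Produces template mean +/- SD curves with the qualitative MMTT shape
# (basal plateau before the meal, single postprandial peak, partial return
# toward basal by 180 min) and known-parameter datasets in which insulin is
# forward-simulated from a chosen model, so that estimation and selection
# can be exercised against a known ground truth. The suprabasal excursion is
# a gamma-like bump A * (t/tp)^a * exp(a * (1 - t/tp)) whose shape exponent
# is solved from the requested residual fraction at 180 min. These shapes
# are package inventions for testing: they are not digitised from any
# published figure.

MMTT_SCHEDULE <- c(-10, -1, 10, 20, 30, 60, 90, 120, 180)

#' Template specification for synthetic MMTT curves
#'
#' Defaults describe two stylised groups: `cnt_like` (normal glucose
#' tolerance: lower basal glucose, early sharp glucose peak, near-complete
#' return to basal, brisk insulin response) and `t2d_like` (type-2-diabetes
#' like: higher basal glucose, larger and later glucose excursion with
#' incomplete return, blunted insulin response). Any field can be
#' overridden.
#'
#' @param group `"cnt_like"` or `"t2d_like"` (selects the defaults).
#' @param g_b,i_b,aa_b basal glucose (mg/dl), insulin (uU/ml), amino acids
#'   (umol/l).
#' @param amp named numeric `(glucose, insulin, aa)`: peak suprabasal
#'   amplitudes (same units as the curves), all >= 0.
#' @param peak_time named numeric: peak times (min), within (0, 180).
#' @param return_frac named numeric in `[0, 1]`: fraction of the excursion
#'   recovered toward basal by 180 min.
#' @param rel_sd named numeric: per-quantity relative SD (SD = rel_sd x
#'   mean) used for template SD bands.
#' @return an object of class `curve_template_spec`.
#' @export
curve_template_spec <- function(group = c("cnt_like", "t2d_like"),
                                g_b = NULL, i_b = NULL, aa_b = NULL,
                                amp = NULL, peak_time = NULL,
                                return_frac = NULL, rel_sd = NULL) {
  group <- match.arg(group)
  defaults <- if (group == "cnt_like") {
    list(g_b = 90, i_b = 8, aa_b = 420,
         amp = c(glucose = 45, insulin = 48, aa = 180),
         peak_time = c(glucose = 30, insulin = 40, aa = 60),
         return_frac = c(glucose = 0.9, insulin = 0.85, aa = 0.6),
         rel_sd = c(glucose = 0.08, insulin = 0.22, aa = 0.10))
  } else {
    # AA peaks later than glucose: amino-acid absorption from a
    # high-protein meal is slower and more sustained, which also keeps the
    # two forcing shapes distinguishable for estimation
    list(g_b = 145, i_b = 11, aa_b = 460,
         amp = c(glucose = 95, insulin = 28, aa = 210),
         peak_time = c(glucose = 60, insulin = 60, aa = 90),
         return_frac = c(glucose = 0.55, insulin = 0.7, aa = 0.5),
         rel_sd = c(glucose = 0.10, insulin = 0.25, aa = 0.10))
  }
  spec <- defaults
  for (nm in c("g_b", "i_b", "aa_b", "amp", "peak_time", "return_frac",
               "rel_sd")) {
    ov <- get(nm)
    if (!is.null(ov)) {
      if (nm %in% c("g_b", "i_b", "aa_b")) spec[[nm]] <- ov
      else {
        bad <- setdiff(names(ov), c("glucose", "insulin", "aa"))
        if (length(bad)) stop("unknown quantity in ", nm, ": ",
                              paste(bad, collapse = ", "))
        spec[[nm]][names(ov)] <- ov
      }
    }
  }
  if (any(c(spec$g_b, spec$i_b, spec$aa_b) <= 0))
    stop("basal values must be positive")
  if (any(spec$amp < 0)) stop("amplitudes must be >= 0")
  if (any(spec$peak_time <= 0 | spec$peak_time >= 180))
    stop("peak times must lie within (0, 180) min")
  if (any(spec$return_frac < 0 | spec$return_frac > 1))
    stop("return fractions must lie in [0, 1]")
  if (any(spec$rel_sd < 0)) stop("relative SDs must be >= 0")
  structure(c(list(group = group), spec), class = "curve_template_spec")
}

# Suprabasal bump, normalised to peak value 1 at t = tp; the shape exponent
# is chosen so that the value at 180 min equals the residual fraction
# 1 - return_frac.
mmtt_bump <- function(t, peak_time, return_frac) {
  residual <- min(max(1 - return_frac, 1e-8), 1)
  x180 <- 180 / peak_time
  a <- if (residual >= 1) 0 else log(residual) / (log(x180) + 1 - x180)
  ifelse(t <= 0, 0, (t / peak_time)^a * exp(a * (1 - t / peak_time)))
}

#' Build a template MMTT dataset (mean +/- SD curves)
#'
#' Evaluates the spec's shapes on the standard MMTT sampling schedule
#' (-10, -1, 10, 20, 30, 60, 90, 120, 180 min), with SD = rel_sd x mean at
#' every sample.
#'
#' @param spec a [curve_template_spec()].
#' @return an [mmtt_dataset()] with SDs, labelled by the spec group.
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "curve_template_spec"))
  basal <- c(glucose = spec$g_b, insulin = spec$i_b, aa = spec$aa_b)
  curves <- lapply(c("glucose", "insulin", "aa"), function(q) {
    m <- basal[[q]] + spec$amp[[q]] *
      mmtt_bump(MMTT_SCHEDULE, spec$peak_time[[q]], spec$return_frac[[q]])
    sampled_curve(MMTT_SCHEDULE, m, sds = spec$rel_sd[[q]] * m, quantity = q)
  })
  mmtt_dataset(curves[[1]], curves[[2]], curves[[3]], label = spec$group)
}

#' Noise configuration for synthetic insulin observations
#'
#' @param insulin_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise on insulin (fraction, `0 <= cv < 0.5`).
#' @param seed integer seed.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(insulin_cv = 0.05, seed = 1L) {
  if (insulin_cv < 0 || insulin_cv >= 0.5)
    stop("insulin_cv must lie in [0, 0.5)")
  structure(list(insulin_cv = insulin_cv, seed = as.integer(seed)),
            class = "noise_config")
}

#' Generate a dataset with known generating parameters
#'
#' Builds glucose and AA input curves from a template spec, forward-
#' simulates insulin with the requested model and parameters (basal insulin
#' from the spec), samples everything on the MMTT schedule, and applies
#' multiplicative Gaussian noise to the insulin samples. The noise deviates
#' are truncated at +/- 3 CV so that no sample can become non-physical
#' (negative); with `insulin_cv = 0` the insulin samples equal the simulated
#' trajectory exactly. Inputs (glucose, AA) are treated as exactly known:
#' noise acts on insulin only, matching the error model assumed by the
#' estimator.
#'
#' @param model one of [model_ids()].
#' @param params named list of generating parameters for `model`.
#' @param spec a [curve_template_spec()] shaping the inputs.
#' @param noise a [noise_config()].
#' @param cfg a [solver_config()].
#' @param aa_node_times,m5_elimination passed to [simulate_insulin()].
#' @return list with `dataset` (an [mmtt_dataset()]) and `truth` (list:
#'   `model`, `params`, `seed`, `insulin_true` at the schedule).
#' @export
make_known_parameter_dataset <- function(model, params, spec,
                                         noise = noise_config(0),
                                         cfg = solver_config(),
                                         aa_node_times = c(0, 60, 180),
                                         m5_elimination = "as_printed") {
  stopifnot(inherits(spec, "curve_template_spec"),
            inherits(noise, "noise_config"))
  template <- make_template(spec)
  # flat insulin placeholder: only its basal value feeds the simulation
  flat_ins <- sampled_curve(MMTT_SCHEDULE, rep(spec$i_b, length(MMTT_SCHEDULE)),
                            quantity = "insulin")
  input_ds <- mmtt_dataset(template$glucose, flat_ins, template$aa,
                           label = template$label)
  traj <- simulate_insulin(model, params, input_ds, out_times = MMTT_SCHEDULE,
                           cfg = cfg, aa_node_times = aa_node_times,
                           m5_elimination = m5_elimination)
  ins_true <- traj$insulin
  cv <- noise$insulin_cv
  if (cv > 0) {
    set.seed(noise$seed)
    z <- stats::rnorm(length(ins_true))
    z <- pmin(pmax(z, -3), 3)
    ins_obs <- ins_true * (1 + cv * z)
    ins_sds <- cv * ins_true
  } else {
    ins_obs <- ins_true
    ins_sds <- NULL
  }
  dataset <- mmtt_dataset(
    template$glucose,
    sampled_curve(MMTT_SCHEDULE, ins_obs, sds = ins_sds,
                  quantity = "insulin"),
    template$aa,
    label = sprintf("%s_%s_synth", spec$group, model))
  list(dataset = dataset,
       truth = list(model = model, params = params, seed = noise$seed,
                    insulin_true = ins_true))
}
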