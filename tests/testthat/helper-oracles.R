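# Independent oracles: an R-level ODE integration of each model (separate
# code path from the package's compiled right-hand sides) and the analytic
# solution of the single-compartment linear model under constant inputs.

`%or%` <- function(a, b) if (is.null(a)) b else a

# R-closure re-statement of the model equations, integrated with deSolve
# directly; used to cross-check the compiled simulation path.
r_level_simulate <- function(model, params, dataset, out_times,
                             m5_elimination = "as_printed") {
  ki <- params$k_i %or% 0.14
  gt <- dataset$glucose$times
  gv <- dataset$glucose$values
  gfun <- approxfun(gt, gv, rule = 2)
  aafun <- approxfun(dataset$aa$times, dataset$aa$values, rule = 2)
  bri <- compute_bri(model, params, dataset$g_b, dataset$i_b, dataset$aa_b)
  slopes <- diff(gv) / diff(gt)
  dgfun <- function(t) {
    j <- findInterval(t, gt, left.open = TRUE)
    c(0, slopes, 0)[j + 1]
  }
  kaafun <- if (model == "M4")
    approxfun(c(0, 60, 180), params$k_aa_nodes, rule = 2) else NULL
  rhs <- function(t, y, p) {
    switch(model,
      M1 = list(params$k_gl * gfun(t) + params$k_aa * aafun(t) -
                  ki * y[1] + bri),
      M2 = list(params$k_gl1 * gfun(t) + params$k_gl2 * dgfun(t) +
                  params$k_aa * aafun(t) - ki * y[1] + bri),
      M3 = list(params$k_gl1 * gfun(t)^params$k_gl2 +
                  params$k_aa * aafun(t) - ki * y[1] + bri),
      M4 = list(params$k_gl * gfun(t) + kaafun(t) * aafun(t) -
                  ki * y[1] + bri),
      M5 = {
        elim <- if (m5_elimination == "as_printed") params$k_gl
                else params$k_glrem
        list(c(params$k_gl * y[2] + params$k_aa * aafun(t) - ki * y[1] + bri,
               -elim * y[2] + params$k_glrem * (gfun(t) - dataset$g_b)))
      })
  }
  y0 <- if (model == "M5") c(I = dataset$i_b, Grem = 0)
        else c(I = dataset$i_b)
  tpos <- sort(unique(c(0, out_times[out_times >= 0])))
  sol <- deSolve::ode(y0, tpos, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ifelse(out_times < 0, dataset$i_b, sol[match(pmax(out_times, 0), tpos), "I"])
}

# Analytic solution of dI/dt = k_gl*G + k_aa*AA - k_i*I + BR_I with
# constant post-meal inputs G_b + dg, AA_b + daa and I(0) = I_b:
#   I(t) = I_b + (k_gl*dg + k_aa*daa)/k_i * (1 - exp(-k_i*t))
m1_step_solution <- function(t, params, i_b, dg = 0, daa = 0) {
  ki <- params$k_i %or% 0.14
  s <- params$k_gl * dg + params$k_aa * daa
  ifelse(t < 0, i_b, i_b + s / ki * (1 - exp(-ki * t)))
}
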