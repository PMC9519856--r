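# Shared fixtures, all built in code.

MMTT_TIMES <- c(-10, -1, 10, 20, 30, 60, 90, 120, 180)

# Constant-basal dataset: every curve flat at its basal value.
flat_dataset <- function(g = 90, i = 10, aa = 400) {
  mmtt_dataset(
    sampled_curve(MMTT_TIMES, rep(g, 9), quantity = "glucose"),
    sampled_curve(MMTT_TIMES, rep(i, 9), quantity = "insulin"),
    sampled_curve(MMTT_TIMES, rep(aa, 9), quantity = "aa"),
    label = "flat")
}

# Step inputs: basal before the meal, basal + step from t = 0 onward
# (the piecewise-linear forcing ramps only on the pre-meal segment
# [-1, 0], so the post-meal input is exactly constant).
step_dataset <- function(g_step = 0, aa_step = 0, g_b = 90, i_b = 10,
                         aa_b = 400) {
  tt <- c(-10, -1, 0, 10, 20, 30, 60, 90, 120, 180)
  mmtt_dataset(
    sampled_curve(tt, c(g_b, g_b, rep(g_b + g_step, 8)), quantity = "glucose"),
    sampled_curve(tt, rep(i_b, 10), quantity = "insulin"),
    sampled_curve(tt, c(aa_b, aa_b, rep(aa_b + aa_step, 8)), quantity = "aa"),
    label = "step")
}

# Parameters under which each model's basal closure holds for all t:
# for M4 the time-varying k_AA(t) must sit at its basal node throughout,
# otherwise constant-basal inputs legitimately move insulin off I_b.
steady_params <- function(model) {
  p <- demo_params(model)
  if (model == "M4") p$k_aa_nodes <- rep(p$k_aa_nodes[1], 3)
  p
}

# Admissible demonstration parameters for each model.
demo_params <- function(model) {
  switch(model,
    M1 = list(k_gl = 0.1, k_aa = 0.02),
    M2 = list(k_gl1 = 0.08, k_gl2 = 0.3, k_aa = 0.02),
    M3 = list(k_gl1 = 0.05, k_gl2 = 1.1, k_aa = 0.02),
    M4 = list(k_gl = 0.1, k_aa_nodes = c(0.02, -0.01, 0.01)),
    M5 = list(k_gl = 0.5, k_glrem = 0.05, k_aa = 0.02))
}

# Minimal fit-like object for exercising ranking/summary logic in
# isolation from the estimator.
make_fit_stub <- function(model = "M1", aicc = 0, label = "ds",
                          obs = as.numeric(1:9), k_gl = 0.1, k_aa = 0.01,
                          ci_aa = c(-0.01, 0.02), notes = character(0)) {
  ci <- rbind(k_gl = c(low = k_gl * 0.5, high = k_gl * 1.5),
              k_aa = c(low = ci_aa[1], high = ci_aa[2]))
  structure(list(model = model, aicc = aicc, dataset_label = label,
                 observed = obs,
                 estimates = c(k_gl = k_gl, k_aa = k_aa),
                 ci95 = ci, notes = notes),
            class = "model_fit")
}

write_mmtt_fixture_csv <- function(path, times = MMTT_TIMES) {
  df <- data.frame(time = times,
                   glucose_mean = 90 + pmax(0, 40 - abs(times - 30)),
                   insulin_mean = 10 + pmax(0, 30 - abs(times - 40)),
                   aa_mean = 400 + pmax(0, 150 - abs(times - 60)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
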