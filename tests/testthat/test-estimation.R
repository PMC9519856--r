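cnt_spec <- curve_template_spec("cnt_like")

test_that("noiseless generating parameters are recovered exactly", {
  gen <- make_known_parameter_dataset("M1",
                                      list(k_gl = 0.0974, k_aa = 0.0247),
                                      cnt_spec)
  fit <- fit_model("M1", gen$dataset, ms = multistart_config(n_per_param = 3))
  expect_lt(abs(fit$estimates["k_gl"] - 0.0974) / 0.0974, 1e-3)
  expect_lt(abs(fit$estimates["k_aa"] - 0.0247) / 0.0247, 1e-3)
  expect_equal(fit$n_points, 9)
  expect_gt(fit$n_converged, 0)
  expect_lte(fit$n_converged, fit$n_starts)
  # 95% CI brackets the estimate and uses the t quantile with n - p = 7 df
  sd_kgl <- fit$cv_percent["k_gl"] / 100 * abs(fit$estimates["k_gl"])
  expect_equal(unname(fit$ci95["k_gl", "high"] - fit$estimates["k_gl"]),
               unname(qt(0.975, 7) * sd_kgl), tolerance = 1e-10)
  expect_true(all(fit$ci95[, "low"] <= fit$estimates &
                    fit$estimates <= fit$ci95[, "high"]))
})

test_that("a null AA effect is recovered as statistically negligible", {
  # noiseless: the estimate collapses onto zero at solver precision
  gen <- make_known_parameter_dataset("M1", list(k_gl = 0.0974, k_aa = 0),
                                      cnt_spec)
  fit <- fit_model("M1", gen$dataset, ms = multistart_config(n_per_param = 3))
  expect_lt(abs(fit$estimates["k_aa"]), 1e-6)
  # at measurement noise: the individual 95% CI covers zero in most
  # replicates (nominally 95%)
  covered <- 0
  for (s in 1:10) {
    gs <- make_known_parameter_dataset("M1", list(k_gl = 0.0974, k_aa = 0),
                                       cnt_spec,
                                       noise = noise_config(0.02, seed = s))
    f <- fit_model("M1", gs$dataset, ms = multistart_config(n_per_param = 2))
    if (f$ci95["k_aa", "low"] <= 0 && f$ci95["k_aa", "high"] >= 0)
      covered <- covered + 1
  }
  expect_gte(covered, 8)
})

test_that("a flat insulin curve yields a degenerate non-identifiable fit", {
  # with all curves flat at basal, the steady-state closure makes EVERY
  # parameter vector fit exactly (RSS = 0): the fit must flag this rather
  # than pretend the parameters mean anything
  ds <- flat_dataset()
  warns <- character(0)
  fit <- withCallingHandlers(
    fit_model("M1", ds, ms = multistart_config(n_per_param = 2)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_match(warns, "degenerate", all = FALSE)
  expect_lt(fit$rss, 1e-10)
  expect_gte(fit$estimates["k_gl"], 0)
  expect_true(any(grepl("non-identifiable", fit$notes)) ||
                all(fit$cv_percent == 0))
})

test_that("finite-difference covariance matches the linear-regression SE", {
  # straight line through the origin, y = a*x + noise: the closed-form
  # standard error of a is sqrt(s^2 / sum(x^2))
  x <- c(1, 2, 3, 4, 5)
  set.seed(7)
  y <- 2 * x + rnorm(5, sd = 0.3)
  resid_fn <- function(theta) y - theta[1] * x
  a_hat <- sum(x * y) / sum(x^2)
  rss <- sum((y - a_hat * x)^2)
  covm <- insukin:::fd_covariance(resid_fn, a_hat, rss, n = 5)
  se_closed_form <- sqrt(rss / (5 - 1) / sum(x^2))
  expect_equal(sqrt(covm[1, 1]), se_closed_form, tolerance = 1e-6)
  # and a perfect fit has zero variance, hence CV% = 0
  cov0 <- insukin:::fd_covariance(resid_fn, a_hat, 0, n = 5)
  expect_equal(cov0[1, 1], 0)
})

test_that("uncertainty for M1 agrees with the linear-design oracle", {
  # M1's prediction is affine in (k_gl, k_aa), so the fit is a linear
  # regression in disguise: build the design by simulation and compare SEs
  gen <- make_known_parameter_dataset("M1",
                                      list(k_gl = 0.0974, k_aa = 0.0247),
                                      cnt_spec,
                                      noise = noise_config(0.05, seed = 21))
  ds <- gen$dataset
  fit <- fit_model("M1", ds, ms = multistart_config(n_per_param = 2))
  base <- simulate_insulin("M1", list(k_gl = 0, k_aa = 0), ds)$insulin
  b_gl <- simulate_insulin("M1", list(k_gl = 1, k_aa = 0), ds)$insulin - base
  b_aa <- simulate_insulin("M1", list(k_gl = 0, k_aa = 1), ds)$insulin - base
  lmfit <- lm(I(ds$insulin$values - base) ~ 0 + b_gl + b_aa)
  expect_equal(unname(coef(lmfit)), unname(fit$estimates), tolerance = 1e-4)
  se_lm <- summary(lmfit)$coefficients[, "Std. Error"]
  se_fit <- fit$cv_percent / 100 * abs(fit$estimates)
  # both routes carry their own finite-difference/integration noise
  expect_equal(unname(se_fit), unname(se_lm), tolerance = 0.02)
})

test_that("restarting from the optimum reproduces it (idempotence)", {
  gen <- make_known_parameter_dataset("M1",
                                      list(k_gl = 0.0974, k_aa = 0.0247),
                                      cnt_spec,
                                      noise = noise_config(0.05, seed = 3))
  fit <- fit_model("M1", gen$dataset,
                   ms = multistart_config(n_per_param = 3))
  kgl <- unname(fit$estimates["k_gl"])
  kaa <- unname(fit$estimates["k_aa"])
  pin <- multistart_config(n_per_param = 1,
                           positive_grid = c(kgl, kgl * (1 + 1e-9)),
                           signed_grid = c(kaa, kaa + 1e-12))
  refit <- fit_model("M1", gen$dataset, ms = pin)
  expect_equal(refit$estimates, fit$estimates, tolerance = 1e-3)
  expect_lt(refit$rss - fit$rss, 1e-4)
})

test_that("positivity bounds are respected under adverse data", {
  # insulin falls after the meal although glucose rises: the best
  # non-negative glucose sensitivity is at/near the bound, never below it
  tt <- MMTT_TIMES
  fall <- 10 * exp(-pmax(tt, 0) / 80)
  ds <- mmtt_dataset(
    sampled_curve(tt, 90 + pmax(0, 40 - abs(tt - 30)), quantity = "glucose"),
    sampled_curve(tt, fall, quantity = "insulin"),
    sampled_curve(tt, rep(400, 9), quantity = "aa"),
    label = "falling")
  fit <- fit_model("M1", ds, ms = multistart_config(n_per_param = 3))
  expect_gte(fit$estimates["k_gl"], 0)
  for (seed in 1:4) {
    gen <- make_known_parameter_dataset(
      "M1", list(k_gl = 0.0974, k_aa = 0.0247), cnt_spec,
      noise = noise_config(0.05, seed = seed))
    f <- fit_model("M1", gen$dataset, ms = multistart_config(n_per_param = 2))
    expect_gte(f$estimates["k_gl"], 0)
  }
})

test_that("estimate_uncertainty guards its degrees of freedom", {
  gen <- make_known_parameter_dataset("M1",
                                      list(k_gl = 0.0974, k_aa = 0.0247),
                                      cnt_spec)
  fit <- fit_model("M1", gen$dataset, ms = multistart_config(n_per_param = 2))
  fit$n_points <- 3  # pretend only 3 points were fitted
  expect_error(estimate_uncertainty(fit, gen$dataset), "n > p \\+ 1")
})

test_that("fit reports serialise to JSON and back", {
  gen <- make_known_parameter_dataset("M1",
                                      list(k_gl = 0.0974, k_aa = 0.0247),
                                      cnt_spec)
  fit <- fit_model("M1", gen$dataset, ms = multistart_config(n_per_param = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$model, "M1")
  expect_equal(back$estimates$k_gl, unname(fit$estimates["k_gl"]))
  expect_equal(unlist(back$ci95$k_aa), unname(fit$ci95["k_aa", ]))
  expect_equal(back$aicc, fit$aicc)
  expect_equal(back$multistart$n_starts, 4)
})
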