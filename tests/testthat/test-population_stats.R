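test_that("k_aa CI classification is exhaustive and matches the rule", {
  expect_equal(classify_kaa(0.0168, 0.0325), "positive")
  expect_equal(classify_kaa(-0.0281, 0.0185), "negligible")
  expect_equal(classify_kaa(-0.02, -0.01), "negative")
  # endpoints touching zero count as crossing (inclusive)
  expect_equal(classify_kaa(0, 0.1), "negligible")
  expect_equal(classify_kaa(-0.1, 0), "negligible")
  expect_error(classify_kaa(0.1, -0.1), "inverted")
  # exhaustive partition over random valid intervals
  set.seed(3)
  for (i in 1:100) {
    ci <- sort(runif(2, -1, 1))
    cls <- classify_kaa(ci[1], ci[2])
    expect_true(cls %in% c("positive", "negative", "negligible"))
    expect_equal(cls == "positive", ci[1] > 0)
    expect_equal(cls == "negative", ci[2] < 0)
  }
})

test_that("population summaries report classes and correlation", {
  fits <- list(make_fit_stub(k_gl = 1, k_aa = 3, ci_aa = c(0.01, 0.02)),
               make_fit_stub(k_gl = 2, k_aa = 2, ci_aa = c(-0.02, -0.01)),
               make_fit_stub(k_gl = 3, k_aa = 1, ci_aa = c(-0.1, 0.1)))
  s <- summarize_population(fits, label = "toy")
  expect_equal(s$n, 3)
  expect_equal(as.numeric(s$class_counts), c(1, 1, 1))
  expect_equal(sum(s$class_percent), 100)
  expect_equal(s$pearson_r, -1, tolerance = 1e-12)
  expect_equal(s$k_gl_mean, 2)

  # two-fit case: 50% positive, 50% negative, 0% negligible
  two <- summarize_population(
    list(make_fit_stub(ci_aa = c(0.01, 0.02)),
         make_fit_stub(ci_aa = c(-0.02, -0.01))), "pair")
  expect_equal(two$class_percent, c(50, 50, 0))

  # hand-computed Pearson correlation: r = 11/sqrt(130)
  fits4 <- mapply(make_fit_stub, k_gl = 1:4, k_aa = c(2, 4, 5, 9),
                  SIMPLIFY = FALSE)
  s4 <- summarize_population(fits4, "hand")
  expect_equal(s4$pearson_r, 11 / sqrt(130), tolerance = 1e-10)
  expect_equal(s4$pearson_r, 0.9647638, tolerance = 1e-6)

  expect_error(summarize_population(list(make_fit_stub()), "x"),
               "at least 2")
})

test_that("identical groups compare as null across all tests", {
  fits <- lapply(1:6, function(i)
    make_fit_stub(k_gl = 0.1 * i, k_aa = 0.01 * i,
                  ci_aa = if (i %% 2) c(0.001, 0.02) else c(-0.01, 0.01)))
  cmp <- suppressWarnings(compare_groups(fits, fits, labels = c("X", "Y")))
  expect_equal(cmp$t_k_gl$statistic, 0)
  expect_equal(cmp$t_k_gl$p_value, 1)
  expect_equal(cmp$t_k_aa$statistic, 0)
  expect_equal(cmp$chisq$statistic, 0, tolerance = 1e-12)
})

test_that("group tests agree with closed-form hand computations", {
  # chi-square of independence on [[25,25,0],[0,25,25]]: expected counts
  # are (12.5, 25, 12.5) per row, so X2 = 4 * 12.5^2/12.5 = 50, df = 2
  fits_a <- c(lapply(1:25, function(i) make_fit_stub(ci_aa = c(1, 2))),
              lapply(1:25, function(i) make_fit_stub(ci_aa = c(-1, 1))))
  fits_b <- c(lapply(1:25, function(i) make_fit_stub(ci_aa = c(-2, -1))),
              lapply(1:25, function(i) make_fit_stub(ci_aa = c(-1, 1))))
  cmp <- compare_groups(fits_a, fits_b)
  expect_equal(unname(cmp$chisq$statistic), 50, tolerance = 1e-10)
  expect_equal(unname(cmp$chisq$df), 2)
  expect_equal(unname(cmp$chisq$p_value),
               pchisq(50, df = 2, lower.tail = FALSE), tolerance = 1e-10)

  # Welch t statistic against its textbook formula
  x <- c(0.01, 0.013, 0.02, 0.011, 0.017)
  y <- c(0.002, 0.004, 0.001, 0.006, 0.003)
  fa <- lapply(x, function(v) make_fit_stub(k_gl = 0.1, k_aa = v))
  fb <- lapply(y, function(v) make_fit_stub(k_gl = 0.1, k_aa = v))
  cmp2 <- compare_groups(fa, fb)
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 5 + var(y) / 5)
  expect_equal(cmp2$t_k_aa$statistic, t_hand, tolerance = 1e-10)
  expect_false(cmp2$t_k_aa$log_transformed)

  # clearly separated groups give a tiny p-value
  fa2 <- lapply(c(1, 2, 3), function(v) make_fit_stub(k_gl = v))
  fb2 <- lapply(c(101, 102, 103), function(v) make_fit_stub(k_gl = v))
  expect_lt(compare_groups(fa2, fb2)$t_k_gl$p_value, 1e-6)
})

test_that("the log-transform rule fires only for skewed positive k_gl", {
  set.seed(8)
  skewed <- exp(rnorm(40, sd = 1.5))
  fa <- lapply(skewed[1:20], function(v) make_fit_stub(k_gl = v))
  fb <- lapply(skewed[21:40] * 2, function(v) make_fit_stub(k_gl = v))
  cmp <- compare_groups(fa, fb)
  expect_true(cmp$t_k_gl$log_transformed)
  expect_false(cmp$t_k_aa$log_transformed)  # sign-free, never transformed
  # symmetric samples stay untransformed
  sym <- lapply(seq(0.1, 0.5, length.out = 10),
                function(v) make_fit_stub(k_gl = v))
  expect_false(compare_groups(sym, sym)$t_k_gl$log_transformed)
})

test_that("classes absent from both groups are dropped with a warning", {
  fa <- lapply(1:5, function(i) make_fit_stub(ci_aa = c(1, 2)))
  fb <- c(lapply(1:3, function(i) make_fit_stub(ci_aa = c(1, 2))),
          lapply(1:2, function(i) make_fit_stub(ci_aa = c(-1, 1))))
  expect_warning(cmp <- compare_groups(fa, fb), "negative")
  expect_equal(colnames(cmp$chisq$table), c("positive", "negligible"))
  expect_equal(cmp$chisq$dropped_classes, "negative")
})

test_that("interaction regression recovers exact linear structure", {
  k_gl <- rep(seq(0.05, 0.5, length.out = 10), 2)
  group <- rep(c("A", "B"), each = 10)
  k_aa <- ifelse(group == "A", 2 - 3 * k_gl, 3 - 3 * k_gl)
  reg <- regress_interaction(k_gl, k_aa, group)
  est <- setNames(reg$coefficients$estimate, reg$coefficients$term)
  expect_equal(unname(est["k_gl"]), -3, tolerance = 1e-10)
  expect_equal(unname(est["groupB"]), 1, tolerance = 1e-10)
  expect_equal(unname(est["k_gl:groupB"]), 0, tolerance = 1e-10)
  expect_error(regress_interaction(k_gl, k_aa, rep("A", 20)),
               "single level")
  expect_error(regress_interaction(k_gl[1:3], k_aa[1:3], group[1:3]),
               "at least 6")
})

test_that("distinct group slopes are detected with high power", {
  hits <- 0
  set.seed(99)
  for (r in 1:100) {
    k_gl <- runif(200, 0.05, 0.5)
    group <- rep(c("A", "B"), each = 100)
    slope <- ifelse(group == "A", -0.5, -0.9)
    k_aa <- 0.05 + slope * k_gl + rnorm(200, sd = 0.01)
    reg <- regress_interaction(k_gl, k_aa, group)
    p_int <- reg$coefficients$p_value[reg$coefficients$term == "k_gl:groupB"]
    if (p_int < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("population reports serialise to JSON and TSV", {
  fits_a <- mapply(make_fit_stub, k_gl = seq(0.1, 0.5, 0.1),
                   k_aa = seq(0.05, 0.01, -0.01), SIMPLIFY = FALSE)
  fits_b <- mapply(make_fit_stub, k_gl = seq(0.2, 0.6, 0.1),
                   k_aa = seq(0.03, -0.01, -0.01), SIMPLIFY = FALSE)
  sa <- summarize_population(fits_a, "A")
  sb <- summarize_population(fits_b, "B")
  cmp <- compare_groups(fits_a, fits_b)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_population_report(sa, sb, cmp, jp, tsv_path = tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$groups$label, c("A", "B"))
  expect_equal(back$groups$n, c(5, 5))
  tsv <- read.delim(tp)
  expect_equal(nrow(tsv), 2)
  expect_equal(tsv$k_gl_mean[1], sa$k_gl_mean)
})
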