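# Population-level analyses over fitted virtual subjects: classification of
# the beta-cell amino-acid sensitivity by its individual 95% CI, summary
# statistics, correlation, group tests and pooled regression.

#' Classify an amino-acid sensitivity estimate by its 95% CI
#'
#' `positive` if the whole interval lies above zero, `negative` if it lies
#' below, `negligible` otherwise (interval contains zero, endpoints
#' inclusive). The three classes are exhaustive and mutually exclusive.
#'
#' @param ci95_low,ci95_high confidence-interval endpoints,
#'   `ci95_low <= ci95_high`.
#' @return one of `"positive"`, `"negative"`, `"negligible"`.
#' @examples
#' classify_kaa(0.0168, 0.0325)   # "positive"
#' classify_kaa(-0.0281, 0.0185)  # "negligible"
#' @export
classify_kaa <- function(ci95_low, ci95_high) {
  if (!is.numeric(ci95_low) || !is.numeric(ci95_high) ||
      any(is.na(c(ci95_low, ci95_high))))
    stop("CI endpoints must be numbers")
  if (ci95_low > ci95_high)
    stop("inverted CI: low (", ci95_low, ") > high (", ci95_high, ")")
  if (ci95_low > 0) "positive"
  else if (ci95_high < 0) "negative"
  else "negligible"
}

# Sample skewness (method-of-moments, m3 / m2^(3/2)).
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

extract_param <- function(fits, name) {
  vapply(fits, function(f) {
    if (inherits(f, "model_fit")) unname(f$estimates[name])
    else as.numeric(f$estimates[[name]])
  }, numeric(1))
}

extract_kaa_class <- function(fits) {
  vapply(fits, function(f) {
    ci <- if (inherits(f, "model_fit")) f$ci95["k_aa", ]
          else unlist(f$ci95[["k_aa"]])
    classify_kaa(ci[[1]], ci[[2]])
  }, character(1))
}

KAA_CLASSES <- c("positive", "negative", "negligible")

#' Summarise fitted parameters over a population
#'
#' Means and SDs of the glucose sensitivity `k_gl` and amino-acid
#' sensitivity `k_aa`, counts and percentages of the three `k_aa` CI
#' classes, and the Pearson correlation between `k_gl` and `k_aa` with its
#' two-sided p-value. Fits may be `model_fit` objects or fit reports loaded
#' with [read_fit_json()].
#'
#' @param fits list of at least two fits on subjects of one group.
#' @param label group label (e.g. `"CNT"`, `"T2D"`).
#' @return an object of class `population_summary`.
#' @export
summarize_population <- function(fits, label = "population") {
  if (!is.list(fits) || length(fits) < 2)
    stop("summarize_population needs at least 2 fits")
  k_gl <- extract_param(fits, intersect(c("k_gl", "k_gl1"),
                                        names_of_first(fits))[1])
  k_aa <- extract_param(fits, "k_aa")
  classes <- factor(extract_kaa_class(fits), levels = KAA_CLASSES)
  counts <- table(classes)
  if (stats::sd(k_gl) == 0 || stats::sd(k_aa) == 0) {
    ct <- NULL
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(k_gl, k_aa)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(label = label, n = length(fits),
         k_gl_mean = mean(k_gl), k_gl_sd = stats::sd(k_gl),
         k_aa_mean = mean(k_aa), k_aa_sd = stats::sd(k_aa),
         class_counts = counts,
         class_percent = 100 * as.numeric(counts) / length(fits),
         pearson_r = r, pearson_p = p,
         k_gl = k_gl, k_aa = k_aa, classes = classes),
    class = "population_summary")
}

names_of_first <- function(fits) {
  f <- fits[[1]]
  if (inherits(f, "model_fit")) names(f$estimates) else names(f$estimates)
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> '%s' (n = %d)\n", x$label, x$n))
  cat(sprintf("  k_gl: %.4f +/- %.4f   k_aa: %.4f +/- %.4f\n",
              x$k_gl_mean, x$k_gl_sd, x$k_aa_mean, x$k_aa_sd))
  cat(sprintf("  k_aa classes: positive %.0f%%, negative %.0f%%, negligible %.0f%%\n",
              x$class_percent[1], x$class_percent[2], x$class_percent[3]))
  cat(sprintf("  Pearson r(k_gl, k_aa) = %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Compare two fitted populations
#'
#' Unpaired two-sided Welch t-tests on `k_gl` and `k_aa`, and a chi-square
#' test of independence (no continuity correction) on the 2 x 3 table of
#' `k_aa` CI classes. Following the usual convention for right-skewed
#' positive parameters, `k_gl` is natural-log-transformed before its t-test
#' when its pooled sample skewness exceeds 1 and all values are strictly
#' positive; the sign-free `k_aa` is never log-transformed. Classes with a
#' zero total count in both groups are dropped from the chi-square table
#' (with a warning). Two-sided p < 0.05 is the conventional significance
#' threshold.
#'
#' @param fits_a,fits_b lists of fits for the two groups (each n >= 2).
#' @param labels character(2) group labels.
#' @return an object of class `group_comparison`: list with `t_k_gl`,
#'   `t_k_aa` (each: statistic, p_value, log_transformed), `chisq`
#'   (statistic, df, p_value, table, dropped_classes), `labels`.
#' @export
compare_groups <- function(fits_a, fits_b, labels = c("A", "B")) {
  if (length(fits_a) < 2 || length(fits_b) < 2)
    stop("both groups need at least 2 fits")
  kgl_name_a <- intersect(c("k_gl", "k_gl1"), names_of_first(fits_a))[1]
  kgl_name_b <- intersect(c("k_gl", "k_gl1"), names_of_first(fits_b))[1]
  a_gl <- extract_param(fits_a, kgl_name_a)
  b_gl <- extract_param(fits_b, kgl_name_b)
  a_aa <- extract_param(fits_a, "k_aa")
  b_aa <- extract_param(fits_b, "k_aa")

  welch <- function(x, y, allow_log) {
    lt <- allow_log && sample_skewness(c(x, y)) > 1 && all(c(x, y) > 0)
    if (lt) {
      x <- log(x)
      y <- log(y)
    }
    if (stats::sd(c(x, y)) == 0) {
      list(statistic = 0, p_value = 1, log_transformed = lt)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      list(statistic = unname(tt$statistic), p_value = tt$p.value,
           log_transformed = lt)
    }
  }

  tab <- rbind(table(factor(extract_kaa_class(fits_a), levels = KAA_CLASSES)),
               table(factor(extract_kaa_class(fits_b), levels = KAA_CLASSES)))
  rownames(tab) <- labels
  empty <- colSums(tab) == 0
  dropped <- colnames(tab)[empty]
  if (any(empty)) {
    warning("k_aa class(es) absent from both groups dropped from the ",
            "chi-square table: ", paste(dropped, collapse = ", "))
    tab <- tab[, !empty, drop = FALSE]
  }
  chisq <- if (ncol(tab) < 2) {
    list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(cs$statistic), df = unname(cs$parameter),
         p_value = cs$p.value)
  }
  chisq$table <- tab
  chisq$dropped_classes <- dropped

  structure(list(labels = labels,
                 t_k_gl = welch(a_gl, b_gl, allow_log = TRUE),
                 t_k_aa = welch(a_aa, b_aa, allow_log = FALSE),
                 chisq = chisq),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  Welch t on k_gl%s: t = %.3f, p = %.3g\n",
              if (x$t_k_gl$log_transformed) " (log-transformed)" else "",
              x$t_k_gl$statistic, x$t_k_gl$p_value))
  cat(sprintf("  Welch t on k_aa: t = %.3f, p = %.3g\n",
              x$t_k_aa$statistic, x$t_k_aa$p_value))
  cat(sprintf("  chi-square on k_aa classes: X2 = %.3f (df = %g), p = %.3g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  invisible(x)
}

#' Pooled regression of k_aa on k_gl with a group factor
#'
#' Ordinary least squares of the amino-acid sensitivity on the glucose
#' sensitivity, the group indicator and their interaction
#' (`k_aa ~ k_gl * group`), over the two groups pooled. Tests whether the
#' k_gl--k_aa relationship differs between groups.
#'
#' @param k_gl,k_aa numeric vectors, pooled over both groups.
#' @param group character or factor of group labels, same length; both
#'   groups must be represented.
#' @return an object of class `interaction_regression`: list with
#'   `coefficients` (data.frame: term, estimate, std_error, p_value) and
#'   `fit` (the underlying `lm`).
#' @export
regress_interaction <- function(k_gl, k_aa, group) {
  if (length(k_gl) != length(k_aa) || length(k_gl) != length(group))
    stop("k_gl, k_aa and group must have the same length")
  if (length(k_gl) < 6) stop("pooled regression needs at least 6 subjects")
  group <- factor(group)
  if (nlevels(group) < 2)
    stop("rank deficiency: the group factor has a single level ('",
         levels(group), "')")
  fit <- stats::lm(k_aa ~ k_gl * group)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("rank deficiency: collinear term(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(sm),
                                   estimate = sm[, 1],
                                   std_error = sm[, 2],
                                   p_value = sm[, 4],
                                   row.names = NULL),
         fit = fit),
    class = "interaction_regression")
}

#' @export
print.interaction_regression <- function(x, ...) {
  cat("<interaction_regression> k_aa ~ k_gl * group\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 6)
  tab$std_error <- signif(tab$std_error, 4)
  tab$p_value <- signif(tab$p_value, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a population analysis report
#'
#' JSON report plus an optional tab-separated summary table for two
#' population summaries and their comparison.
#'
#' @param summary_a,summary_b `population_summary` objects.
#' @param comparison a `group_comparison`.
#' @param json_path output JSON path.
#' @param tsv_path optional TSV summary path.
#' @return `json_path`, invisibly.
#' @export
write_population_report <- function(summary_a, summary_b, comparison,
                                    json_path, tsv_path = NULL) {
  pack <- function(s) list(
    label = s$label, n = s$n,
    k_gl_mean = s$k_gl_mean, k_gl_sd = s$k_gl_sd,
    k_aa_mean = s$k_aa_mean, k_aa_sd = s$k_aa_sd,
    class_counts = as.list(stats::setNames(as.numeric(s$class_counts),
                                           KAA_CLASSES)),
    class_percent = as.list(stats::setNames(s$class_percent, KAA_CLASSES)),
    pearson_r = s$pearson_r, pearson_p = s$pearson_p)
  obj <- list(groups = list(pack(summary_a), pack(summary_b)),
              comparison = list(
                t_k_gl = comparison$t_k_gl,
                t_k_aa = comparison$t_k_aa,
                chisq = list(statistic = comparison$chisq$statistic,
                             df = comparison$chisq$df,
                             p_value = comparison$chisq$p_value,
                             dropped_classes = comparison$chisq$dropped_classes)))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    rows <- lapply(list(summary_a, summary_b), function(s) {
      data.frame(label = s$label, n = s$n,
                 k_gl_mean = s$k_gl_mean, k_gl_sd = s$k_gl_sd,
                 k_aa_mean = s$k_aa_mean, k_aa_sd = s$k_aa_sd,
                 pct_positive = s$class_percent[1],
                 pct_negative = s$class_percent[2],
                 pct_negligible = s$class_percent[3],
                 pearson_r = s$pearson_r, pearson_p = s$pearson_p)
    })
    utils::write.table(do.call(rbind, rows), tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
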