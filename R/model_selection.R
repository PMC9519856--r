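# Small-sample Akaike model comparison: AICc, relative likelihood and a
# ranked cross-model report.

#' Corrected Akaike information criterion for least-squares fits
#'
#' Gaussian-error least-squares form
#' `n * ln(RSS/n) + 2p + 2p(p+1)/(n - p - 1)`, where `p` counts only the
#' estimated kinetic parameters (the fixed disappearance rate k_I and the
#' derived basal appearance rate BR_I are not counted, and no +1 is added
#' for the error variance; the convention is fixed package-wide so that
#' AICc differences between models are always comparable).
#'
#' @param rss residual sum of squares, must be > 0.
#' @param n number of fitted data points.
#' @param p number of estimated parameters; requires `n > p + 1`.
#' @return the AICc value (lower is better).
#' @examples
#' aicc(1, 9, 2) # -13.775
#' @export
aicc <- function(rss, n, p) {
  if (!is.finite(rss) || rss <= 0)
    stop("AICc undefined: rss must be strictly positive")
  if (n <= p + 1)
    stop("AICc undefined: requires n > p + 1 (n = ", n, ", p = ", p, ")")
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Relative likelihood of a reference model over another
#'
#' `exp((AICc_other - AICc_ref) / 2)`: the evidence in favour of the
#' reference model relative to the other. Values above 1 favour the
#' reference model; equal AICc gives 1.
#'
#' @param aicc_ref AICc of the reference model.
#' @param aicc_other AICc of the competing model.
#' @return the relative likelihood (positive scalar).
#' @examples
#' relative_likelihood(20.53, 25.36) # 11.19
#' @export
relative_likelihood <- function(aicc_ref, aicc_other) {
  if (any(!is.finite(aicc_ref)) || any(!is.finite(aicc_other)))
    stop("both AICc values must be finite")
  exp((aicc_other - aicc_ref) / 2)
}

#' Compare fitted models on the same dataset
#'
#' Ranks the fits by AICc (ascending; ties broken by model id for
#' determinism), attaching the AICc difference from the best model and the
#' relative likelihood of the best model over each competitor.
#' Identifiability caveats carried by individual fits are collected in the
#' report notes.
#'
#' @param fits list of `model_fit` objects from [fit_model()], all fitted to
#'   the same dataset.
#' @return an object of class `comparison_report`: list with `entries`
#'   (data.frame `model`, `aicc`, `delta_aicc`, `rel_likelihood_vs_best`),
#'   `best` (model id), `notes`.
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2)
    stop("compare_models needs at least 2 fits")
  for (f in fits) stopifnot(inherits(f, "model_fit"))
  ref <- fits[[1]]
  for (f in fits[-1]) {
    if (f$dataset_label != ref$dataset_label ||
        length(f$observed) != length(ref$observed) ||
        any(f$observed != ref$observed))
      stop("all fits must come from the same dataset (found '",
           f$dataset_label, "' vs '", ref$dataset_label, "')")
  }
  entries <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    stringsAsFactors = FALSE)
  entries <- entries[order(entries$aicc, entries$model), , drop = FALSE]
  rownames(entries) <- NULL
  best_aicc <- entries$aicc[1]
  entries$delta_aicc <- entries$aicc - best_aicc
  entries$rel_likelihood_vs_best <-
    vapply(entries$aicc, function(a) relative_likelihood(best_aicc, a),
           numeric(1))
  notes <- unlist(lapply(fits, function(f) {
    if (length(f$notes))
      paste0(f$model, ": ", paste(f$notes, collapse = "; "))
    else character(0)
  }))
  structure(list(entries = entries, best = entries$model[1],
                 notes = notes %||% character(0)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> best model:", x$best, "\n")
  tab <- x$entries
  tab$aicc <- sprintf("%.4f", tab$aicc)
  tab$delta_aicc <- sprintf("%.4f", tab$delta_aicc)
  tab$rel_likelihood_vs_best <- sprintf("%.4g", tab$rel_likelihood_vs_best)
  print(tab, row.names = FALSE)
  if (length(x$notes)) cat("notes:\n ", paste(x$notes, collapse = "\n  "), "\n")
  invisible(x)
}

#' Mean AICc of one model across several datasets
#'
#' Aggregation used when a single criterion value is wanted for a model
#' fitted separately to several average datasets (e.g. the mean of the AICc
#' over a normal-glucose-tolerance and a type-2-diabetes average curve).
#'
#' @param fits list of `model_fit` objects for the *same* model on different
#'   datasets.
#' @return the arithmetic mean of their AICc values.
#' @export
mean_aicc <- function(fits) {
  if (!is.list(fits) || length(fits) < 1) stop("need at least one fit")
  for (f in fits) stopifnot(inherits(f, "model_fit"))
  models <- unique(vapply(fits, function(f) f$model, character(1)))
  if (length(models) > 1)
    stop("mean_aicc aggregates one model across datasets; got: ",
         paste(models, collapse = ", "))
  mean(vapply(fits, function(f) f$aicc, numeric(1)))
}

#' Export a comparison report
#'
#' Writes the ranked table as JSON and, optionally, as a plain-text table.
#'
#' @param report a `comparison_report`.
#' @param json_path output JSON path.
#' @param txt_path optional plain-text table path.
#' @return `json_path`, invisibly.
#' @export
write_comparison_json <- function(report, json_path, txt_path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(
    list(best = report$best, entries = report$entries, notes = report$notes),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(json_path)
}
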