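# Virtual-subject generation from mean +/- SD template curves.
#
# Each sample of each curve is drawn from Normal(mean_j, SD_j) and accepted
# only if (i) it lies within the 95% band mean_j +/- 1.96 SD_j and (ii) the
# sign of the step from the subject's previously accepted sample equals the
# sign of the corresponding step of the template mean curve (a zero template
# step imposes no constraint). Curves are generated independently of each
# other; sampling is chronological within a curve.

#' Virtual-population configuration
#'
#' @param n_subjects number of virtual subjects (default 100).
#' @param seed integer seed; the full population is reproducible from it.
#' @param max_rejections_per_sample rejection-sampling budget per sample
#'   (default 10000); exhausting it raises a generation error naming the
#'   curve and time index.
#' @param zero_sd_policy what to do at template points with SD = 0:
#'   `"copy_mean"` (the degenerate Normal; default) or `"error"`.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_subjects = 100, seed = 1L,
                              max_rejections_per_sample = 10000,
                              zero_sd_policy = c("copy_mean", "error")) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 max_rejections_per_sample =
                   as.integer(max_rejections_per_sample),
                 zero_sd_policy = match.arg(zero_sd_policy)),
            class = "population_config")
}

# One constrained curve draw. mean/sd are the template vectors.
draw_constrained_curve <- function(mean, sd, budget, zero_sd_policy) {
  n <- length(mean)
  out <- numeric(n)
  for (j in seq_len(n)) {
    if (sd[j] == 0) {
      if (zero_sd_policy == "error")
        stop("template SD is zero at time index ", j,
             " and zero_sd_policy = 'error'")
      out[j] <- mean[j]
      next
    }
    sgn <- if (j == 1) 0 else sign(mean[j] - mean[j - 1])
    ok <- FALSE
    for (attempt in seq_len(budget)) {
      x <- stats::rnorm(1, mean[j], sd[j])
      if (abs(x - mean[j]) > 1.96 * sd[j]) next
      if (sgn != 0 && sign(x - out[j - 1]) != sgn) next
      out[j] <- x
      ok <- TRUE
      break
    }
    if (!ok)
      stop("rejection budget (", budget, ") exhausted at time index ", j)
  }
  out
}

#' Generate a constrained virtual population
#'
#' Draws `cfg$n_subjects` virtual subjects around a template
#' [mmtt_dataset()] that carries per-sample SDs on every curve. Every
#' accepted sample lies within the 95% band of its template point, and every
#' consecutive-sample difference has the same sign as the template's (where
#' the template is strictly monotone). Basal values are recomputed per
#' subject from its own pre-meal samples. The generation is bit-reproducible
#' from `cfg$seed`; per-subject seeds are derived from it and recorded.
#'
#' @param template an [mmtt_dataset()] with SDs on all three curves.
#' @param cfg a [population_config()].
#' @return list of `virtual_subject` objects, each a list with `id`,
#'   `dataset` (an [mmtt_dataset()]), `seed_state` (the subject seed).
#' @export
generate_population <- function(template, cfg = population_config()) {
  stopifnot(inherits(template, "mmtt_dataset"),
            inherits(cfg, "population_config"))
  for (q in c("glucose", "insulin", "aa")) {
    if (is.null(template[[q]]$sds))
      stop("template ", q, " curve carries no SDs; cannot generate subjects")
  }
  set.seed(cfg$seed)
  subject_seeds <- sample.int(.Machine$integer.max, cfg$n_subjects)
  lapply(seq_len(cfg$n_subjects), function(i) {
    set.seed(subject_seeds[i])
    curves <- lapply(c("glucose", "insulin", "aa"), function(q) {
      tc <- template[[q]]
      vals <- tryCatch(
        draw_constrained_curve(tc$values, tc$sds,
                               cfg$max_rejections_per_sample,
                               cfg$zero_sd_policy),
        error = function(e) stop("generation failed for subject ", i,
                                 ", curve '", q, "': ", conditionMessage(e)))
      sampled_curve(tc$times, vals, quantity = q)
    })
    structure(list(id = i,
                   dataset = mmtt_dataset(curves[[1]], curves[[2]],
                                          curves[[3]],
                                          label = sprintf("%s_vs%03d",
                                                          template$label, i)),
                   seed_state = subject_seeds[i]),
              class = "virtual_subject")
  })
}

#' Export a virtual population to a directory
#'
#' Writes one CSV per subject (the [read_mmtt_csv()] dialect, without SD
#' columns) plus a `manifest.json` recording the configuration and the
#' per-subject seeds, so the population can be re-imported or regenerated.
#'
#' @param subjects list of `virtual_subject` objects.
#' @param dir output directory (created if needed).
#' @param cfg the [population_config()] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
export_population <- function(subjects, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(subjects, function(s) {
    f <- sprintf("subject_%03d.csv", s$id)
    write_mmtt_csv(s$dataset, file.path(dir, f), sidecar = FALSE)
    f
  }, character(1))
  manifest <- list(
    n_subjects = length(subjects),
    files = files,
    labels = vapply(subjects, function(s) s$dataset$label, character(1)),
    subject_seeds = vapply(subjects, function(s) s$seed_state, numeric(1)),
    config = if (is.null(cfg)) NULL else unclass(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-import a virtual population exported by [export_population()]
#'
#' @param dir directory containing subject CSVs and `manifest.json`.
#' @return list of `virtual_subject` objects.
#' @export
import_population <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lapply(seq_len(manifest$n_subjects), function(i) {
    ds <- read_mmtt_csv(file.path(dir, manifest$files[i]),
                        label = manifest$labels[i])
    structure(list(id = i, dataset = ds,
                   seed_state = manifest$subject_seeds[i]),
              class = "virtual_subject")
  })
}
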