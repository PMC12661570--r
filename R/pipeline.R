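#' End-to-end pipeline configuration
#'
#' Collects every stage's parameters in one nested list and fills defaults.
#' Pass the result (or a YAML file parsed with [yaml::read_yaml()]) to
#' [validate_config()] / [run_pipeline()].
#'
#' @param cohort a [cohort_config()] or a list of its arguments.
#' @param preprocessing list: `window_s`, `frame_s`, `stride_s`,
#'   `working_fs`, `wavelet`, `J`, `band`.
#' @param scalogram a [scalogram_config()] or argument list.
#' @param gan a [gan_config()] or argument list.
#' @param classifier list with `spec` ([cnn_spec()]) and `config`
#'   ([classifier_config()]).
#' @param experiment list: `task`, `amounts`, `repetitions`, `n_test`,
#'   `welch_pair`.
#' @param seed global seed.
#' @param out_dir run directory (NULL = no artifacts written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), preprocessing = list(),
                            scalogram = list(), gan = list(),
                            classifier = list(), experiment = list(),
                            seed = 1L, out_dir = NULL) {
  structure(list(cohort = cohort, preprocessing = preprocessing,
                 scalogram = scalogram, gan = gan, classifier = classifier,
                 experiment = experiment, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML top level mirrors the arguments of [pipeline_config()]
#' (`cohort`, `preprocessing`, `scalogram`, `gan`, `classifier`,
#' `experiment`, `seed`, `out_dir`); missing keys fall back to the
#' defaults. The result is validated with [validate_config()].
#'
#' @param path path to a YAML file.
#' @return a normalized `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  validate_config(do.call(pipeline_config, raw[keep]))
}

fill_config <- function(x, ctor) {
  if (inherits(x, class(ctor())[1])) return(x)
  do.call(ctor, x)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every stage's defaults and checks cross-stage invariants; each
#' violation is reported with the offending key.
#'
#' @param config a [pipeline_config()] (or a bare list with its fields).
#' @return the normalized configuration (all stage objects constructed), or
#'   an error listing the violated invariants.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  errors <- character(0)
  norm <- config
  try_stage <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(key, ": ", conditionMessage(e)))
      NULL
    })
  }
  norm$cohort <- try_stage("cohort", fill_config(config$cohort, cohort_config))
  pp <- utils::modifyList(list(window_s = 10, frame_s = 4, stride_s = 0.5,
                               working_fs = 200, wavelet = "sym4", J = 8L,
                               band = c(0.8, 3.5)),
                          as.list(config$preprocessing))
  if (pp$frame_s > pp$window_s)
    errors <- c(errors, "preprocessing.frame_s: exceeds window_s")
  if (pp$band[2] >= pp$working_fs / 2)
    errors <- c(errors, "preprocessing.band: upper edge at or above Nyquist of working_fs")
  norm$preprocessing <- pp
  norm$scalogram <- try_stage("scalogram", fill_config(config$scalogram, scalogram_config))
  norm$gan <- try_stage("gan", fill_config(config$gan, gan_config))
  cl <- as.list(config$classifier)
  norm$classifier <- list(
    spec = try_stage("classifier.spec",
                     if (inherits(cl$spec, "cnn_spec")) cl$spec
                     else do.call(cnn_spec, as.list(cl$spec))),
    config = try_stage("classifier.config",
                       if (inherits(cl$config, "classifier_config")) cl$config
                       else do.call(classifier_config, as.list(cl$config))))
  ex <- utils::modifyList(list(task = "sex", amounts = c(0, 75),
                               repetitions = 2L, n_test = 2L,
                               welch_pair = NULL),
                          as.list(config$experiment))
  if (any(ex$amounts < 0))
    errors <- c(errors, "experiment.amounts: negative augmentation amount")
  norm$experiment <- ex
  if (!is.null(norm$scalogram) && !is.null(norm$classifier$spec) &&
      norm$scalogram$size != norm$classifier$spec$image_size)
    errors <- c(errors, "classifier.spec.image_size: does not match scalogram.size")
  if (!is.null(norm$scalogram) && !is.null(norm$gan) &&
      norm$gan$image_size != norm$scalogram$size)
    errors <- c(errors, "gan.image_size: does not match scalogram.size")
  if (length(errors) > 0)
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  norm
}

#' Run the full analysis pipeline
#'
#' simulate -> demodulate -> isolate -> scalograms -> (GAN ->) classify ->
#' evaluate, from one configuration and one seed. When `out_dir` is set, the
#' normalized configuration, the per-run metric table and a JSON summary are
#' written there.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_run`: the `experiment`
#'   (a `leak_experiment`), the `scalograms` tibble, the `cohort` tibble and
#'   the normalized `config`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- config$seed
  cohort <- simulate_cohort(cohort_cfg)
  pp <- config$preprocessing
  scalos <- compute_scalograms(cohort,
                               window_s = pp$window_s, frame_s = pp$frame_s,
                               stride_s = pp$stride_s, working_fs = pp$working_fs,
                               wavelet = pp$wavelet, J = pp$J, band = pp$band,
                               config = config$scalogram,
                               wavelength = cohort_cfg$wavelength)
  ex <- config$experiment
  experiment <- run_experiment(scalos, task = ex$task, amounts = ex$amounts,
                               repetitions = ex$repetitions, n_test = ex$n_test,
                               spec = config$classifier$spec,
                               config = config$classifier$config,
                               gan = config$gan,
                               welch_pair = ex$welch_pair,
                               seed = config$seed + 1L)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(experiment$report,
                     file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    summary <- list(
      task = experiment$task,
      mean_accuracy_by_amount = experiment$report |>
        dplyr::group_by(.data$amount) |>
        dplyr::summarise(accuracy_windows = mean(.data$accuracy_windows),
                         .groups = "drop") |>
        as.list(),
      welch = if (!is.null(experiment$welch)) unclass(experiment$welch))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(experiment = experiment, scalograms = scalos,
                 cohort = cohort, config = config),
            class = "pipeline_run")
}
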