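#' Experiment run configuration
#'
#' Bundles everything one optimization experiment needs. Defaults mirror
#' the study's common configuration: population size 10, 10 repetitions,
#' 5 training epochs per evaluation.
#'
#' @param data_source Either a directory path (directory-per-class PNG
#'   layout) or a list of arguments for
#'   \code{\link{make_synthetic_imageset}}.
#' @param algorithm \code{"AO"} or \code{"GTO"}.
#' @param n_solutions Population size (default 10).
#' @param t_max Optimizer iterations per repetition (default 10).
#' @param epochs Training epochs per fitness evaluation (default 5).
#' @param repetitions Independent restarts with derived seeds (default 10).
#' @param seed Base seed (repetition r runs with \code{seed + r - 1}).
#' @param backend \code{"surrogate"} or \code{"tiny_classifier"}, or a
#'   backend object.
#' @param fitness_metric \code{"accuracy"} or \code{"weighted_sum"}.
#' @param output_dir Directory for result files (created if missing);
#'   \code{NULL} to skip writing.
#' @param image_size Working image size after resize (default
#'   \code{c(128, 128)}).
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(data_source = list(n_per_class = c(40, 40),
                                          size = c(32, 32)),
                       algorithm = c("AO", "GTO"), n_solutions = 10,
                       t_max = 10, epochs = 5, repetitions = 10, seed = 1,
                       backend = "surrogate",
                       fitness_metric = c("accuracy", "weighted_sum"),
                       output_dir = NULL, image_size = c(128, 128)) {
  structure(list(data_source = data_source,
                 algorithm = match.arg(algorithm),
                 n_solutions = n_solutions, t_max = t_max, epochs = epochs,
                 repetitions = repetitions, seed = seed, backend = backend,
                 fitness_metric = match.arg(fitness_metric),
                 output_dir = output_dir, image_size = image_size),
            class = "run_config")
}

.resolve_backend <- function(backend) {
  if (is.list(backend)) return(backend)
  switch(backend,
         surrogate = surrogate_backend(),
         tiny_classifier = tiny_classifier_backend(),
         stop("unknown backend '", backend, "'"))
}

#' Run a full optimization experiment
#'
#' End-to-end pipeline: ingest (read a class-per-directory tree or generate
#' a synthetic set), resize to the working size, partition into
#' train/validation/test, run the chosen metaheuristic with the fitness
#' backend as objective for each repetition, re-evaluate the overall best
#' configuration, and (optionally) write the best-configuration JSON, the
#' metric-report CSV and the per-repetition optimization histories.
#' Balancing and scaling happen inside each fitness evaluation, driven by
#' the decoded configuration. Everything is derived from the base seed.
#'
#' @param config A \code{\link{run_config}}.
#' @param quiet Suppress progress messages? Default \code{TRUE}.
#' @return A list of class \code{experiment_result} with \code{best}
#'   (the best repetition's \code{optimizer_run}), \code{best_evaluation}
#'   (an \code{evaluation_result} for data-using backends, or the surrogate
#'   report), \code{repetition_summary} (data frame of per-repetition best
#'   fitness), \code{runs} (all \code{optimizer_run}s) and \code{config}.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  backend <- .resolve_backend(config$backend)
  space <- build_default_space(include_augmentation = TRUE)
  data <- NULL
  if (isTRUE(backend$needs_data)) {
    say("[ingest] seed %d", config$seed)
    dataset <- if (is.character(config$data_source)) {
      read_imageset(config$data_source)
    } else {
      do.call(make_synthetic_imageset,
              c(config$data_source, list(seed = config$seed)))
    }
    say("[resize] %d images -> %dx%d", length(dataset),
        config$image_size[1], config$image_size[2])
    dataset$images <- lapply(dataset$images, resize_image,
                             target = config$image_size)
    data <- partition_dataset(dataset, ratio = 0.85, seed = config$seed)
    say("[partition] train %d / validation %d / test %d",
        length(data$train), length(data$validation), length(data$test))
  }
  runs <- vector("list", config$repetitions)
  for (r in seq_len(config$repetitions)) {
    rep_seed <- config$seed + r - 1L
    objective <- backend_objective(backend, data, epochs = config$epochs,
                                   seed = rep_seed,
                                   fitness_metric = config$fitness_metric)
    runs[[r]] <- run_optimizer(objective, space,
                               n_solutions = config$n_solutions,
                               t_max = config$t_max,
                               algorithm = config$algorithm, seed = rep_seed)
    say("[optimize] repetition %d/%d: best fitness %.3f", r,
        config$repetitions, runs[[r]]$best_fitness)
  }
  best_idx <- which.max(vapply(runs, `[[`, numeric(1), "best_fitness"))
  best <- runs[[best_idx]]
  best_evaluation <- evaluate_solution(best$best_vector, space, backend,
                                       data, epochs = config$epochs,
                                       seed = config$seed + best_idx - 1L,
                                       fitness_metric = config$fitness_metric)
  summary_df <- data.frame(
    repetition = seq_len(config$repetitions),
    seed = config$seed + seq_len(config$repetitions) - 1L,
    best_fitness = vapply(runs, `[[`, numeric(1), "best_fitness"))
  result <- structure(list(best = best, best_evaluation = best_evaluation,
                           repetition_summary = summary_df, runs = runs,
                           config = config),
                      class = "experiment_result")
  if (!is.null(config$output_dir)) write_experiment(result, config$output_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, %d repetitions, best fitness %.3f\n",
              x$config$algorithm, x$config$repetitions, x$best$best_fitness))
  print(x$best$best_configuration)
  invisible(x)
}

#' Write experiment outputs
#'
#' Emits the best-configuration JSON (with run metadata), the
#' metric-report CSV in metrics-by-run shape, the per-repetition summary
#' CSV and the best run's optimization history CSV.
#'
#' @param result An \code{experiment_result}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  meta <- list(algorithm = cfg$algorithm, seed = cfg$seed,
               n_solutions = cfg$n_solutions, t_max = cfg$t_max,
               epochs = cfg$epochs, repetitions = cfg$repetitions,
               backend = if (is.list(cfg$backend)) cfg$backend$name
                         else cfg$backend,
               fitness_metric = cfg$fitness_metric,
               best_fitness = result$best$best_fitness,
               best_configuration = unclass_deep(result$best$best_configuration))
  jsonlite::write_json(meta, file.path(dir, "best_configuration.json"),
                       auto_unbox = TRUE, digits = NA)
  write_report_table(list(best = result$best_evaluation$report),
                     file.path(dir, "metric_report.csv"))
  utils::write.csv(result$repetition_summary,
                   file.path(dir, "repetition_summary.csv"),
                   row.names = FALSE)
  write_history(result$best, file.path(dir, "optimization_history.csv"))
  invisible(dir)
}
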