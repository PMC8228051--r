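#' Configuration of one end-to-end training run
#'
#' Defaults follow the reference configuration for mine-vegetation
#' recognition -- depth 3, 60 hidden units per layer, learning rate 0.01,
#' 2 iterations -- with the scene and sample count scaled to desk size
#' (512 x 512 pixels, 200,000 training samples); the full 2000 x 1000 /
#' 2,000,000-pixel setting is reached by passing a larger `scene` and
#' `n_samples`.
#'
#' @param depth Number of hidden layers.
#' @param hidden_size Units per hidden layer.
#' @param learning_rate Shared step size for pretraining and fine-tuning.
#' @param iterations Epochs for both pretraining (per layer) and
#'   fine-tuning.
#' @param n_samples Pixels subsampled from the scene for the experiment.
#' @param seed Master seed driving scene generation, sampling, splitting
#'   and training.
#' @param scene A [scene_config()]; its own seed is ignored in favour of the
#'   master seed.
#' @param test_fraction Held-out fraction of the sampled pixels.
#' @return An object of class `run_config`.
#' @export
run_config <- function(depth = 3L, hidden_size = 60L, learning_rate = 0.01,
                       iterations = 2L, n_samples = 200000L, seed = 1L,
                       scene = scene_config(512L, 512L),
                       test_fraction = 0.2) {
  stopifnot(depth >= 1, hidden_size >= 1, learning_rate >= 0,
            iterations >= 1, n_samples >= 1,
            inherits(scene, "scene_config"),
            test_fraction > 0, test_fraction < 1)
  if (n_samples > scene$width * scene$height)
    stop("n_samples exceeds the number of scene pixels", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed), scene = scene,
                 test_fraction = test_fraction),
            class = "run_config")
}

#' Run one scene-to-assessment experiment
#'
#' Generates the scene, extracts pixel features, subsamples `n_samples`
#' pixels, splits train/test, pretrains the RBM stack, fine-tunes with the
#' softmax top layer, and evaluates on the held-out pixels. Training time is
#' the wall-clock of pretraining plus fine-tuning only. A run is flagged
#' `collapsed` when every test prediction is a single class, in which case
#' overall accuracy equals that class's test prevalence and kappa is 0.
#'
#' @param config A [run_config()].
#' @param varied_parameter,value Optional annotations recorded in the result
#'   (used by [control_variable_sweep()]).
#' @return A list of class `sweep_result`: `result` (one-row data frame with
#'   `varied_parameter`, `value`, `overall_accuracy`, `kappa`, `train_time`,
#'   `collapsed`, `seed`), `model`, `confusion`, `assessment`.
#' @export
run_single <- function(config, varied_parameter = NA_character_,
                       value = NA_real_) {
  stopifnot(inherits(config, "run_config"))
  res <- try(withr::with_seed(config$seed, {
    sc <- config$scene
    sc$seed <- NULL
    scene <- generate_scene(sc)
    data <- extract_features(scene)
    data <- subsample(data, config$n_samples)
    parts <- split_dataset(data, config$test_fraction)
    opts <- train_opts(config$learning_rate, 100L, config$iterations)
    t0 <- proc.time()["elapsed"]
    model <- pretrain(parts$train$features,
                      rep(config$hidden_size, config$depth), opts)
    model <- fine_tune(model, parts$train, opts)
    train_time <- unname(proc.time()["elapsed"] - t0)
    pred <- predict(model, parts$test$features)
    cm <- confusion_counts(parts$test$labels, pred$labels)
    list(model = model, cm = cm, train_time = train_time,
         collapsed = length(unique(pred$labels)) == 1L)
  }), silent = TRUE)
  if (inherits(res, "try-error"))
    stop("run failed [depth=", config$depth, " hidden=", config$hidden_size,
         " lr=", config$learning_rate, " iter=", config$iterations,
         " n=", config$n_samples, " seed=", config$seed, "]: ",
         attr(res, "condition")$message, call. = FALSE)
  rep_ <- assessment_report(res$cm)
  structure(list(result = data.frame(varied_parameter = varied_parameter,
                                     value = value,
                                     overall_accuracy = rep_$overall_accuracy,
                                     kappa = rep_$kappa,
                                     train_time = res$train_time,
                                     collapsed = res$collapsed,
                                     seed = config$seed),
                 model = res$model, confusion = res$cm, assessment = rep_),
            class = "sweep_result")
}

#' Default sweep grids
#'
#' The grids of the control-variable study: depth 1-10, hidden width
#' 10-120, learning rate 1e-6 to 0.5, iterations 1-20, sample size from
#' 10,000 upward (values beyond the scene's pixel count are rejected when
#' the run is configured).
#'
#' @return Named list of numeric grids.
#' @export
default_grids <- function() {
  list(depth = 1:10,
       hidden_size = seq(10L, 120L, by = 10L),
       learning_rate = c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.3, 0.5),
       iterations = c(1L, 2L, 3L, 5L, 10L, 20L),
       n_samples = c(10000L, 50000L, 100000L, 200000L))
}

#' Control-variable hyperparameter sweep
#'
#' Varies one of `depth`, `hidden_size`, `learning_rate`, `iterations`,
#' `n_samples` over a grid while holding the others at the base
#' configuration, one run (or `replicates` seeded runs) per value.
#'
#' @param parameter Name of the varied parameter.
#' @param values Grid of settings; defaults to [default_grids()] for the
#'   chosen parameter.
#' @param base A [run_config()] providing the fixed settings.
#' @param replicates Runs per value; replicate `r` uses seed
#'   `base$seed + (r - 1)`.
#' @return Data frame with one row per run, in grid order.
#' @export
control_variable_sweep <- function(parameter, values = NULL,
                                   base = run_config(), replicates = 1L) {
  ok <- c("depth", "hidden_size", "learning_rate", "iterations", "n_samples")
  if (!parameter %in% ok)
    stop("unknown parameter '", parameter, "'; expected one of ",
         paste(ok, collapse = ", "), call. = FALSE)
  if (is.null(values)) values <- default_grids()[[parameter]]
  stopifnot(length(values) >= 1L, replicates >= 1L)
  rows <- list()
  for (v in values) {
    for (r in seq_len(replicates)) {
      cfg <- base
      cfg[[parameter]] <- if (parameter == "learning_rate") v else as.integer(v)
      cfg$seed <- base$seed + (r - 1L)
      cfg <- do.call(run_config, unclass(cfg))  # re-validate
      rows[[length(rows) + 1L]] <-
        run_single(cfg, varied_parameter = parameter, value = v)$result
    }
  }
  do.call(rbind, rows)
}

#' Select the optimal setting from sweep results
#'
#' The value maximizing overall accuracy; ties broken by higher kappa, then
#' lower training time, then smaller value.
#'
#' @param results Data frame of sweep rows (from [control_variable_sweep()]).
#' @return The winning `value`.
#' @export
select_optimal <- function(results) {
  if (is.null(results) || nrow(results) < 1L)
    stop("no sweep results", call. = FALSE)
  ord <- order(-results$overall_accuracy, -results$kappa,
               results$train_time, results$value)
  results$value[ord[1L]]
}

#' Write sweep results to CSV (with optional bar charts)
#'
#' One CSV row per run; when `plots = TRUE`, bar charts of overall accuracy,
#' kappa and training time against the varied parameter are written next to
#' the CSV as PNG files.
#'
#' @param results Sweep data frame.
#' @param path Path of the CSV file.
#' @param plots Whether to render the bar charts.
#' @export
write_report <- function(results, path, plots = FALSE) {
  utils::write.csv(results, path, row.names = FALSE)
  if (plots && nrow(results) > 0) {
    stub <- sub("\\.csv$", "", path)
    for (metric in c("overall_accuracy", "kappa", "train_time")) {
      grDevices::png(paste0(stub, "_", metric, ".png"), 640, 480)
      graphics::barplot(results[[metric]], names.arg = results$value,
                        xlab = results$varied_parameter[1L], ylab = metric,
                        col = "darkseagreen")
      grDevices::dev.off()
    }
  }
  invisible(path)
}

#' Read back a sweep report CSV
#'
#' @param path CSV path written by [write_report()].
#' @return Sweep data frame.
#' @export
read_report <- function(path) {
  utils::read.csv(path)
}
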