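# End-to-end pipeline with a declarative config, derived stage seeds and
# per-stage manifests enabling exact re-runs.

#' Default run configuration
#'
#' Returns the nested list understood by [run_pipeline()]; any element can
#' be overridden via `modifyList()` semantics or a YAML file. Stage seeds
#' are all derived deterministically from the single `seed`.
#'
#' @param out_dir Output directory for artifacts and manifests.
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(out_dir = "ecgwolf-run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(n_beats = 2000L, noise_sd = 0.05,
                    class_proportions = NULL,  # NULL = default mixture
                    baseline_amp = 0.1, baseline_freq = 0.3),
    input = list(dataset = NULL, record = NULL),  # paths; override simulate
    preprocess = list(keep_prob = 0.15, wavelet = "sym5", levels = 3L,
                      pre_samples = 99L, post_samples = 180L,
                      normalize = TRUE, denoise = TRUE),
    split = list(train_fraction = 0.8),
    model = "hybrid",
    train = list(epochs = 10L, batch_size = 20L, learning_rate = 1e-3,
                 optimizer = "adamw"),
    optimize = list(enabled = FALSE, n_wolves = 10L, n_iters = 20L,
                    budget_epochs = 5L, extended_space = FALSE)
  )
}

#' Load a run configuration from a YAML file
#'
#' File values override the defaults of [default_run_config()].
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such config file: ", path))
  utils::modifyList(default_run_config(), yaml::read_yaml(path))
}

write_manifest <- function(out_dir, stage, data) {
  path <- file.path(out_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(data, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full classification pipeline
#'
#' Stage order: acquire data (synthetic generation or dataset/record
#' input) -> preprocess -> stratified split -> optional hyperparameter
#' optimization -> training -> evaluation. Each stage writes a JSON
#' manifest (inputs, seed, parameters) under `out_dir`, and the final
#' evaluation report is written both as text and JSON.
#'
#' @param config Nested list from [default_run_config()] /
#'   [read_run_config()], or a path to a YAML file.
#' @return Invisibly, a list with the trained model, the evaluation
#'   report and the split datasets.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir)) abort_validation("config lacks out_dir")
  for (p in c(config$input$dataset, config$input$record)) {
    if (!is.null(p) && !file.exists(p) && !file.exists(paste0(p, ".hea")))
      abort_validation(paste0("configured input path does not exist: ", p))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- vapply(1:5, function(k) derive_seed(config$seed, k), integer(1))

  # --- stage 1: data acquisition ----------------------------------------
  if (!is.null(config$input$dataset)) {
    ds <- read_beat_dataset(config$input$dataset)
    src <- config$input$dataset
  } else if (!is.null(config$input$record)) {
    rec <- read_record(config$input$record)
    pp <- config$preprocess
    ds <- segment_beats(rec, detect_r_peaks(rec),
                        segmentation_config(pp$pre_samples, pp$post_samples))
    src <- config$input$record
  } else {
    sim <- config$simulate
    props <- sim$class_proportions
    if (is.null(props)) props <- default_class_proportions()
    spec <- synthetic_spec(sim$n_beats, class_proportions = props,
                           noise_sd = sim$noise_sd,
                           baseline_amp = sim$baseline_amp,
                           baseline_freq = sim$baseline_freq,
                           seed = seeds[1])
    ds <- generate_beat_dataset(spec)
    src <- "synthetic"
  }
  write_manifest(config$out_dir, "data",
                 list(source = src, seed = seeds[1],
                      n_beats = nrow(ds$segments),
                      class_counts = as.list(ds$class_counts)))

  # --- stage 2: preprocessing -------------------------------------------
  pp <- config$preprocess
  n0 <- nrow(ds$segments)
  if (isTRUE(pp$normalize)) ds <- normalize_dataset(ds)
  ds <- subsample_majority(ds, keep_prob = pp$keep_prob, seed = seeds[2])
  ds <- clean_nonfinite(ds)
  if (isTRUE(pp$denoise))
    ds <- denoise_dataset(ds, wavelet_name = pp$wavelet, levels = pp$levels)
  write_manifest(config$out_dir, "preprocess",
                 list(seed = seeds[2], keep_prob = pp$keep_prob,
                      wavelet = pp$wavelet, levels = pp$levels,
                      beats_in = n0, beats_out = nrow(ds$segments),
                      class_counts = as.list(ds$class_counts)))

  # --- stage 3: split ----------------------------------------------------
  sp <- stratified_split(ds, config$split$train_fraction, seed = seeds[3])
  write_manifest(config$out_dir, "split",
                 list(seed = seeds[3],
                      train_fraction = config$split$train_fraction,
                      train_counts = as.list(sp$train$class_counts),
                      test_counts = as.list(sp$test$class_counts)))

  # --- stage 4: optional GWO + training ---------------------------------
  tr <- config$train
  input_len <- ncol(sp$train$segments)
  if (isTRUE(config$optimize$enabled)) {
    opt <- config$optimize
    space <- default_search_space(extended = isTRUE(opt$extended_space))
    budget <- train_config(epochs = opt$budget_epochs,
                           batch_size = tr$batch_size,
                           learning_rate = tr$learning_rate,
                           optimizer_name = "adamw", seed = seeds[4])
    res <- gwo_optimize(function(hp)
      accuracy_fitness(hp, sp$train, sp$test, budget),
      space, n_wolves = opt$n_wolves, n_iters = opt$n_iters,
      seed = seeds[4])
    cfg <- hybrid_params_to_config(res$best_params, input_len = input_len)
    write_manifest(config$out_dir, "optimize",
                   list(seed = seeds[4], n_wolves = opt$n_wolves,
                        n_iters = opt$n_iters,
                        best_params = res$best_params,
                        best_fitness = res$best_fitness))
    model <- build_hybrid(cfg)
  } else {
    model <- switch(config$model,
      hybrid = build_hybrid(hybrid_config(input_len = input_len)),
      cnn = build_cnn(cnn_config(input_len = input_len)),
      lstm = build_lstm(lstm_config(input_len = input_len)),
      abort_validation(paste0("unknown model kind: ", config$model)))
  }
  model <- kaiming_init(model, seed = seeds[5])
  tcfg <- train_config(epochs = tr$epochs, batch_size = tr$batch_size,
                       learning_rate = tr$learning_rate,
                       optimizer_name = tr$optimizer, seed = seeds[5])
  fit <- train_model(model, sp$train, sp$test, tcfg)
  write_manifest(config$out_dir, "train",
                 list(seed = seeds[5], model = config$model,
                      epochs = tr$epochs,
                      parameters = count_parameters(fit$model),
                      best_epoch = fit$best_epoch,
                      final_valid_acc =
                        fit$history$valid_acc[nrow(fit$history)]))

  # --- stage 5: evaluation ----------------------------------------------
  report <- evaluate_model(fit$model, sp$test)
  rendered <- render_report(report)
  writeLines(rendered$text, file.path(config$out_dir, "report.txt"))
  jsonlite::write_json(rendered$record,
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$history,
                   file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)
  invisible(list(model = fit$model, history = fit$history,
                 report = report, train = sp$train, test = sp$test))
}
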