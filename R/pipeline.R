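#' Default end-to-end pipeline configuration
#'
#' All defaults follow the study settings: level-2 db2 wavelet compression,
#' 20-frame windows, 3000 training epochs, L2 weight 1e-4, 50:50 stratified
#' split, sum-rule ensemble with two members of hidden sizes 46 and 15.
#' 48,000 raw frames per gait compress to 12,000, giving 600 windows per
#' gait and a 2400 x 40 feature table.
#'
#' @param n_frames_per_gait raw frames simulated per gait.
#' @param wavelet,level compression filter and approximation level.
#' @param window_size frames per feature window.
#' @param member_hidden_sizes list of member hidden-size vectors; a single
#'   entry trains one SAE instead of an ensemble.
#' @param fusion `"sum"` or `"product"`.
#' @param max_epochs,learning_rate,l2_weight,sparsity_weight training knobs
#'   (see [train_config()]).
#' @param seed master seed driving simulation, split and training.
#' @param out_dir optional directory; when set, every stage's artifacts are
#'   written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_frames_per_gait = 48000L,
                            wavelet = "db2", level = 2L, window_size = 20L,
                            member_hidden_sizes = list(46L, 15L),
                            fusion = "sum",
                            max_epochs = 3000L, learning_rate = 0.1,
                            l2_weight = 1e-4, sparsity_weight = 0,
                            seed = 1L, out_dir = NULL) {
  structure(list(n_frames_per_gait = as.integer(n_frames_per_gait),
                 wavelet = wavelet, level = as.integer(level),
                 window_size = as.integer(window_size),
                 member_hidden_sizes = member_hidden_sizes,
                 fusion = fusion, max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, l2_weight = l2_weight,
                 sparsity_weight = sparsity_weight,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full gait-classification pipeline
#'
#' simulate -> compress -> featurize -> split -> scale -> train members ->
#' fuse -> evaluate. Identical configs (including the master seed) produce
#' identical reports. When `config$out_dir` is set, recordings, feature
#' tables, the trained model, the evaluation report and a run manifest
#' (config + derived seeds) are written there.
#'
#' @param config a [pipeline_config()].
#' @return List with `report` (an `eval_report`), `model` (`esae_model` or
#'   `sae_model`), `scaler`, `split` sizes and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  result <- tryCatch({
    specs <- default_gait_specs()
    recordings <- generate_dataset(specs, config$n_frames_per_gait,
                                   seed = derive_seed(config$seed, 1L))
    stage <- "featurize"
    filters <- wavelet_filters(config$wavelet)
    features <- featurize_dataset(recordings, filters, config$level,
                                  config$window_size)
    stage <- "split"
    split <- split_5050(features, seed = derive_seed(config$seed, 2L))
    stage <- "scale"
    scaled <- scale_features(split$train, split$test)
    stage <- "train"
    tc <- train_config(max_epochs = config$max_epochs,
                       learning_rate = config$learning_rate,
                       l2_weight = config$l2_weight,
                       sparsity_weight = config$sparsity_weight,
                       seed = derive_seed(config$seed, 3L))
    model <- if (length(config$member_hidden_sizes) >= 2L) {
      train_ensemble(scaled$train$values, scaled$train$labels,
                     member_hidden_sizes = config$member_hidden_sizes,
                     config = tc, fusion = config$fusion,
                     class_names = gait_classes())
    } else {
      train_sae(scaled$train$values, scaled$train$labels,
                hidden_sizes = config$member_hidden_sizes[[1L]],
                config = tc, class_names = gait_classes())
    }
    stage <- "evaluate"
    predicted <- classify(model, scaled$test$values)
    report <- evaluate_predictions(scaled$test$labels, predicted,
                                   class_names = gait_classes())
    list(report = report, model = model, scaler = scaled$scaler,
         split = list(n_train = nrow(scaled$train$values),
                      n_test = nrow(scaled$test$values)),
         recordings = recordings, features = features, config = config)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rec in result$recordings) {
      write_recording(rec, file.path(config$out_dir,
                                     paste0("recording_", rec$gait_label, ".csv")))
    }
    write_features(result$features, file.path(config$out_dir, "features.csv"))
    save_model(result$model, file.path(config$out_dir, "model.rds"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("ridergait")),
      config = config[setdiff(names(config), "out_dir")],
      derived_seeds = list(simulate = derive_seed(config$seed, 1L),
                           split = derive_seed(config$seed, 2L),
                           train = derive_seed(config$seed, 3L)),
      accuracy_overall = result$report$accuracy_overall,
      n_test = result$report$n_test)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    report_out <- list(confusion = result$report$confusion,
                       per_class = result$report$per_class,
                       accuracy_overall = result$report$accuracy_overall,
                       accuracy_percent = result$report$accuracy_percent,
                       n_test = result$report$n_test)
    jsonlite::write_json(report_out, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  result$recordings <- NULL
  result
}
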