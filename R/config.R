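#' Pipeline configuration
#'
#' Nested configuration for every stage, loadable from a single YAML
#' file. Unknown keys are rejected so typos fail loudly. Block names and
#' defaults:
#' * `segmentation`: `threshold_fraction` (0.05), `resample_points` (60)
#' * `features`: `unit_basis` (TRUE), `M` (6)
#' * `model`: `kind` ("LSTM"), `hidden_units` (32), `epochs` (500),
#'   `learning_rate` (1e-3), `batch_size` (32), `seed` (1)
#' * `eval`: `test_fraction` (0.3), `seed` (1)
#' * `generator`: see [generator_config()]
#'
#' @param segmentation,features,model,eval,generator named lists
#'   overriding the defaults above.
#' @return a `pipeline_config` list with fully resolved blocks.
#' @export
pipeline_config <- function(segmentation = list(), features = list(),
                            model = list(), eval = list(),
                            generator = list()) {
  merge_block <- function(given, defaults, block) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0L) {
      stop("unknown key(s) in config block '", block, "': ",
           paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults, given)
  }
  seg <- merge_block(segmentation,
                     list(threshold_fraction = 0.05, resample_points = 60L),
                     "segmentation")
  feat <- merge_block(features, list(unit_basis = TRUE, M = 6L),
                      "features")
  mod <- merge_block(model,
                     list(kind = "LSTM", hidden_units = 32L,
                          epochs = 500L, learning_rate = 1e-3,
                          batch_size = 32L, seed = 1L),
                     "model")
  ev <- merge_block(eval, list(test_fraction = 0.3, seed = 1L), "eval")
  gen_defaults <- unclass(generator_config())
  gen <- merge_block(generator, gen_defaults, "generator")
  structure(list(segmentation = seg, features = feat, model = mod,
                 eval = ev, generator = gen),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the blocks above.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("segmentation", "features", "model",
                                   "eval", "generator"))
  if (length(unknown) > 0L) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Materialize stage objects from a pipeline config
#'
#' @param config a [pipeline_config()].
#' @return list with `seg_config`, `win_config`, `classifier_config`,
#'   `generator_config` ready to pass to the stage functions.
#' @export
resolve_configs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  list(
    seg_config = segmentation_config(config$segmentation$threshold_fraction,
                                     config$segmentation$resample_points),
    win_config = windowing_config(config$features$M),
    classifier_config = classifier_config(
      model_kind = config$model$kind,
      hidden_units = config$model$hidden_units,
      epochs = config$model$epochs,
      learning_rate = config$model$learning_rate,
      batch_size = config$model$batch_size,
      seed = config$model$seed),
    generator_config = generator_config(
      n_users = gen$n_users, n_repetitions = gen$n_repetitions,
      behaviors = gen$behaviors, height_range_m = gen$height_range_m,
      skeleton_rate_hz = gen$skeleton_rate_hz,
      imu_rate_hz = gen$imu_rate_hz,
      trial_duration_s = gen$trial_duration_s,
      active_window_s = gen$active_window_s,
      noise_sd = unlist(gen$noise_sd), signal_scale = gen$signal_scale,
      amplitude_jitter = gen$amplitude_jitter, seed = gen$seed))
}
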