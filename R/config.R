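# Configuration: a nested list (YAML-serializable) fully resolvable to
# defaults; unknown keys are rejected with their field path.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "run",
    data = list(
      synthetic = list(n_classes = 3L, per_class_count = 70L, image_size = 64L,
                       lesion_count_mean = 3, lesion_size_range = c(4, 8),
                       color_jitter_sd = 0.03),
      manifest = NULL,
      train_fraction = 0.8),
    augmentation = list(enabled = FALSE, fold = 10L,
                        skew_range_deg = c(-45, 45), shear_max_deg = 10,
                        distortion_intensity = 5, flip_probability = 0.5,
                        hue_shift = 0.1, saturation_shift = 0.3,
                        brightness_shift = 0.2),
    model = list(backbone_name = "tiny", addon_channels = 32L,
                 pretrained = FALSE, per_class = 10L, epsilon = 1e-4,
                 embed_dim = 64L),
    training = list(batch_size = 80L, epochs = 50L, learning_rate = 1e-4,
                    input_side = 224L, lambda1 = 0.8, lambda2 = 0.08,
                    lambda3 = 0.1, queue_size = 1024L, momentum = 0.999,
                    tau = 0.07, push_every = 10L, head_tune_epochs = 5L,
                    restarts = 1L),
    evaluation = list(explain_top = 1L, percentile = 95))
}

#' Desk-scale pipeline configuration
#'
#' The default configuration with the CPU profile substituted for the
#' training section: image side 64, batch 16, 30 epochs, learning rate 0.02
#' for the from-scratch tiny backbone (see [desk_train_config()]), and
#' three-fold offline augmentation of the training split (the reference
#' pipeline's ten-fold policy scaled to desk runtime).
#'
#' @param ... Top-level overrides merged into the configuration.
#' @return A resolved run configuration list.
#' @export
desk_run_config <- function(...) {
  cfg <- default_run_config()
  cfg$training$batch_size <- 16L
  cfg$training$epochs <- 30L
  cfg$training$learning_rate <- 0.02
  cfg$training$input_side <- 64L
  cfg$augmentation$enabled <- TRUE
  cfg$augmentation$fold <- 3L
  cfg$training$lambda3 <- 3
  cfg$training$momentum <- 0.5
  cfg$training$tau <- 0.2
  cfg$training$restarts <- 2L
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- modify_defaults(cfg[[nm]], over[[nm]], nm)
  validate_config(cfg)
}

modify_defaults <- function(def, val, path) {
  if (!is.list(def) || !is.list(val)) return(val)
  for (nm in names(val)) {
    if (!nm %in% names(def))
      abort_config("unknown configuration key: %s.%s", path, nm)
    def[[nm]] <- modify_defaults(def[[nm]], val[[nm]], paste(path, nm, sep = "."))
  }
  def
}

check_positive <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- cfg
  for (p in parts) v <- v[[p]]
  if (!is.null(v) && any(!is.finite(v) | v <= 0))
    abort_config("configuration field %s must be positive", path)
}

#' Validate and resolve a run configuration
#'
#' Accepts a YAML file path, a YAML string, a nested list, or `NULL` (all
#' defaults). Missing fields are filled with documented defaults; unknown
#' keys are rejected with their field path; cross-field constraints are
#' checked.
#'
#' @param raw Path, YAML text, list, or `NULL`.
#' @return The resolved configuration list (class `run_config`).
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) {
    raw <- if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort_config("configuration must be a mapping")
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) abort_config("unknown configuration key: %s", nm)
    cfg[[nm]] <- modify_defaults(cfg[[nm]], raw[[nm]], nm)
  }
  for (p in c("training.learning_rate", "training.batch_size", "training.epochs",
              "training.queue_size", "training.tau", "training.push_every",
              "model.per_class", "model.epsilon", "model.addon_channels",
              "data.train_fraction"))
    check_positive(cfg, p)
  if (cfg$data$train_fraction >= 1)
    abort_config("configuration field data.train_fraction must be < 1")
  if (is.null(cfg$data$manifest) && is.null(cfg$data$synthetic))
    abort_config("configuration section data must provide synthetic or manifest")
  if (cfg$augmentation$enabled && cfg$augmentation$fold < 1)
    abort_config("configuration field augmentation.fold must be >= 1")
  structure(cfg, class = "run_config")
}
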