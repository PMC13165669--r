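## Composed run configuration: one YAML file with sections mapping 1:1
## onto the module configurations.

#' Read a run configuration from YAML
#'
#' Sections `sim`, `akf`, `model`, `train` map field-for-field onto
#' [radar_sim_config()], [akf_config()], [model_config()] and
#' [train_config()]; the `model` section may instead name an ablation via
#' `ablation:` (`full`, `model1` ... `model4`) plus overrides. Every field
#' has a default; unknown keys are rejected. A top-level `seed` overrides
#' the per-section seeds.
#'
#' @param path YAML file; a missing file yields all defaults.
#' @return A list of class `run_config` with elements `sim`, `akf`,
#'   `model`, `train`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (!is.null(path) && file.exists(path)) {
    yaml::read_yaml(path)
  } else list()
  known_sections <- c("sim", "akf", "model", "train", "seed")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown))
    stop_config("unknown config section(s): ", paste(unknown, collapse = ", "))
  apply_section <- function(section, ctor, extra_keys = character(0)) {
    args <- raw[[section]] %||% list()
    allowed <- c(names(formals(ctor)), extra_keys)
    bad <- setdiff(names(args), allowed)
    if (length(bad))
      stop_config("unknown key(s) in '", section, "': ",
                  paste(bad, collapse = ", "))
    args
  }
  sim <- do.call(radar_sim_config, apply_section("sim", radar_sim_config))
  akf <- do.call(akf_config, apply_section("akf", akf_config))
  margs <- apply_section("model", model_config, extra_keys = "ablation")
  ab <- margs$ablation %||% "full"
  margs$ablation <- NULL
  model <- do.call(ablation_config, c(list(name = ab), margs))
  targs <- apply_section("train", train_config)
  if (!is.null(raw$seed)) targs$seed <- raw$seed
  train <- do.call(train_config, targs)
  structure(list(sim = sim, akf = akf, model = model, train = train,
                 seed = raw$seed %||% train$seed),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Inverse of [read_run_config()]: the file round-trips unchanged through
#' read and write.
#'
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  model <- unclass(cfg$model)
  model$l <- NULL                  # derived field
  yaml::write_yaml(list(seed = cfg$seed,
                        sim = unclass(cfg$sim),
                        akf = unclass(cfg$akf),
                        model = model,
                        train = unclass(cfg$train)), path)
  invisible(path)
}
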