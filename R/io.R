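#' Experiment configuration
#'
#' A validated bundle of task, network and fitting hyperparameters with a
#' content hash that is stable under key reordering. Defaults reproduce the
#' standard study conditions (tau = 200 ms, dt = 40 ms, sigma_rec = 0.15,
#' sigma_in = 0.01, N = 50, 8 latent nodes). Unknown keys are rejected.
#'
#' @param ... overrides of the default fields
#' @return list of class `experiment_config` with a `hash` attribute
#' @export
experiment_config <- function(...) {
  defaults <- list(
    N = 50L, n_latent = 8L, tau = 200, dt = 40, sigma_rec = 0.15,
    sigma_in = 0.01, spectral_radius = 1.5, exc_frac = 0.8,
    rnn_learning_rate = 0.01, rnn_weight_decay = 0.001, lambda_r = 0.05,
    lambda_orth = 1, minibatch = 128L, n_trials = 1800L,
    fit_learning_rate = 0.02, fit_weight_decay = 0.001, lambda = 0.5,
    patience = 25L, tol = 0.001, seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = "experiment_config", hash = config_hash(cfg))
}

# order-independent content hash
config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  rlang::hash(cfg)
}

#' Load / save experiment configurations as YAML
#'
#' `load_config()` fills unspecified fields with the defaults of
#' [experiment_config()] and rejects unknown keys with a field-level
#' message; an empty file yields the all-defaults configuration.
#'
#' @param path YAML file path
#' @return an `experiment_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(experiment_config, vals)
}

#' @rdname load_config
#' @param cfg an `experiment_config`
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Save and load model objects
#'
#' Round-trips any of the package's model objects (`rnn_params`,
#' `latent_circuit`, `latent_fit`, `trial_batch`, ...) bit-exactly through
#' R serialization, together with a format-version tag checked on load.
#'
#' @param object object to store
#' @param path file path
#' @export
save_model <- function(object, path) {
  saveRDS(list(format_version = 1L, object = object), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  wrapped <- readRDS(path)
  if (!is.list(wrapped) || is.null(wrapped$format_version)) {
    stop("not a recognized model file: ", path, call. = FALSE)
  }
  if (wrapped$format_version > 1L) {
    stop("model file written by a newer format version", call. = FALSE)
  }
  wrapped$object
}

#' Write a run manifest for provenance
#'
#' Records the configuration hash, seeds, package version and wall time of
#' a run as YAML next to its outputs.
#'
#' @param cfg an `experiment_config`
#' @param path output file
#' @param extra named list of additional fields
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  manifest <- c(list(
    config_hash = attr(cfg, "hash"),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("latentcircuit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
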