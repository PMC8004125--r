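#' Default experiment configuration
#'
#' Nested list mirroring the YAML configuration layout: sections `data`,
#' `synthesis`, `patches`, `features`, `selection`, `backbones` (training
#' defaults: learning rate 0.0002, momentum 0.1, minibatch 25, 70 epochs),
#' `fusion` and `evaluation`.
#'
#' @return a nested list.
#' @export
default_config <- function() {
  list(
    data = list(out_dir = "ceusfuse_out"),
    synthesis = list(seed = 1L, n_per_class = 100L, patch_size = 51L,
                     n_frames = 2L, frame_size = 360L),
    patches = list(patch_size = 51L, region = 250L),
    features = list(channels = "both"),
    selection = list(gain_ratio_threshold = 0.15, bins = 10L),
    backbones = list(name = "tiny", learning_rate = 2e-4, momentum = 0.1,
                     minibatch = 25L, epochs = 70L, augmentation = TRUE),
    fusion = list(image_method = "arithmetic_mean",
                  vector_method = "concatenation",
                  decision_method = "arithmetic_mean",
                  weights = c(2, 1), kpca_dim = 128L),
    evaluation = list(cnn_fractions = c(0.60, 0.15, 0.25),
                      baseline_fractions = c(0.75, 0, 0.25)))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML experiment configuration
#'
#' Values present in the file override [default_config()] entries;
#' everything else keeps its default.
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @return a nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file '%s' not found", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration snapshot, seed, package version, and the MD5
#' digest of every output file of a pipeline stage; re-running a stage from
#' its manifest reproduces all deterministic outputs on the same platform.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param config configuration list used.
#' @param seed seed used.
#' @param outputs character vector of produced file paths.
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(path, stage, config, seed, outputs = character(0)) {
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    stage = stage,
    seed = seed,
    package = "ceusfuse",
    version = as.character(utils::packageVersion("ceusfuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = if (length(outputs))
      as.list(stats::setNames(unname(tools::md5sum(outputs)),
                              basename(outputs)))
    else stats::setNames(list(), character(0)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
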