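config_defaults <- function() {
  list(
    weights = list(alpha = 200, beta = 1, gamma = 10, delta = 5,
                   mu1 = 1, mu2 = 0.5),
    learning_rate = 2e-4,
    learning_rate_local = NA,
    adam_betas = c(0.5, 0.999),
    iterations_global = 200L,
    iterations_local = 200L,
    global_downsample_shape = c(64L, 64L, 48L),
    patch_shape = c(64L, 64L, 64L),
    overlap = c(32L, 32L, 48L),
    seed = 1L,
    disc_steps_per_gen_step = 1L,
    gen_filters = 8L,
    disc_filters = 8L)
}

#' Load and validate a training/inference configuration
#'
#' Reads a YAML file, fills every missing key with the package defaults
#' (similarity/adversarial/regularization weights 200, 1, 10, 5 with
#' mu1 = 1, mu2 = 0.5; patch 64^3 with overlap 32x32x48) and rejects
#' unknown keys.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A validated [train_config()].
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("no such config file: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(user$weights)) {
    badw <- setdiff(names(user$weights), names(defaults$weights))
    if (length(badw))
      stop("unknown weight keys: ", paste(badw, collapse = ", "))
    defaults$weights[names(user$weights)] <- user$weights
    user$weights <- NULL
  }
  defaults[names(user)] <- user
  train_config(
    weights = do.call(loss_weights, defaults$weights),
    learning_rate = defaults$learning_rate,
    learning_rate_local = if (length(defaults$learning_rate_local) == 1 &&
                                is.na(defaults$learning_rate_local)) NULL
                            else defaults$learning_rate_local,
    adam_betas = defaults$adam_betas,
    iterations_global = defaults$iterations_global,
    iterations_local = defaults$iterations_local,
    global_downsample_shape = defaults$global_downsample_shape,
    patch_shape = defaults$patch_shape,
    overlap = defaults$overlap,
    seed = defaults$seed,
    disc_steps_per_gen_step = defaults$disc_steps_per_gen_step,
    gen_filters = defaults$gen_filters,
    disc_filters = defaults$disc_filters)
}

# jsonlite refuses S3-classed lists; strip classes recursively before
# serializing configurations.
strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Write a run manifest
#'
#' Records command, configuration hash, seed, input checksums and package
#' version as JSON next to a run's outputs, so every run is attributable
#' and repeatable.
#'
#' @param cmd Command name (e.g. "train").
#' @param config The configuration used (a list).
#' @param inputs Character vector of input file paths (checksummed if they
#'   exist).
#' @param out_dir Output directory (must exist).
#' @return Invisibly, the manifest list.
#' @export
run_manifest <- function(cmd, config, inputs = character(), out_dir = ".") {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  manifest <- list(
    command = cmd,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dirgan")),
    seed = config$seed,
    config_hash = config_hash(config),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = if (file.exists(p))
        as.character(tools::md5sum(p)) else NA)))
  path <- file.path(out_dir, paste0("manifest_", cmd, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Hash of a configuration
#' @param config A configuration list.
#' @return Character md5 hash of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  j <- jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                        digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(j, tf)
  unname(as.character(tools::md5sum(tf)))
}
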