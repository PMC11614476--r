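# YAML run configuration: model dimensions, diffusion settings, masking and
# seeds, validated against a fixed schema (unknown keys rejected).

config_schema <- function() {
  c(
    "c_m", "c_z", "n_blocks", "c_head", "n_head", "c_opu", "tri_hidden",
    "w_hidden", "embed_dim", "n_rbf", "rbf_max", "r_max", "time_dim",
    "T", "schedule", "mask_ratio", "delta", "seed"
  )
}

#' Read a run configuration from YAML
#'
#' Validates keys against the published schema; unknown keys are an error.
#' Missing keys fall back to the [model_config()] defaults.
#'
#' @param path YAML file.
#' @return list with \code{cfg} (a \code{model_config}) and \code{seed}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_schema())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- raw$seed %||% 0L
  raw$seed <- NULL
  cfg <- do.call(model_config, raw)
  list(cfg = cfg, seed = as.integer(seed))
}

#' Write a run configuration as YAML
#'
#' @param cfg a [model_config()].
#' @param path output file.
#' @param seed seed recorded alongside the model dimensions.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path, seed = 0L) {
  out <- unclass(cfg)
  out$seed <- as.integer(seed)
  yaml::write_yaml(out, path)
  invisible(path)
}
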