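#' Read / write a run configuration
#'
#' The configuration is a structured key-value YAML file; any operation
#' parameter is addressable by a dotted key such as
#' `"cluster.min_cluster_size"` or `"preprocess.sigma_max"`.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a nested named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Nested named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_config
#' @param key Dotted key, e.g. `"cluster.min_cluster_size"`.
#' @param default Value returned when the key is absent.
#' @export
config_get <- function(config, key, default = NULL) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  node <- config
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) return(default)
    node <- node[[p]]
  }
  node
}
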