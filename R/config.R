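#' Save and load simulator configurations as YAML
#'
#' Configurations ([screen_sim_config()], [genome_sim_config()],
#' [image_sim_config()]) round-trip through YAML so a run is fully described
#' by a small text file plus a seed.
#'
#' @param cfg A simulator configuration object.
#' @param path YAML file path.
#' @return `save_config()`: `path`, invisibly. `load_config()`: the
#'   reconstructed configuration object (validated by its constructor).
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' save_config(screen_sim_config(n_genes = 85, seed = 1), p)
#' load_config(p)
#' @export
save_config <- function(cfg, path) {
  type <- class(cfg)[1]
  if (!type %in% c("screen_sim_config", "genome_sim_config", "image_sim_config")) {
    rlang::abort("`cfg` must be a pluriexit simulator configuration")
  }
  fields <- unclass(cfg)
  if (!is.null(fields$planted_hits)) {
    fields$planted_hits <- as.list(fields$planted_hits)
  }
  yaml::write_yaml(c(list(type = type), fields), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  type <- raw$type
  if (is.null(type)) rlang::abort(sprintf("%s: missing `type` field", path))
  raw$type <- NULL
  constructor <- switch(
    type,
    screen_sim_config = screen_sim_config,
    genome_sim_config = genome_sim_config,
    image_sim_config = image_sim_config,
    rlang::abort(sprintf("%s: unknown configuration type '%s'", path, type))
  )
  if (!is.null(raw$planted_hits)) {
    raw$planted_hits <- tibble::as_tibble(raw$planted_hits)
  }
  # scalars parsed as length-1 vectors are fine; list-valued fields
  # (factors, planted_distances, image_size) arrive as vectors already
  do.call(constructor, lapply(raw, function(x) {
    if (is.list(x) && !is.data.frame(x)) unlist(x) else x
  }))
}
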