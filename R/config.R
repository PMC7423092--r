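#' Read and write analysis configuration files
#'
#' Plain YAML key-value files carrying the tunable parameters: per-type
#' `radii` (Angstrom), fallback B-factor `slopes`, the significance
#' thresholds (`significance_2fofc` = 1.5, `significance_fofc` = 3), the
#' aggregation floors (`residue_floor` = 4, `chain_floor` = 50) and the
#' optimizer tolerance (0.05). Defaults reproduce the published parameters.
#'
#' @param path File path.
#' @param config A configuration list as returned by `default_config()`.
#' @return `read_run_config()` and `default_config()` return a named list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
default_config <- function() {
  list(
    radii = as.list(unclass(default_radii())),
    slopes = as.list(unclass(default_slopes())),
    significance_2fofc = 1.5,
    significance_fofc = 3.0,
    threshold_sum = FALSE,
    residue_floor = 4L,
    chain_floor = 50L,
    tolerance = 0.05,
    blob_cutoff = 5.0,
    connectivity = 26L
  )
}

#' @rdname default_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$radii <- radii_set(unlist(base$radii), provenance = "user")
  base$slopes <- slope_table(unlist(base$slopes))
  base
}

#' @rdname default_config
#' @export
write_run_config <- function(config, path) {
  config$radii <- as.list(unclass(config$radii))
  config$slopes <- as.list(unclass(config$slopes))
  yaml::write_yaml(config, path)
  invisible(path)
}
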