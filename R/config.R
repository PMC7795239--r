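# Run configuration: one nested list holding every tunable with defaults,
# serializable to YAML or JSON and back without change.

#' Default pipeline configuration
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged one level deep, e.g. `pnp = list(top_k = 100)`).
#' @return Nested configuration list of class `"gw_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    paths = list(
      network = NULL, expression = NULL, groups = NULL, gene_sets = NULL,
      out_dir = "results"
    ),
    identify = list(log1p = FALSE),
    pnp = list(energy_threshold = 0.85, top_k = 3000),
    compare = list(min_abs_log2fc = 0.5),
    dti = list(enabled = FALSE, hidden = c(512, 256, 128, 64), dropout = 0.4,
               learning_rate = 1e-4, epochs = 100, batch_size = 100,
               patience = 10, n_components = 618, test_fraction = 0.25,
               cv_folds = 10),
    drug = list(enabled = FALSE, max_size = 2, min_ld50 = -Inf, max_ec50 = Inf,
                max_side_effect = Inf, allow_unwanted = FALSE,
                desired = as.list(default_desired_regulation())),
    seeds = list(pipeline = 1L, dti = 1L),
    log_level = "info"
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "gw_config")
}

#' Read a configuration file (YAML or JSON by extension)
#'
#' Values in the file are merged over [default_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"gw_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, raw)
}

#' Write a configuration file (YAML or JSON by extension)
#'
#' @param config A `"gw_config"` list.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
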