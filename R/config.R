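#' Read a run configuration from YAML
#'
#' The file may contain any of the top-level sections `fit`, `search`,
#' `weights` and `sim`, whose keys are the arguments of [fit_config()],
#' [search_config()], [objective_weights()] and [sim_config()]; omitted
#' sections and keys fall back to the defaults. A `planted` list under
#' `sim` is converted to [planted_bicluster()] specs.
#'
#' @param path YAML file path (requires the `yaml` package).
#' @return List with elements `fit`, `search`, `weights`, `sim`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs requires the 'yaml' package.",
          class = "treebic_config_error")
  }
  raw <- yaml::read_yaml(path)
  take <- function(x, f) {
    x <- x %||% list()
    known <- intersect(names(x), names(formals(f)))
    do.call(f, x[known])
  }
  sim_raw <- raw$sim %||% list()
  if (!is.null(sim_raw$planted)) {
    sim_raw$planted <- lapply(sim_raw$planted, function(p)
      do.call(planted_bicluster,
              p[intersect(names(p), names(formals(planted_bicluster)))]))
  }
  list(
    fit = take(raw$fit, fit_config),
    search = take(raw$search, search_config),
    weights = take(raw$weights, objective_weights),
    sim = take(sim_raw, sim_config)
  )
}
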