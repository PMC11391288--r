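#' Read a scan configuration from a YAML file
#'
#' A config file fully determines a run: top-level keys `local`
#' (per-parameter `c(lower, upper)` bounds, see [local_param_config()]),
#' `connectivity` (`diag`, `offdiag` ranges), `stability` (`n_kappa`,
#' `kappa_min`, `kappa_max`, `zero_tol`, `asymptotic_tol`),
#' `equilibrium` (see [equilibrium_control()]) and `seed`. Missing keys
#' fall back to the package defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return List with elements `local`, `connectivity`, `stability`,
#'   `equilibrium`, `seed`.
#' @export
read_scan_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(fun, key) {
    args <- raw[[key]] %||% list()
    do.call(fun, args)
  }
  list(local = take(local_param_config, "local"),
       connectivity = take(connectivity_config, "connectivity"),
       stability = take(stability_config, "stability"),
       equilibrium = take(equilibrium_control, "equilibrium"),
       seed = as.integer(raw$seed %||% 1L))
}
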