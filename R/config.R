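#' Read a SWeRF configuration file
#'
#' YAML key-value configuration overriding the convention parameters and PSD
#' reader defaults. Recognised keys: `inhalable_decay`, `respirable_median`,
#' `respirable_gsd` (convention), `psd.dialect`, `psd.diameter_basis`
#' (reader defaults, nested under `psd:`).
#'
#' @param path YAML file.
#' @return A list with elements `params` (a [convention_params()]) and
#'   `psd` (list of reader defaults).
#' @export
read_swerf_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- convention_params()
  params <- convention_params(
    inhalable_decay = cfg$inhalable_decay %||% defaults$inhalable_decay,
    respirable_median = cfg$respirable_median %||% defaults$respirable_median,
    respirable_gsd = cfg$respirable_gsd %||% defaults$respirable_gsd
  )
  list(
    params = params,
    psd = list(
      dialect = cfg$psd$dialect %||% "bin_table",
      diameter_basis = cfg$psd$diameter_basis %||% "spherical_equivalent"
    )
  )
}
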