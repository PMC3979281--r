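#' Describe a powder material
#'
#' Bundles the density descriptors and optional crystalline-silica content of
#' a material. The specific gravity is the particle density relative to unit
#' density (1000 kg m^-3): 2.66 for quartz, 4.48 for barite. For porous or
#' hollow particles an effective density (skeleton density corrected for
#' internal porosity, kg m^-3) overrides the specific gravity in every
#' density-dependent step.
#'
#' @param name Material name.
#' @param specific_gravity Particle density relative to 1000 kg m^-3 (> 0).
#' @param effective_density Optional effective density in kg m^-3 for
#'   porous/hollow particles; when set it replaces `specific_gravity * 1000`.
#' @param cs_mass_fraction Optional crystalline-silica mass fraction in
#'   \[0, 1\].
#' @return A list of class `swerf_material`.
#' @examples
#' quartz <- material("quartz", specific_gravity = 2.66, cs_mass_fraction = 1)
#' barite <- material("barite", specific_gravity = 4.48, cs_mass_fraction = 0)
#' @export
material <- function(name, specific_gravity, effective_density = NULL,
                     cs_mass_fraction = NULL) {
  if (!is.numeric(specific_gravity) || length(specific_gravity) != 1 ||
      specific_gravity <= 0)
    stop("`specific_gravity` must be a single positive number", call. = FALSE)
  if (!is.null(effective_density) &&
      (!is.numeric(effective_density) || effective_density <= 0))
    stop("`effective_density` must be positive (kg m^-3)", call. = FALSE)
  if (!is.null(cs_mass_fraction) &&
      (!is.numeric(cs_mass_fraction) || cs_mass_fraction < 0 ||
       cs_mass_fraction > 1))
    stop("`cs_mass_fraction` must lie in [0, 1]", call. = FALSE)
  structure(
    list(
      name = as.character(name),
      specific_gravity = specific_gravity,
      effective_density = effective_density,
      cs_mass_fraction = cs_mass_fraction
    ),
    class = "swerf_material"
  )
}

# density actually used in aerodynamic conversion and Stokes settling, kg m^-3
particle_density <- function(material) {
  if (!is.null(material$effective_density)) material$effective_density
  else material$specific_gravity * 1000
}

#' @export
print.swerf_material <- function(x, ...) {
  cat(sprintf("material: %s (SG %g", x$name, x$specific_gravity))
  if (!is.null(x$effective_density))
    cat(sprintf(", effective density %g kg/m^3", x$effective_density))
  if (!is.null(x$cs_mass_fraction))
    cat(sprintf(", CS fraction %g", x$cs_mass_fraction))
  cat(")\n")
  invisible(x)
}
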