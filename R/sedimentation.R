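#' Liquid properties for sedimentation
#'
#' Dynamic viscosity and density of the sedimentation liquid. Defaults are
#' water at 20 degrees C. Temperature itself is not modelled; supply the
#' viscosity and density at the working temperature.
#'
#' @param name Liquid name.
#' @param dynamic_viscosity Dynamic viscosity in kg m^-1 s^-1 (Pa s).
#' @param density Liquid density in kg m^-3.
#' @return A list of class `swerf_liquid`.
#' @export
liquid_properties <- function(name = "water",
                              dynamic_viscosity = 1.002e-3,
                              density = 998) {
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("`dynamic_viscosity` must be strictly positive", call. = FALSE)
  if (!is.numeric(density) || density <= 0)
    stop("`density` must be strictly positive", call. = FALSE)
  structure(list(name = name, dynamic_viscosity = dynamic_viscosity,
                 density = density),
            class = "swerf_liquid")
}

#' Sedimentation cut diameter equivalent to the respirable convention
#'
#' The gravimetric protocol separates at a survival function
#' \eqn{S(D) = \max(0, 1 - (D/D_c)^2)}. Its integral over diameter is
#' \eqn{2 D_c / 3}; equating it with the integral of the respirable
#' convention fixes the cut: \eqn{D_c = 1.5 \int_0^\infty R(D)\,dD}
#' (about 6.42 um aerodynamic for the default convention).
#'
#' @param params EN 481 [convention_params()].
#' @return The cut diameter in um aerodynamic.
#' @export
cut_diameter <- function(params = convention_params()) {
  1.5 * respirable_integral(params)
}

#' Stokes settling time for the convention-equivalent separation
#'
#' Time for a particle of aerodynamic cut diameter `cut_diameter_um` to
#' settle through the extraction height under Stokes' law with buoyancy:
#' \deqn{t = \frac{18\,\eta\,h\,\rho_p}{g\,(\rho_p - \rho_l)\,\rho_0\,D_c^2}}
#' with \eqn{D_c} in metres. The aerodynamic-to-physical conversion in the
#' liquid, \eqn{d = D_c \sqrt{\rho_0 / \rho_p}}, is what brings
#' \eqn{\rho_0} into the formula.
#'
#' @param cut_diameter_um Aerodynamic cut diameter in um.
#' @param particle_density Particle (or effective) density in kg m^-3.
#' @param liquid A [liquid_properties()] object.
#' @param extraction_height_m Height h of the supernatant layer extracted, m.
#' @param g Gravitational acceleration, m s^-2.
#' @param unit_density Unit density rho_0, kg m^-3.
#' @return Settling time in seconds.
#' @export
settling_time <- function(cut_diameter_um, particle_density,
                          liquid = liquid_properties(),
                          extraction_height_m, g = 9.81,
                          unit_density = 1000) {
  stopifnot(cut_diameter_um > 0, extraction_height_m > 0)
  if (particle_density <= liquid$density)
    stop("particles do not settle: particle density must exceed liquid density",
         call. = FALSE)
  Dc_m <- cut_diameter_um * 1e-6
  18 * liquid$dynamic_viscosity * extraction_height_m * particle_density /
    (g * (particle_density - liquid$density) * unit_density * Dc_m^2)
}

#' Plan a sedimentation experiment equivalent to EN 481
#'
#' Derives the cut diameter and settling time for a gravimetric sedimentation
#' experiment whose separation matches the EN 481 respirable convention. When
#' the crystalline-silica fine fraction is the target, use the density of
#' quartz/cristobalite, not that of the bulk sample.
#'
#' @param material A [material()] (supplies the particle or effective
#'   density), or a bare particle density in kg m^-3.
#' @param liquid A [liquid_properties()] object.
#' @param extraction_height_m Height h of the extracted supernatant layer, m.
#' @param column_height_m Total column height H, m (>= h).
#' @param g Gravitational acceleration, m s^-2.
#' @param unit_density Unit density rho_0, kg m^-3.
#' @param params EN 481 [convention_params()].
#' @return A list of class `sedimentation_plan` with the inputs plus the
#'   derived `cut_diameter_um` and `settling_time_s`.
#' @examples
#' plan <- sedimentation_plan(material("quartz", 2.66),
#'                            extraction_height_m = 0.05,
#'                            column_height_m = 0.20)
#' plan$cut_diameter_um
#' plan$settling_time_s
#' @export
sedimentation_plan <- function(material, liquid = liquid_properties(),
                               extraction_height_m,
                               column_height_m = extraction_height_m,
                               g = 9.81, unit_density = 1000,
                               params = convention_params()) {
  rho_p <- if (inherits(material, "swerf_material")) particle_density(material)
           else material
  stopifnot(is.numeric(rho_p), rho_p > 0)
  if (extraction_height_m <= 0 || column_height_m < extraction_height_m)
    stop("need 0 < extraction height <= column height", call. = FALSE)
  Dc <- cut_diameter(params)
  t <- settling_time(Dc, rho_p, liquid, extraction_height_m, g, unit_density)
  structure(
    list(liquid = liquid, particle_density = rho_p,
         unit_density = unit_density, g = g,
         extraction_height_m = extraction_height_m,
         column_height_m = column_height_m,
         cut_diameter_um = Dc, settling_time_s = t),
    class = "sedimentation_plan"
  )
}

#' @export
print.sedimentation_plan <- function(x, ...) {
  t <- round(x$settling_time_s)
  cat("sedimentation plan (EN 481 respirable equivalent)\n")
  cat(sprintf("  liquid: %s (eta %g Pa s, rho %g kg/m^3)\n",
              x$liquid$name, x$liquid$dynamic_viscosity, x$liquid$density))
  cat(sprintf("  particle density: %g kg/m^3\n", x$particle_density))
  cat(sprintf("  extraction height h: %g m of %g m column\n",
              x$extraction_height_m, x$column_height_m))
  cat(sprintf("  cut diameter D_c: %.3f um aerodynamic\n", x$cut_diameter_um))
  cat(sprintf("  settling time t: %.0f s (%02d:%02d:%02d)\n",
              x$settling_time_s, t %/% 3600, (t %% 3600) %/% 60, t %% 60))
  invisible(x)
}

#' Suspension survival probability
#'
#' Fraction of particles of aerodynamic diameter `D` that remain in the top
#' `h` of an initially homogeneous column after the plan's settling time:
#' \eqn{S(D) = \max(0, 1 - (D/D_c)^2)}, the sedimentation analogue of the
#' respirable convention (Stokes velocity scales with \eqn{D^2}).
#'
#' @param D Aerodynamic diameter in um (vectorised, >= 0).
#' @param plan A derived [sedimentation_plan()].
#' @return Probabilities in \[0, 1\].
#' @export
survival_probability <- function(D, plan) {
  if (!inherits(plan, "sedimentation_plan") ||
      is.null(plan$cut_diameter_um))
    stop("`plan` must be a derived sedimentation_plan", call. = FALSE)
  check_diameter(D)
  pmax(0, 1 - (D / plan$cut_diameter_um)^2)
}

#' Evaluate gravimetric sedimentation measurements
#'
#' Turns supernatant-residue weighings into SWeRF estimates:
#' \deqn{\mathrm{SWeRF} = \frac{m\,H}{M\,h}} where `M` is the dispersed mass,
#' `m` the residue recovered from the extracted supernatant, `H` the column
#' height and `h` the extraction height. When a crystalline-silica fraction
#' of the residue (`f_cs`, from FT-IR or XRD) is present,
#' \eqn{\mathrm{SWeRF}_{CS} = \mathrm{SWeRF} \times f_{CS}}. Raw ratios
#' slightly above 1 (weighing noise) are clamped to 1 with a warning.
#'
#' @param measurements A data frame with columns `M_mg`, `m_mg`, `H_mm`,
#'   `h_mm` and optionally `f_cs` (fraction in \[0, 1\]) and `material`.
#' @return A `swerf_result` tibble, one row per measurement, with
#'   `method = "sedimentation"`.
#' @examples
#' swerf_from_measurement(
#'   data.frame(M_mg = 5000, m_mg = 100, H_mm = 200, h_mm = 40)
#' )
#' @export
swerf_from_measurement <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  need <- c("M_mg", "m_mg", "H_mm", "h_mm")
  if (!all(need %in% names(m)))
    stop("measurements need columns M_mg, m_mg, H_mm, h_mm", call. = FALSE)
  if (any(m$m_mg < 0) || any(m$m_mg > m$M_mg))
    stop("residue mass must satisfy 0 <= m <= M", call. = FALSE)
  if (any(m$h_mm <= 0) || any(m$h_mm > m$H_mm))
    stop("heights must satisfy 0 < h <= H", call. = FALSE)
  raw <- (m$m_mg * m$H_mm) / (m$M_mg * m$h_mm)
  if (any(raw > 1))
    warning(sprintf("%d raw SWeRF ratio(s) exceed 1; clamped to 1",
                    sum(raw > 1)), call. = FALSE)
  sw <- pmin(raw, 1)
  f <- if ("f_cs" %in% names(m)) m$f_cs else rep(NA_real_, nrow(m))
  nm <- if ("material" %in% names(m)) as.character(m$material)
        else rep("unnamed", nrow(m))
  out <- purrr::pmap(
    list(nm, sw, f, raw, seq_len(nrow(m))),
    function(name, s, fcs, r, i) {
      cs <- if (is.na(fcs)) NA_real_ else swerf_cs_from_measurement(s, fcs)
      new_swerf_result(name, "sedimentation", s, cs,
                       details = list(raw_ratio = r, M_mg = m$M_mg[i],
                                      m_mg = m$m_mg[i], H_mm = m$H_mm[i],
                                      h_mm = m$h_mm[i]))
    }
  )
  dplyr::bind_rows(out)
}

#' Crystalline-silica SWeRF from a sedimentation measurement
#'
#' For a mixture, the fine fraction attributable to a constituent is the
#' product of the measured SWeRF and the constituent's fraction in the
#' supernatant residue:
#' \eqn{\mathrm{SWeRF}_{CS} = \mathrm{SWeRF} \times f_{CS}}.
#'
#' @param swerf Measured SWeRF as a fraction in \[0, 1\] (vectorised).
#' @param f_cs Constituent fraction in the supernatant residue, \[0, 1\].
#' @return `swerf * f_cs` as a fraction.
#' @examples
#' round(100 * swerf_cs_from_measurement(0.345, 0.283), 1) # 9.8
#' @export
swerf_cs_from_measurement <- function(swerf, f_cs) {
  if (any(swerf < 0 | swerf > 1) || any(f_cs < 0 | f_cs > 1))
    stop("`swerf` and `f_cs` must lie in [0, 1]", call. = FALSE)
  swerf * f_cs
}

#' Simulate an ideal sedimentation experiment
#'
#' Expected outcome of a noiseless sedimentation run on a known PSD: each bin
#' survives in the supernatant with probability \eqn{S(D)} at its
#' representative aerodynamic diameter, so the implied
#' \eqn{m H / (M h)} is \eqn{\sum_b P(b)\,S(D_b)}. With the
#' convention-equivalent cut diameter this agrees with [swerf_from_psd()] by
#' construction for distributions spread across the separation range. No
#' flocculation, hindered settling or wall effects are modelled.
#'
#' @param psd A [psd()] on the aerodynamic basis.
#' @param plan A derived [sedimentation_plan()].
#' @param material_name Name for the result row.
#' @return A one-row `swerf_result` with `method = "sedimentation"`.
#' @export
virtual_sedimentation <- function(psd, plan, material_name = "virtual") {
  stopifnot(inherits(psd, "swerf_psd"))
  if (diameter_basis(psd) != "aerodynamic")
    stop("virtual sedimentation needs an aerodynamic-basis PSD; convert first",
         call. = FALSE)
  w <- sum(psd$fraction * survival_probability(bin_representative(psd), plan))
  new_swerf_result(material_name, "sedimentation", w,
                   details = list(cut_diameter_um = plan$cut_diameter_um,
                                  settling_time_s = plan$settling_time_s))
}

#' Check the dilute-suspension rule of the sedimentation protocol
#'
#' The protocol disperses about 5 g in a 250 ml cylinder and asks that solids
#' stay at or below 1% of the liquid volume so particles settle unhindered.
#' Violations warn rather than error.
#'
#' @param sample_mass_g Dispersed mass in g.
#' @param particle_density Particle density in kg m^-3.
#' @param liquid_volume_ml Total liquid volume in ml. Default 250.
#' @return Solids volume fraction, invisibly.
#' @export
check_solids_loading <- function(sample_mass_g, particle_density,
                                 liquid_volume_ml = 250) {
  stopifnot(sample_mass_g >= 0, particle_density > 0, liquid_volume_ml > 0)
  vol_frac <- (sample_mass_g / (particle_density / 1000)) / liquid_volume_ml
  if (vol_frac > 0.01)
    warning(sprintf(
      "solids at %.2f%% v/v exceed the 1%% guideline; settling may be hindered",
      100 * vol_frac), call. = FALSE)
  invisible(vol_frac)
}
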