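# shared fixtures built in code

# uniform (linear-binned) PSD on [0, upper] um
uniform_psd <- function(upper, n_bins, basis = "aerodynamic") {
  edges <- seq(0, upper, length.out = n_bins + 1)
  psd(edges[-(n_bins + 1)], edges[-1], rep(1 / n_bins, n_bins),
      diameter_basis = basis)
}

# near-Dirac PSD: all mass in one narrow bin whose geometric mean is `at`
dirac_psd <- function(at, rel_width = 1e-4, basis = "aerodynamic") {
  psd(at * (1 - rel_width), at * (1 + rel_width), 1, diameter_basis = basis)
}

# brute-force trapezoid oracle for the respirable-convention integral
trapezoid_integral <- function(params = convention_params(), upper = 50,
                               step = 0.01) {
  g <- seq(0, upper, by = step)
  R <- respirable_fraction(g, params)
  sum((R[-1] + R[-length(R)]) / 2) * step
}

# emulation of the very fine flux-calcined diatomaceous earth repeatability
# sample: D50 9.3 um, porous particles handled through an effective density
repeatability_fixture <- function() {
  list(
    psd = lognormal_psd(median = 9.3, gsd = 2.0),
    material = material("flux-calcined diatomaceous earth",
                        specific_gravity = 2.3,
                        effective_density = 1400)
  )
}

# published quartz-spiked barite study: percent quartz added, SWeRF_CS
# calculated from the quartz flour's PSD, measured sedimentation SWeRF,
# quartz fraction of the supernatant residue (FT-IR), sedimentation SWeRF_CS
spiking_study <- list(
  spike_percent = c(0, 25, 50, 75, 100),
  calculated_swerf_cs = c(0, 11.3, 21.9, 32.0, 41.4),
  sed_swerf = c(0, 34.5, 38.1, 40.8, 41.8),
  ftir_percent = c(0, 28.3, 58.3, 79.4, 91.9),
  sed_swerf_cs = c(0, 9.8, 22.2, 32.4, 38.4)
)

# published diatomaceous-earth product comparison (both methods, %) and the
# seven replicate sedimentation determinations of the repeatability study
de_products <- list(sedimentation = c(16.5, 15.4, 6.9, 4.7, 6.7),
                    calculated = c(19.4, 17.0, 8.5, 4.9, 8.0))
repeatability_values <- c(17.6, 14.9, 14.8, 17.1, 14.9, 13.6, 15.2)
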