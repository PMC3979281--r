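#' Synthetic lognormal particle size distribution
#'
#' Builds a binned PSD from a lognormal volume distribution, the standard
#' emulation of milled-mineral granulometry as reported by laser diffraction.
#' Bins are log-spaced over `median * gsd^(-range_factor)` to
#' `median * gsd^(+range_factor)`, with fractions taken as CDF differences
#' (tail mass folded into the end bins), so the median of the result tracks
#' `median` to well within 1%.
#'
#' @param median Median diameter in um (> 0).
#' @param gsd Geometric standard deviation (> 1).
#' @param n_bins Number of bins (>= 10). Default 256.
#' @param range_factor Half-width of the support in GSD multiples. Default 4.
#' @param diameter_basis Basis the diameters are to be interpreted on.
#' @return A [psd()] tibble.
#' @examples
#' d50(lognormal_psd(median = 9.3, gsd = 2))
#' @export
lognormal_psd <- function(median, gsd, n_bins = 256, range_factor = 4,
                          diameter_basis = c("spherical_equivalent",
                                             "aerodynamic")) {
  diameter_basis <- match.arg(diameter_basis)
  if (!is.numeric(median) || median <= 0)
    stop("`median` must be strictly positive", call. = FALSE)
  if (!is.numeric(gsd) || gsd <= 1)
    stop("`gsd` must be > 1", call. = FALSE)
  if (n_bins < 10)
    stop("`n_bins` must be at least 10", call. = FALSE)
  edges <- exp(seq(log(median) - range_factor * log(gsd),
                   log(median) + range_factor * log(gsd),
                   length.out = n_bins + 1))
  cdf <- stats::plnorm(edges, meanlog = log(median), sdlog = log(gsd))
  frac <- diff(cdf)
  # fold the (tiny) tails into the end bins so the mass balance is exact
  frac[1] <- frac[1] + cdf[1]
  frac[n_bins] <- frac[n_bins] + (1 - cdf[n_bins + 1])
  psd(edges[-(n_bins + 1)], edges[-1], frac, diameter_basis = diameter_basis)
}

#' Spike a base powder with a second component
#'
#' Describes a two-component blend (e.g. quartz flour spiked into
#' quartz-free barite) at the component level: each component keeps its own
#' PSD and density, and the blend SWeRF is the mass-weighted sum of the
#' component SWeRFs. When the spike is the only crystalline-silica carrier,
#' the blend's CS mass fraction equals
#' `spike_fraction * spike$material$cs_mass_fraction`.
#'
#' @param base,spike Lists with elements `psd` (a [psd()]) and `material`
#'   (a [material()]).
#' @param spike_fraction Mass fraction of the spike in the blend, \[0, 1\].
#' @param params EN 481 [convention_params()].
#' @return A list of class `swerf_blend`: per-component `swerf_result` rows,
#'   the blended result, and the blend CS mass fraction.
#' @export
spiked_blend <- function(base, spike, spike_fraction,
                         params = convention_params()) {
  if (!is.numeric(spike_fraction) || spike_fraction < 0 || spike_fraction > 1)
    stop("`spike_fraction` must lie in [0, 1]", call. = FALSE)
  comp <- function(x) {
    r <- swerf_from_psd(x$psd, x$material, params)
    f <- x$material$cs_mass_fraction %||% 0
    swerf_cs_calculated(r, f)
  }
  base_r <- comp(base)
  spike_r <- comp(spike)
  blended <- blend_swerf(
    dplyr::bind_rows(base_r, spike_r),
    c(1 - spike_fraction, spike_fraction),
    material_name = sprintf("%s + %.0f%% %s", base$material$name,
                            100 * spike_fraction, spike$material$name)
  )
  cs_fraction <-
    (1 - spike_fraction) * (base$material$cs_mass_fraction %||% 0) +
    spike_fraction * (spike$material$cs_mass_fraction %||% 0)
  structure(
    list(components = dplyr::bind_rows(base_r, spike_r),
         blend = blended,
         spike_fraction = spike_fraction,
         cs_mass_fraction = cs_fraction),
    class = "swerf_blend"
  )
}

#' Simulate noisy gravimetric sedimentation replicates
#'
#' Draws virtual measurement records around the ideal sedimentation outcome
#' of a known PSD: the expected residue mass is
#' `M * (h/H) * virtual_swerf`, and multiplicative Gaussian noise with
#' relative standard deviation `noise` is applied to the residue weighing
#' `m` only (the dominant gravimetric error; heights and the dispersed mass
#' are treated as exact). With `noise = 0` the records are deterministic and
#' seed-independent.
#'
#' @param psd A [psd()] on the aerodynamic basis.
#' @param plan A derived [sedimentation_plan()].
#' @param noise Relative standard deviation of the residue weighing (>= 0).
#' @param n_replicates Number of replicate records. Default 1.
#' @param seed Integer seed for reproducibility (optional).
#' @param M_mg Dispersed mass in mg. Default 5000 (the 5 g protocol).
#' @return A tibble of measurement records (`M_mg`, `m_mg`, `H_mm`, `h_mm`)
#'   consumable by [swerf_from_measurement()].
#' @export
noisy_sedimentation_run <- function(psd, plan, noise, n_replicates = 1,
                                    seed = NULL, M_mg = 5000) {
  if (!is.numeric(noise) || noise < 0)
    stop("`noise` must be >= 0", call. = FALSE)
  true_swerf <- virtual_sedimentation(psd, plan)$swerf
  H_mm <- plan$column_height_m * 1000
  h_mm <- plan$extraction_height_m * 1000
  m_expected <- M_mg * (h_mm / H_mm) * true_swerf
  if (!is.null(seed)) set.seed(seed)
  mult <- if (noise == 0) rep(1, n_replicates)
          else stats::rnorm(n_replicates, mean = 1, sd = noise)
  tibble::tibble(
    replicate = seq_len(n_replicates),
    M_mg = M_mg,
    m_mg = pmax(0, m_expected * mult),
    H_mm = H_mm,
    h_mm = h_mm
  )
}
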