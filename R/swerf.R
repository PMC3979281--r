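#' @importFrom rlang .data %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# single-row result tibble shared by the calculated and sedimentation routes
new_swerf_result <- function(material_name, method, swerf, swerf_cs = NA_real_,
                             details = list()) {
  stopifnot(swerf >= -1e-12, swerf <= 1 + 1e-12)
  out <- tibble::tibble(
    material = material_name,
    method = method,
    swerf = min(max(swerf, 0), 1),
    swerf_cs = swerf_cs,
    details = list(details)
  )
  class(out) <- c("swerf_result", class(out))
  out
}

#' Size-weighted relevant fine fraction from a PSD
#'
#' Weights each PSD bin by the EN 481 respirable-convention probability at the
#' bin's representative aerodynamic diameter (geometric mean of its edges) and
#' sums: \deqn{\mathrm{SWeRF} = \sum_b P(b)\, R(D_b).} A
#' spherical-equivalent PSD is first converted with [to_aerodynamic()], which
#' requires the material's density. The result is the mass fraction of the
#' powder that, if made airborne and inhaled, would reach the alveoli.
#'
#' @param psd A [psd()] object.
#' @param material A [material()]; required (for the density) when `psd` is on
#'   the spherical-equivalent basis, and for the material name and
#'   crystalline-silica fraction.
#' @param params EN 481 [convention_params()].
#' @return A one-row `swerf_result` tibble with columns `material`, `method`
#'   (`"calculated"`), `swerf`, `swerf_cs` (`NA` until
#'   [swerf_cs_calculated()]), `details`.
#' @examples
#' q <- material("quartz flour", 2.66, cs_mass_fraction = 1)
#' p <- lognormal_psd(median = 3, gsd = 2)
#' swerf_from_psd(p, q)
#' @export
swerf_from_psd <- function(psd, material = NULL,
                           params = convention_params()) {
  stopifnot(inherits(psd, "swerf_psd"))
  name <- if (is.null(material)) "unnamed" else material$name
  if (diameter_basis(psd) == "spherical_equivalent") {
    if (is.null(material))
      stop(paste("a material (density) is required to convert a",
                 "spherical-equivalent PSD to aerodynamic diameter"),
           call. = FALSE)
    psd <- to_aerodynamic(psd, material)
  }
  w <- sum(psd$fraction * respirable_fraction(bin_representative(psd), params))
  new_swerf_result(name, "calculated", w,
                   details = list(n_bins = nrow(psd), d50_um = d50(psd)))
}

#' Crystalline-silica SWeRF under the homogeneity assumption
#'
#' When the crystalline silica in a product shares the size distribution of
#' the other minerals, its fine fraction is simply the product of the bulk
#' SWeRF and the CS mass fraction:
#' \eqn{\mathrm{SWeRF}_{CS} = f_{CS} \cdot \mathrm{SWeRF}}.
#'
#' @param result A `swerf_result` row from [swerf_from_psd()].
#' @param material A [material()] with `cs_mass_fraction` set, or a bare
#'   numeric fraction in \[0, 1\].
#' @return The result with `swerf_cs` filled in.
#' @export
swerf_cs_calculated <- function(result, material) {
  stopifnot(inherits(result, "swerf_result"))
  f <- if (inherits(material, "swerf_material")) material$cs_mass_fraction
       else material
  if (is.null(f))
    stop("`cs_mass_fraction` is not set on this material", call. = FALSE)
  stopifnot(is.numeric(f), f >= 0, f <= 1)
  result$swerf_cs <- f * result$swerf
  result
}

#' Mass-weighted SWeRF of a blend
#'
#' SWeRF is linear in mass: the fine fraction of a physical blend is the
#' mass-weighted sum of the component fine fractions. Components of different
#' densities are combined here, at the result level, never by merging their
#' PSDs.
#'
#' @param results A `swerf_result` tibble (one row per component) or a list
#'   of one-row results.
#' @param weights Non-negative mass weights summing to 1 (within 1e-9).
#' @param material_name Name for the blend.
#' @return A one-row `swerf_result` for the blend; `swerf_cs` is the weighted
#'   sum when every component has it, else `NA`.
#' @export
blend_swerf <- function(results, weights, material_name = "blend") {
  if (is.list(results) && !inherits(results, "data.frame"))
    results <- dplyr::bind_rows(results)
  stopifnot(is.numeric(weights), length(weights) == nrow(results))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  cs <- if (anyNA(results$swerf_cs)) NA_real_
        else sum(weights * results$swerf_cs)
  new_swerf_result(
    material_name, "calculated",
    swerf = sum(weights * results$swerf), swerf_cs = cs,
    details = list(components = results$material, weights = weights)
  )
}

#' @export
print.swerf_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s (%s): SWeRF %.1f%%", x$material[i], x$method[i],
                100 * x$swerf[i]))
    if (!is.na(x$swerf_cs[i]))
      cat(sprintf(", SWeRF_CS %.1f%%", 100 * x$swerf_cs[i]))
    cat("\n")
  }
  invisible(x)
}

#' Tidy a SWeRF result
#'
#' @param x A `swerf_result` tibble.
#' @param ... Unused.
#' @return A plain tibble with `material`, `method`, `swerf` and `swerf_cs`
#'   as percentages, and the STOT RE category where `swerf_cs` is known.
#' @method tidy swerf_result
#' @export
tidy.swerf_result <- function(x, ...) {
  out <- tibble::tibble(
    material = x$material,
    method = x$method,
    swerf_percent = 100 * x$swerf,
    swerf_cs_percent = 100 * x$swerf_cs
  )
  out$stot_re <- ifelse(
    is.na(out$swerf_cs_percent), NA_character_,
    classify_stot_re(ifelse(is.na(out$swerf_cs_percent), 0,
                            out$swerf_cs_percent))$category
  )
  out
}

#' One-line summary of a SWeRF result set
#'
#' @param x A `swerf_result` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of results, methods used, SWeRF range.
#' @method glance swerf_result
#' @export
glance.swerf_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    methods = paste(sort(unique(x$method)), collapse = "+"),
    min_swerf = min(x$swerf),
    max_swerf = max(x$swerf)
  )
}

#' Plot the respirable convention with result markers
#'
#' Draws the EN 481 respirable efficiency curve and, optionally, the median
#' diameters of one or more analysed materials.
#'
#' @param results Optional `swerf_result` tibble; rows whose `details` carry
#'   a `d50_um` are marked.
#' @param params [convention_params()].
#' @return A ggplot.
#' @export
plot_convention <- function(results = NULL, params = convention_params()) {
  grid <- tibble::tibble(D = exp(seq(log(0.1), log(40), length.out = 400)))
  grid$R <- respirable_fraction(grid$D, params)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$D, y = 100 * .data$R)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "aerodynamic diameter (um)",
                  y = "probability of reaching the alveoli (%)")
  if (!is.null(results)) {
    d50s <- purrr::map_dbl(results$details,
                           ~ .x$d50_um %||% NA_real_)
    mk <- tibble::tibble(material = results$material, d50 = d50s,
                         swerf = 100 * results$swerf)
    mk <- mk[!is.na(mk$d50), ]
    if (nrow(mk) > 0)
      p <- p + ggplot2::geom_point(
        data = mk,
        ggplot2::aes(x = .data$d50, y = .data$swerf, colour = .data$material),
        inherit.aes = FALSE
      )
  }
  p
}
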