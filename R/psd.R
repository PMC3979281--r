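#' Construct a binned particle size distribution
#'
#' A PSD is a tibble with one row per bin (`lower_um`, `upper_um`,
#' `fraction`) and two attributes: `diameter_basis` (`"spherical_equivalent"`
#' from e.g. laser diffraction, or `"aerodynamic"`) and `quantity_basis`
#' (`"volume"` or `"mass"`; the two are interchangeable for a material of
#' uniform density). Bins are half-open intervals \[lower, upper) on strictly
#' increasing edges, and fractions are normalised to sum to 1.
#'
#' @param lower_um,upper_um Bin edges in um; `lower_um[1] >= 0`, edges
#'   strictly increasing and contiguous is not required but lower < upper.
#' @param fraction Non-negative mass/volume fraction per bin; renormalised to
#'   sum to 1 (with a warning if the raw sum is off by more than 1e-6).
#' @param diameter_basis `"spherical_equivalent"` or `"aerodynamic"`.
#' @param quantity_basis `"volume"` or `"mass"`.
#' @return A tibble of class `swerf_psd`.
#' @examples
#' psd(c(0, 2), c(2, 10), c(0.5, 0.5), diameter_basis = "aerodynamic")
#' @export
psd <- function(lower_um, upper_um, fraction,
                diameter_basis = c("spherical_equivalent", "aerodynamic"),
                quantity_basis = c("volume", "mass")) {
  diameter_basis <- match.arg(diameter_basis)
  quantity_basis <- match.arg(quantity_basis)
  if (length(lower_um) == 0)
    stop("empty particle size distribution", call. = FALSE)
  if (length(lower_um) != length(upper_um) ||
      length(lower_um) != length(fraction))
    stop("`lower_um`, `upper_um` and `fraction` must have equal length",
         call. = FALSE)
  if (anyNA(c(lower_um, upper_um, fraction)))
    stop("PSD contains missing values", call. = FALSE)
  if (lower_um[1] < 0)
    stop("diameters must be non-negative", call. = FALSE)
  n <- length(lower_um)
  if (any(upper_um <= lower_um) ||
      (n > 1 && any(lower_um[-1] < upper_um[-n])))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (any(fraction < 0))
    stop("bin fractions must be non-negative", call. = FALSE)
  tot <- sum(fraction)
  if (tot <= 0)
    stop("bin fractions sum to zero", call. = FALSE)
  if (abs(tot - 1) > 1e-6)
    warning(sprintf("bin fractions sum to %.6g; renormalising to 1", tot),
            call. = FALSE)
  out <- tibble::tibble(lower_um = as.numeric(lower_um),
                        upper_um = as.numeric(upper_um),
                        fraction = as.numeric(fraction) / tot)
  attr(out, "diameter_basis") <- diameter_basis
  attr(out, "quantity_basis") <- quantity_basis
  class(out) <- c("swerf_psd", class(out))
  out
}

#' @export
print.swerf_psd <- function(x, ...) {
  cat(sprintf("particle size distribution: %d bins on [%g, %g] um (%s basis)\n",
              nrow(x), x$lower_um[1], x$upper_um[nrow(x)],
              gsub("_", "-", diameter_basis(x))))
  NextMethod()
}

#' Diameter basis of a PSD
#' @param psd A [psd()] object.
#' @return `"spherical_equivalent"` or `"aerodynamic"`.
#' @export
diameter_basis <- function(psd) {
  b <- attr(psd, "diameter_basis")
  if (is.null(b)) stop("not a swerf_psd: missing diameter basis", call. = FALSE)
  b
}

# representative diameter per bin: geometric mean of edges, with the zero
# lower edge of the first bin floored at 0.01 um to avoid a degenerate mean
bin_representative <- function(psd, floor_um = 0.01) {
  lo <- pmax(psd$lower_um, floor_um)
  sqrt(lo * psd$upper_um)
}

#' Read a particle size distribution from CSV
#'
#' Two dialects are supported. `"bin_table"` expects columns `lower_um`,
#' `upper_um`, `fraction`. `"cumulative_passing"` expects columns
#' `diameter_um` (increasing) and `cumulative_percent` (non-decreasing,
#' ending at 100 +/- 0.5); the table is differenced into bins with an
#' implicit first edge at 0 um.
#'
#' @param path CSV file (UTF-8, header row, `.` decimal separator).
#' @param dialect `"bin_table"` or `"cumulative_passing"`.
#' @param diameter_basis Declared basis of the diameters in the file.
#' @return A [psd()] tibble.
#' @export
read_psd <- function(path, dialect = c("bin_table", "cumulative_passing"),
                     diameter_basis = c("spherical_equivalent",
                                        "aerodynamic")) {
  dialect <- match.arg(dialect)
  diameter_basis <- match.arg(diameter_basis)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "bin_table") {
    need <- c("lower_um", "upper_um", "fraction")
    if (!all(need %in% names(df)))
      stop("bin_table CSV must have columns lower_um, upper_um, fraction",
           call. = FALSE)
    psd(df$lower_um, df$upper_um, df$fraction,
        diameter_basis = diameter_basis)
  } else {
    need <- c("diameter_um", "cumulative_percent")
    if (!all(need %in% names(df)))
      stop(paste("cumulative_passing CSV must have columns diameter_um,",
                 "cumulative_percent"), call. = FALSE)
    d <- df$diameter_um
    cp <- df$cumulative_percent
    if (any(diff(d) <= 0))
      stop("diameter_um must be strictly increasing", call. = FALSE)
    if (any(diff(cp) < 0))
      stop("cumulative_percent must be non-decreasing", call. = FALSE)
    last <- cp[length(cp)]
    if (abs(last - 100) > 0.5)
      stop(sprintf("cumulative_percent must end at 100 +/- 0.5, got %g", last),
           call. = FALSE)
    psd(c(0, d[-length(d)]), d, diff(c(0, cp)) / last,
        diameter_basis = diameter_basis)
  }
}

#' Write a particle size distribution to CSV
#'
#' Writes the `bin_table` dialect (columns `lower_um`, `upper_um`,
#' `fraction`) so that `read_psd(write_psd(x))` is an identity within 1e-9.
#'
#' @param psd A [psd()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "swerf_psd"))
  df <- tibble::tibble(
    lower_um = formatC(psd$lower_um, digits = 15, format = "g"),
    upper_um = formatC(psd$upper_um, digits = 15, format = "g"),
    fraction = formatC(psd$fraction, digits = 15, format = "g")
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Convert a PSD from spherical-equivalent to aerodynamic diameter
#'
#' Scales every bin edge by \eqn{\sqrt{SG}} (or
#' \eqn{\sqrt{\rho_{eff}/1000}} when an effective density is set), the
#' relation between the spherical-equivalent diameter reported by laser
#' diffraction and the aerodynamic diameter of the sampling conventions:
#' \eqn{D = d\sqrt{SG}}. Bin fractions are unchanged.
#'
#' @param psd A [psd()] with `diameter_basis = "spherical_equivalent"`.
#' @param material A [material()] supplying the density.
#' @return The converted `swerf_psd` (aerodynamic basis).
#' @export
to_aerodynamic <- function(psd, material) {
  stopifnot(inherits(psd, "swerf_psd"), inherits(material, "swerf_material"))
  if (diameter_basis(psd) == "aerodynamic")
    stop("PSD is already on the aerodynamic basis; refusing double conversion",
         call. = FALSE)
  k <- sqrt(particle_density(material) / 1000)
  out <- psd
  out$lower_um <- psd$lower_um * k
  out$upper_um <- psd$upper_um * k
  attr(out, "diameter_basis") <- "aerodynamic"
  out
}

#' Median diameter (D50) of a PSD
#'
#' Median of the mass/volume distribution, by linear interpolation of the
#' cumulative curve within the bin containing 0.5.
#'
#' @param psd A [psd()] object.
#' @return The median diameter in um.
#' @export
d50 <- function(psd) {
  stopifnot(inherits(psd, "swerf_psd"))
  cum <- cumsum(psd$fraction)
  i <- which(cum >= 0.5)[1]
  below <- if (i == 1) 0 else cum[i - 1]
  w <- (0.5 - below) / psd$fraction[i]
  psd$lower_um[i] + w * (psd$upper_um[i] - psd$lower_um[i])
}

#' Plot a particle size distribution
#'
#' Mass/volume density against diameter on a log axis, with the median
#' marked.
#'
#' @param object A [psd()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot swerf_psd
#' @export
autoplot.swerf_psd <- function(object, ...) {
  df <- tibble::tibble(
    mid = bin_representative(object),
    density = object$fraction / (object$upper_um - object$lower_um)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = d50(object), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("diameter (um, %s)", gsub("_", "-", diameter_basis(object))),
      y = "mass density (per um)"
    )
}
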