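#' GHS/CLP STOT RE classification from the fine-fraction CS content
#'
#' Applies the generic concentration limits for specific target organ
#' toxicity, repeated exposure (silicosis endpoint): category 1 when the
#' fine-fraction crystalline silica content is >= 10% w/w, category 2 when it
#' is in \[1, 10)%, and no classification below 1%. The 1.0% boundary is
#' treated as the inclusive lower bound of category 2. Thresholds compare
#' full-precision values; round only for display.
#'
#' @param swerf_cs_percent Fine-fraction CS content in percent w/w
#'   (vectorised, in \[0, 100\]).
#' @return A tibble with `swerf_cs_percent`, `category` (`"STOT_RE_1"`,
#'   `"STOT_RE_2"` or `"NOT_CLASSIFIED"`) and `rule_applied`.
#' @examples
#' classify_stot_re(c(41.4, 5, 0.99))
#' @export
classify_stot_re <- function(swerf_cs_percent) {
  if (!is.numeric(swerf_cs_percent) || anyNA(swerf_cs_percent) ||
      any(swerf_cs_percent < 0 | swerf_cs_percent > 100))
    stop("`swerf_cs_percent` must lie in [0, 100]", call. = FALSE)
  category <- ifelse(
    swerf_cs_percent >= 10, "STOT_RE_1",
    ifelse(swerf_cs_percent >= 1, "STOT_RE_2", "NOT_CLASSIFIED")
  )
  rule <- c(
    STOT_RE_1 = "fine-fraction CS >= 10% w/w",
    STOT_RE_2 = "fine-fraction CS in [1, 10)% w/w",
    NOT_CLASSIFIED = "fine-fraction CS < 1% w/w"
  )
  tibble::tibble(
    swerf_cs_percent = swerf_cs_percent,
    category = category,
    rule_applied = unname(rule[category])
  )
}

#' Repeatability statistics of replicate SWeRF measurements
#'
#' Arithmetic mean and sample (n - 1) standard deviation of replicate
#' determinations, the summaries used to report method repeatability.
#'
#' @param values Numeric vector of at least two measurements (percent or
#'   fraction; units are preserved).
#' @return A one-row tibble with `n`, `mean` and `sd`.
#' @examples
#' repeatability_stats(c(17.6, 14.9, 14.8, 17.1, 14.9, 13.6, 15.2))
#' @export
repeatability_stats <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || anyNA(values))
    stop("need at least two non-missing measurements", call. = FALSE)
  tibble::tibble(n = length(values), mean = mean(values),
                 sd = stats::sd(values))
}

#' Agreement between two determinations of the same quantity
#'
#' Squared Pearson correlation between paired results from two methods
#' (e.g. calculated-from-PSD versus sedimentation), the recovery measurand
#' used in spiking and method-comparison studies. Computed from the
#' covariance/variance form directly.
#'
#' @param x,y Paired numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return The squared Pearson correlation (scalar in \[0, 1\]).
#' @examples
#' method_agreement_r2(c(0, 11.3, 21.9, 32.0, 41.4),
#'                     c(0, 9.8, 22.2, 32.4, 38.4))
#' @export
method_agreement_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3 || anyNA(x) || anyNA(y))
    stop("`x` and `y` must be complete, paired, length >= 3", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  sum(dx * dy)^2 / (vx * vy)
}

#' Render a SWeRF report
#'
#' Summarises a set of results as a table in the field's usual layout
#' (material, method, SWeRF %, SWeRF_CS %, STOT RE category), as markdown or
#' versioned JSON.
#'
#' @param results A `swerf_result` tibble.
#' @param path Output file.
#' @param format `"md"` or `"json"`.
#' @return `path`, invisibly.
#' @export
swerf_report <- function(results, path, format = c("md", "json")) {
  format <- match.arg(format)
  td <- tidy(results)
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON reports", call. = FALSE)
    payload <- list(swerf_report_version = "1.0", results = td)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    fmt1 <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
    lines <- c(
      "| Material | Method | SWeRF (%) | SWeRF_CS (%) | STOT RE |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s |",
              td$material, td$method, fmt1(td$swerf_percent),
              fmt1(td$swerf_cs_percent),
              ifelse(is.na(td$stot_re), "-", td$stot_re))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
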