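#' Correction constants for a survey
#'
#' Bundles the two laboratory quality-control quantities that drive the count
#' corrections: the spectroscopic verification subsample (how many counted
#' particles were analysed and how many of those were confirmed as
#' microplastic) and the procedural blanks (background particles observed in
#' control dishes run through the full extraction protocol).
#'
#' The defaults are the reference survey's values: 79 particles analysed, 64
#' confirmed, and 2 background particles over 3 control dishes.
#'
#' @param n_analyzed Number of counted particles put through spectroscopy.
#' @param n_verified Number of those confirmed as microplastic
#'   (`0 <= n_verified <= n_analyzed`).
#' @param blank_particles Total particles found in procedural blank dishes.
#' @param blank_units Number of blank dishes (>= 1).
#' @return An object of class `mp_constants` (a named list).
#' @seealso [verification_rate()], [blank_rate()]
#' @examples
#' mp_constants()
#' mp_constants(n_analyzed = 100, n_verified = 90)
#' @export
mp_constants <- function(n_analyzed = 79, n_verified = 64,
                         blank_particles = 2, blank_units = 3) {
  check_number(n_analyzed, "n_analyzed", min = 0)
  check_number(n_verified, "n_verified", min = 0)
  check_number(blank_particles, "blank_particles", min = 0)
  check_number(blank_units, "blank_units", min = 1)
  if (n_verified > n_analyzed) {
    stop_canmp("`n_verified` cannot exceed `n_analyzed`.", class = "validation")
  }
  structure(
    list(n_analyzed = n_analyzed, n_verified = n_verified,
         blank_particles = blank_particles, blank_units = blank_units),
    class = "mp_constants"
  )
}

#' @export
print.mp_constants <- function(x, ...) {
  cat("<mp_constants>\n")
  cat(sprintf("  verification: %d / %d analysed (rate %.4f)\n",
              x$n_verified, x$n_analyzed,
              if (x$n_analyzed > 0) x$n_verified / x$n_analyzed else NA_real_))
  cat(sprintf("  blanks:       %g particles / %g dishes (rate %.4f items/dish)\n",
              x$blank_particles, x$blank_units,
              x$blank_particles / x$blank_units))
  invisible(x)
}

#' Consumption scenarios for intake estimation
#'
#' Builds the scenario grid crossing consumption rates with exposure
#' frequencies. Two rates are used: per-capita canned-fish consumption
#' (`canned_fish`) and overall fish consumption (`fish`), both in
#' g/person/week. Exposure frequencies of 52, 156 and 260 days/year
#' correspond to eating the product one, three, or five days a week.
#'
#' Defaults are the Turkish per-capita figures used by the reference survey:
#' 0.54 g/person/week of canned fish and 16.84 g/person/week of fish.
#'
#' @param canned_fish_g_per_week Canned-fish consumption rate, g/person/week.
#' @param fish_g_per_week Fish consumption rate, g/person/week.
#' @param exposure_days Integer vector of exposure frequencies (days/year);
#'   the supported values are 52, 156 and 260.
#' @return A tibble with columns `label` (`canned_fish` / `fish`),
#'   `weekly_rate_g` and `exposure_days_per_year`, one row per scenario.
#' @examples
#' consumption_scenarios()
#' @export
consumption_scenarios <- function(canned_fish_g_per_week = 0.54,
                                  fish_g_per_week = 16.84,
                                  exposure_days = c(52L, 156L, 260L)) {
  check_number(canned_fish_g_per_week, "canned_fish_g_per_week", min = 0)
  check_number(fish_g_per_week, "fish_g_per_week", min = 0)
  if (canned_fish_g_per_week <= 0 || fish_g_per_week <= 0) {
    stop_canmp("Weekly consumption rates must be positive.", class = "validation")
  }
  bad <- setdiff(exposure_days, c(52L, 156L, 260L))
  if (length(bad)) {
    stop_canmp(sprintf("Unsupported exposure frequency: %s. Use 52, 156 or 260 days/year.",
                       paste(bad, collapse = ", ")),
               class = "validation")
  }
  tidyr::crossing(
    tibble(label = c("canned_fish", "fish"),
           weekly_rate_g = c(canned_fish_g_per_week, fish_g_per_week)),
    exposure_days_per_year = as.integer(exposure_days)
  ) |>
    arrange(.data$label, .data$exposure_days_per_year)
}

#' Path to a bundled reference data file
#'
#' The package ships the reference market survey of 33 canned fish products
#' (product metadata, per-brand concentrations with intake columns, and
#' polymer composition shares by particle shape) as plain CSV files.
#'
#' @param file File name, one of `"reference_products.csv"`,
#'   `"reference_concentrations.csv"`, `"reference_polymer_shares.csv"`.
#'   `NULL` lists the available files.
#' @return A file path (or a character vector of file names if `file` is NULL).
#' @examples
#' canmp_example()
#' canmp_example("reference_products.csv")
#' @export
canmp_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "canmp")))
  }
  path <- system.file("extdata", file, package = "canmp")
  if (identical(path, "")) {
    stop_canmp(sprintf("No bundled file named '%s'. See canmp_example() for options.",
                       file), class = "validation")
  }
  path
}
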