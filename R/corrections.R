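# Count corrections: spectroscopic verification scaling and procedural-blank
# subtraction. The order of operations matters and is deliberately
# scale-then-subtract at the survey level; see the methods vignette.

#' Spectroscopic verification rate
#'
#' Fraction of microscopically counted, microplastic-like particles that
#' spectroscopy confirmed as synthetic polymer. Applied multiplicatively to
#' raw counts, it corrects for visual over-counting. The rate is returned as
#' the exact ratio (e.g. 64/79 = 0.8101..., which displays as 81\%), never
#' pre-rounded, so it does not compound rounding error downstream.
#'
#' @param constants An [mp_constants()] object.
#' @return A single number in `[0, 1]`.
#' @examples
#' verification_rate(mp_constants())    # 64/79
#' @export
verification_rate <- function(constants) {
  stopifnot(inherits(constants, "mp_constants"))
  if (constants$n_analyzed < 1) {
    stop_canmp("Verification rate is undefined: no particles were analysed.",
               class = "undefined_rate")
  }
  constants$n_verified / constants$n_analyzed
}

#' Procedural blank rate
#'
#' Mean number of background particles per blank unit (one control dish run
#' through the full digestion/separation/filtration protocol). This is the
#' laboratory contamination level subtracted from the survey grand mean.
#'
#' @param constants An [mp_constants()] object.
#' @return Items per blank unit (e.g. 2/3 = 0.6667, displayed as 0.67).
#' @examples
#' blank_rate(mp_constants())    # 2/3
#' @export
blank_rate <- function(constants) {
  stopifnot(inherits(constants, "mp_constants"))
  if (constants$blank_units < 1) {
    stop_canmp("Blank rate is undefined: no blank dishes.", class = "undefined_rate")
  }
  constants$blank_particles / constants$blank_units
}

#' Per-brand raw concentrations from can-level counts
#'
#' Converts each can's particle count to a concentration
#' (`particle_count / subsample_mass_g * 100`, MPs/100 g) and summarises per
#' brand: the mean over replicate cans, the standard error (sample SD over
#' replicates divided by sqrt(n)), and the replicate count.
#'
#' @param observations A tibble as returned by [read_observations()] (or
#'   [simulate_survey()]), one row per can.
#' @return A tibble `code`, `raw_mean_per100g`, `std_error_per100g`,
#'   `n_replicates`, one row per brand. Brands with a single replicate get an
#'   `NA` standard error.
#' @examples
#' obs <- tibble::tibble(code = "X-1", replicate = 1:3,
#'                       subsample_mass_g = 50, particle_count = c(1L, 2L, 3L))
#' brand_concentrations(obs)   # mean 4, SE 1.1547
#' @export
brand_concentrations <- function(observations) {
  obs <- validate_observations(observations)
  if (nrow(obs) == 0) {
    stop_canmp("No observations supplied.", class = "validation")
  }
  obs |>
    mutate(per100g = .data$particle_count / .data$subsample_mass_g * 100) |>
    group_by(.data$code) |>
    summarise(
      raw_mean_per100g = mean(.data$per100g),
      std_error_per100g = if (n() > 1) stats::sd(.data$per100g) / sqrt(n()) else NA_real_,
      n_replicates = n(),
      .groups = "drop"
    ) |>
    arrange(.data$code)
}

#' Apply the verification correction to brand concentrations
#'
#' Scales each brand's raw mean by the verification rate:
#' `corrected_mean_per100g = raw_mean_per100g * rate`. No blank subtraction
#' happens at the brand level; background contamination is removed once, from
#' the survey grand mean (see [grand_mean()]). By default the standard error
#' is scaled by the same factor, consistent with scaling every replicate
#' value; set `scale_se = FALSE` to keep the raw-scale standard error.
#'
#' @param concentrations A tibble with `raw_mean_per100g` (and optionally
#'   `std_error_per100g`), e.g. from [brand_concentrations()].
#' @param rate Verification fraction in `[0, 1]`; see [verification_rate()].
#' @param scale_se Scale `std_error_per100g` by `rate` as well (default TRUE).
#' @return The input tibble with a `corrected_mean_per100g` column added (and
#'   `std_error_per100g` rescaled when requested). The choice made for the
#'   standard error is recorded in the `se_scaled` attribute.
#' @examples
#' conc <- tibble::tibble(code = c("D-C-1", "D-D-3"),
#'                        raw_mean_per100g = c(10, 16.67))
#' correct_concentrations(conc, 64 / 79)
#' @export
correct_concentrations <- function(concentrations, rate, scale_se = TRUE) {
  check_df_cols(concentrations, "raw_mean_per100g", "concentrations")
  check_number(rate, "rate", min = 0)
  if (length(rate) != 1 || rate > 1) {
    stop_canmp("`rate` must be a single fraction in [0, 1].", class = "validation")
  }
  out <- mutate(as_tibble(concentrations),
                corrected_mean_per100g = .data$raw_mean_per100g * rate)
  if (scale_se && "std_error_per100g" %in% names(out)) {
    out <- mutate(out, std_error_per100g = .data$std_error_per100g * rate)
  }
  attr(out, "se_scaled") <- scale_se && "std_error_per100g" %in% names(concentrations)
  out
}

#' Survey grand mean with verification and blank corrections
#'
#' The survey-level concentration: the unweighted mean of the per-brand raw
#' means, scaled by the verification rate, with the procedural-blank rate
#' then subtracted (floored at zero). The order is scale-then-subtract: the
#' blank particles were visually counted background items, so they are
#' removed from the corrected concentration, not scaled by the verification
#' rate.
#'
#' `blank_mode` controls the units of the subtraction:
#' \describe{
#'   \item{`"direct"`}{(default) subtracts the per-dish blank rate directly
#'     from the per-100 g grand mean. One dish corresponds to one 50 g
#'     subsample, so this convention under-subtracts by a factor of two, but
#'     it is the convention used by the reference survey and is kept as the
#'     default for comparability.}
#'   \item{`"unit_consistent"`}{converts the per-dish rate to per-100 g
#'     (`blank * 100 / subsample_mass_g`) before subtracting.}
#' }
#'
#' @param concentrations A tibble of per-brand values with `raw_mean_per100g`
#'   (a `grand` row, if present, is ignored).
#' @param rate Verification fraction; see [verification_rate()].
#' @param blank Blank rate in items per dish; see [blank_rate()].
#' @param blank_mode `"direct"` or `"unit_consistent"`.
#' @param subsample_mass_g Mass represented by one blank dish, used only by
#'   `"unit_consistent"` (default 50 g).
#' @return A one-row tibble: `code = "grand"`, `raw_mean_per100g`,
#'   `corrected_mean_per100g`, `std_error_per100g` (standard error of the
#'   verification-scaled brand means), `n_brands`, `blank_mode`.
#' @examples
#' conc <- read_concentrations(canmp_example("reference_concentrations.csv"))
#' grand_mean(conc[conc$code != "grand", ], rate = 64 / 79, blank = 2 / 3)
#' @export
grand_mean <- function(concentrations, rate, blank,
                       blank_mode = c("direct", "unit_consistent"),
                       subsample_mass_g = 50) {
  blank_mode <- arg_match(blank_mode)
  check_df_cols(concentrations, "raw_mean_per100g", "concentrations")
  check_number(rate, "rate", min = 0)
  check_number(blank, "blank", min = 0)
  brands <- filter(as_tibble(concentrations), .data$code != "grand")
  if (nrow(brands) == 0) {
    stop_canmp("No brand rows to average.", class = "validation")
  }
  subtract <- switch(blank_mode,
                     direct = blank,
                     unit_consistent = blank * 100 / subsample_mass_g)
  raw <- mean(brands$raw_mean_per100g)
  corrected_brand <- brands$raw_mean_per100g * rate
  tibble(
    code = "grand",
    raw_mean_per100g = raw,
    corrected_mean_per100g = max(0, raw * rate - subtract),
    std_error_per100g = if (nrow(brands) > 1) {
      stats::sd(corrected_brand) / sqrt(nrow(brands))
    } else NA_real_,
    n_brands = nrow(brands),
    blank_mode = blank_mode
  )
}
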