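# Annual microplastic intake: point estimates from consumption scenarios and
# Monte Carlo uncertainty propagation.

#' Daily consumption rate
#'
#' Converts a weekly per-capita consumption rate to g/person/day. The annual
#' intake formulas multiply a daily rate by an exposure frequency in
#' days/year, so weekly survey rates must be divided by 7 first.
#'
#' @param weekly_rate_g Consumption in g/person/week (positive).
#' @return g/person/day.
#' @examples
#' daily_rate(0.54)    # canned fish, Turkish per-capita rate
#' daily_rate(16.84)   # all fish
#' @export
daily_rate <- function(weekly_rate_g) {
  check_number(weekly_rate_g, "weekly_rate_g")
  if (any(weekly_rate_g <= 0)) {
    stop_canmp("`weekly_rate_g` must be positive.", class = "validation")
  }
  weekly_rate_g / 7
}

#' Annual microplastic intake
#'
#' The point intake estimate: `concentration (items/g) x daily consumption
#' (g/day) x exposure days (days/year)`, in items/person/year. Concentrations
#' are supplied on the conventional per-100 g scale and divided by 100
#' internally. Intake is linear in all three inputs.
#'
#' @param concentration_per100g Microplastic concentration, MPs/100 g
#'   (non-negative; typically a corrected mean).
#' @param weekly_rate_g Consumption rate, g/person/week.
#' @param exposure_days Exposure frequency, one of 52, 156, 260 days/year.
#' @return Items/person/year.
#' @examples
#' annual_intake(8.10, 16.84, 52)    # ~10.13 items/year
#' @export
annual_intake <- function(concentration_per100g, weekly_rate_g, exposure_days) {
  check_number(concentration_per100g, "concentration_per100g", min = 0)
  if (!all(exposure_days %in% c(52, 156, 260))) {
    stop_canmp(sprintf("Unsupported exposure frequency: %s. Use 52, 156 or 260 days/year.",
                       paste(setdiff(exposure_days, c(52, 156, 260)), collapse = ", ")),
               class = "validation")
  }
  concentration_per100g / 100 * daily_rate(weekly_rate_g) * exposure_days
}

#' Intake table across brands and scenarios
#'
#' Computes the annual intake for every brand (and `grand` row, if present)
#' under every consumption scenario. Set `round_concentration = TRUE` to
#' round corrected concentrations half-up to 2 decimals before computing
#' intakes, which matches how published survey tables are typically built
#' from their own printed concentration column ([reproduce_reference()] uses
#' this).
#'
#' @param concentrations A tibble with `code` and `corrected_mean_per100g`.
#' @param scenarios A scenario tibble from [consumption_scenarios()].
#' @param round_concentration Round concentrations to 2 decimals first
#'   (default FALSE: full precision).
#' @return A long tibble: `code`, `label`, `weekly_rate_g`,
#'   `exposure_days_per_year`, `intake_items_per_year`.
#' @examples
#' conc <- read_concentrations(canmp_example("reference_concentrations.csv"))
#' intake_table(conc, round_concentration = TRUE)
#' @export
intake_table <- function(concentrations, scenarios = consumption_scenarios(),
                         round_concentration = FALSE) {
  check_df_cols(concentrations, c("code", "corrected_mean_per100g"), "concentrations")
  if (anyNA(concentrations$corrected_mean_per100g)) {
    stop_canmp("Missing corrected means; run correct_concentrations() first.",
               class = "validation")
  }
  check_df_cols(scenarios, c("label", "weekly_rate_g", "exposure_days_per_year"),
                "scenarios")
  conc <- as_tibble(concentrations)[, c("code", "corrected_mean_per100g")]
  if (round_concentration) {
    conc$corrected_mean_per100g <- round_half_up(conc$corrected_mean_per100g, 2)
  }
  tidyr::crossing(conc, as_tibble(scenarios)) |>
    mutate(intake_items_per_year = annual_intake(
      .data$corrected_mean_per100g, .data$weekly_rate_g,
      .data$exposure_days_per_year)) |>
    select("code", "label", "weekly_rate_g", "exposure_days_per_year",
           "intake_items_per_year") |>
    arrange(.data$code, .data$label, .data$exposure_days_per_year)
}

#' Pivot an intake table to the conventional wide layout
#'
#' One row per code with columns `micf_52 ... micf_260` (canned-fish
#' scenarios) and `mif_52 ... mif_260` (fish scenarios).
#'
#' @param intakes A long intake tibble from [intake_table()].
#' @return A wide tibble, one row per `code`.
#' @export
intake_table_wide <- function(intakes) {
  check_df_cols(intakes, c("code", "label", "exposure_days_per_year",
                           "intake_items_per_year"), "intakes")
  intakes |>
    mutate(column = paste0(
      if_else(.data$label == "canned_fish", "micf_", "mif_"),
      .data$exposure_days_per_year)) |>
    select("code", "column", "intake_items_per_year") |>
    tidyr::pivot_wider(names_from = "column", values_from = "intake_items_per_year")
}

#' Monte Carlo configuration
#'
#' @param iterations Number of draws (default 10,000).
#' @param seed Optional integer seed; when set, results are reproducible and
#'   the seed is echoed in every output object.
#' @param truncate_at_zero Draw from the normal distribution truncated to
#'   non-negative values (default TRUE: an intake cannot be negative). FALSE
#'   mirrors a literal untruncated normal assumption.
#' @param percentiles Reported percentiles, in (0, 100) (default 5 and 95).
#' @return An object of class `mc_config`.
#' @seealso [mc_intake()]
#' @export
mc_config <- function(iterations = 10000, seed = NULL,
                      truncate_at_zero = TRUE, percentiles = c(5, 95)) {
  check_number(iterations, "iterations", min = 1)
  check_number(percentiles, "percentiles")
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop_canmp("`percentiles` must lie strictly between 0 and 100.",
               class = "validation")
  }
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(iterations = as.integer(iterations), seed = seed,
         truncate_at_zero = isTRUE(truncate_at_zero),
         percentiles = sort(percentiles)),
    class = "mc_config"
  )
}

mc_draw <- function(mean, sd, config) {
  n <- config$iterations
  if (sd == 0) return(rep(mean, n))
  if (config$truncate_at_zero) {
    # inverse-CDF sampling from Normal(mean, sd) truncated to [0, Inf)
    lo <- pnorm(0, mean, sd)
    qnorm(runif(n, lo, 1), mean, sd)
  } else {
    rnorm(n, mean, sd)
  }
}

#' Monte Carlo uncertainty for an intake estimate
#'
#' Propagates uncertainty through the intake calculation by simulation:
#' draws `iterations` values from `Normal(mean, sd)` (truncated at zero by
#' default) and summarises the empirical mean and the configured percentiles.
#' This is the probabilistic counterpart of the point estimate: the spread
#' parameter is the standard deviation of the quantity whose uncertainty is
#' being propagated (for a survey grand intake, the between-brand SD; see
#' [intake_uncertainty()]).
#'
#' @param mean Centre of the intake distribution, items/person/year.
#' @param sd Spread (standard deviation), items/person/year, `>= 0`.
#' @param config An [mc_config()] object.
#' @return An object of class `canmp_mc` with elements `draws`, `mean`,
#'   `percentiles` (named vector, e.g. `p5`/`p95`), `input` and `config`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- mc_intake(5.15, 4.48, mc_config(seed = 1))
#' glance(sim)
#' @export
mc_intake <- function(mean, sd, config = mc_config()) {
  stopifnot(inherits(config, "mc_config"))
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean) ||
      !is.numeric(sd) || length(sd) != 1 || !is.finite(sd)) {
    stop_canmp("`mean` and `sd` must be single finite numbers.",
               class = "validation")
  }
  if (sd < 0) stop_canmp("`sd` must be >= 0.", class = "validation")
  draws <- if (!is.null(config$seed)) {
    withr::with_seed(config$seed, mc_draw(mean, sd, config))
  } else {
    mc_draw(mean, sd, config)
  }
  q <- stats::quantile(draws, probs = config$percentiles / 100, names = FALSE)
  structure(
    list(
      draws = draws,
      mean = base::mean(draws),
      percentiles = setNames(q, paste0("p", config$percentiles)),
      input = c(mean = mean, sd = sd),
      config = config
    ),
    class = "canmp_mc"
  )
}

#' @export
print.canmp_mc <- function(x, ...) {
  cat("<canmp_mc> ", length(x$draws), " draws from Normal(",
      format(x$input[["mean"]], digits = 4), ", ",
      format(x$input[["sd"]], digits = 4), ")",
      if (x$config$truncate_at_zero) " truncated at 0", "\n", sep = "")
  stats <- c(mean = x$mean, x$percentiles)
  print(round(stats, 4))
  invisible(x)
}

#' @rdname mc_intake
#' @param x A `canmp_mc` object.
#' @param ... Unused.
#' @export
tidy.canmp_mc <- function(x, ...) {
  tibble(quantity = c("mean", names(x$percentiles)),
         value = unname(c(x$mean, x$percentiles)))
}

#' @rdname mc_intake
#' @method glance canmp_mc
#' @export
glance.canmp_mc <- function(x, ...) {
  out <- tibble(
    input_mean = x$input[["mean"]],
    input_sd = x$input[["sd"]],
    iterations = x$config$iterations,
    truncated = x$config$truncate_at_zero,
    mc_mean = x$mean
  )
  for (nm in names(x$percentiles)) out[[paste0("mc_", nm)]] <- x$percentiles[[nm]]
  out$seed <- if (is.null(x$config$seed)) NA_integer_ else as.integer(x$config$seed)
  out
}

#' Monte Carlo uncertainty across consumption scenarios
#'
#' Runs [mc_intake()] for every scenario, centring each simulation on the
#' scenario's point intake and giving it spread
#' `SE x sqrt(n_brands)` propagated through the same intake formula — i.e.
#' the between-brand standard deviation of the intake, reconstructed from
#' the grand concentration's standard error.
#'
#' When `config` has a seed, each scenario uses `seed + i` (row order) so
#' scenarios are independent but the whole table is reproducible.
#'
#' @param grand A one-row tibble from [grand_mean()] (needs
#'   `corrected_mean_per100g`, `std_error_per100g`, `n_brands`).
#' @param scenarios A tibble from [consumption_scenarios()].
#' @param config An [mc_config()] object.
#' @return A tibble with one row per scenario: `label`,
#'   `exposure_days_per_year`, `point_items_per_year`, `mc_mean`, and one
#'   `mc_p*` column per configured percentile.
#' @examples
#' conc <- read_concentrations(canmp_example("reference_concentrations.csv"))
#' g <- grand_mean(conc, rate = 64 / 79, blank = 2 / 3)
#' intake_uncertainty(g, config = mc_config(seed = 7))
#' @export
intake_uncertainty <- function(grand, scenarios = consumption_scenarios(),
                               config = mc_config()) {
  check_df_cols(grand, c("corrected_mean_per100g", "std_error_per100g", "n_brands"),
                "grand")
  stopifnot(nrow(grand) == 1)
  sd_conc <- grand$std_error_per100g * sqrt(grand$n_brands)
  rows <- as_tibble(scenarios)
  res <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    point <- annual_intake(grand$corrected_mean_per100g, rows$weekly_rate_g[i],
                           rows$exposure_days_per_year[i])
    sd_intake <- sd_conc / 100 * daily_rate(rows$weekly_rate_g[i]) *
      rows$exposure_days_per_year[i]
    cfg_i <- config
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + i
    sim <- mc_intake(point, sd_intake, cfg_i)
    row <- tibble(label = rows$label[i],
                  exposure_days_per_year = rows$exposure_days_per_year[i],
                  point_items_per_year = point,
                  mc_mean = sim$mean)
    for (nm in names(sim$percentiles)) {
      row[[paste0("mc_", nm)]] <- sim$percentiles[[nm]]
    }
    res[[i]] <- row
  }
  bind_rows(res)
}
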