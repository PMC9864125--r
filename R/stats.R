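# Inferential stage: normality checks, log transformation, one-way ANOVA
# across survey factors, weight-abundance correlation.

#' Logarithmic transformation for count-derived abundances
#'
#' `log(x + offset)` with `offset = 1` by default, so zero abundances map to
#' zero and ordering is preserved. Set `offset = 0` for a plain log on
#' strictly positive data.
#'
#' @param values Non-negative numeric vector.
#' @param offset Added before taking the log (default 1).
#' @return Transformed vector.
#' @examples
#' log_transform(c(0, exp(1) - 1))   # 0, 1
#' @export
log_transform <- function(values, offset = 1) {
  check_number(values, "values")
  if (any(values < 0)) {
    stop_canmp("`values` must be non-negative.", class = "validation")
  }
  if (offset == 0 && any(values == 0)) {
    stop_canmp("Plain log (offset = 0) requires strictly positive values.",
               class = "validation")
  }
  log(values + offset)
}

#' Normality tests
#'
#' Runs the two standard normality checks on one sample: Shapiro-Wilk, and a
#' Kolmogorov-Smirnov-type test. Because the normal parameters are estimated
#' from the same data, the KS variant used is the Lilliefors-corrected test
#' (`nortest::lillie.test`) whenever `n >= 4`; at `n = 3` the plain KS test
#' against the fitted normal is reported instead. A sample is flagged
#' non-normal when either test rejects at `alpha`.
#'
#' A constant (zero-variance) vector cannot be tested: the result carries
#' `degenerate = TRUE` with `NA` statistics, with a warning.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level for the `non_normal` flag (default 0.05).
#' @return A tibble with one row per test: `test`, `statistic`, `p_value`,
#'   `non_normal`, `degenerate`.
#' @examples
#' normality_tests(rnorm(50))
#' @export
normality_tests <- function(values, alpha = 0.05) {
  check_number(values, "values")
  n <- length(values)
  if (n < 3) {
    stop_canmp("Normality tests need at least 3 observations.", class = "validation")
  }
  if (stats::sd(values) == 0) {
    warn("Constant sample: normality tests are degenerate.",
         class = "canmp_degenerate")
    return(tibble(test = c("kolmogorov_smirnov", "shapiro_wilk"),
                  statistic = NA_real_, p_value = NA_real_,
                  non_normal = NA, degenerate = TRUE))
  }
  ks <- if (n >= 4) {
    nortest::lillie.test(values)
  } else {
    suppressWarnings(ks.test(values, "pnorm", base::mean(values), stats::sd(values)))
  }
  sw <- shapiro.test(if (n > 5000) sample(values, 5000) else values)
  tibble(
    test = c("kolmogorov_smirnov", "shapiro_wilk"),
    statistic = c(unname(ks$statistic), unname(sw$statistic)),
    p_value = c(ks$p.value, sw$p.value),
    non_normal = c(ks$p.value, sw$p.value) < alpha,
    degenerate = FALSE
  )
}

#' One-way ANOVA on (log-transformed) abundances
#'
#' Classical one-way analysis of variance of a per-can abundance against a
#' grouping factor. Abundances are log(x+1)-transformed by default before
#' fitting, the usual variance-stabilising choice for right-skewed count
#' concentrations. Groups with fewer than 2 observations are dropped with a
#' warning (several survey factor levels contain a single brand); if fewer
#' than 2 usable groups remain, an error is raised.
#'
#' @param data A data frame.
#' @param value Column with the response (per-can abundance, MPs/100 g);
#'   bare name or string.
#' @param group Grouping column; bare name or string.
#' @param log_transform Apply [log_transform()] first (default TRUE).
#' @return A one-row tibble: `factor`, `n_groups`, `n_obs`, `df_between`,
#'   `df_within`, `f_statistic`, `p_value`, `transformed`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 7, 8, 9))
#' one_way_anova(d, y, g)
#' @export
one_way_anova <- function(data, value, group, log_transform = TRUE) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  check_df_cols(data, c(value, group), "data")
  d <- tibble(y = as.numeric(data[[value]]), g = as.character(data[[group]]))
  d <- filter(d, !is.na(.data$y), !is.na(.data$g))
  sizes <- count(d, .data$g)
  drop <- sizes$g[sizes$n < 2]
  if (length(drop)) {
    warn(sprintf("Dropping group(s) with a single observation: %s.",
                 paste(drop, collapse = ", ")),
         class = "canmp_dropped_groups")
    d <- filter(d, !.data$g %in% drop)
  }
  if (length(unique(d$g)) < 2) {
    stop_canmp("One-way ANOVA needs at least 2 groups with >= 2 observations.",
               class = "validation")
  }
  if (log_transform) d$y <- log_transform(d$y)
  if (stats::sd(d$y) == 0) {
    # no variation at all: between- and within-group mean squares are both 0
    return(tibble(factor = group, n_groups = length(unique(d$g)),
                  n_obs = nrow(d),
                  df_between = length(unique(d$g)) - 1L,
                  df_within = nrow(d) - length(unique(d$g)),
                  f_statistic = 0, p_value = 1, transformed = log_transform))
  }
  fit <- anova(lm(y ~ g, data = d))
  tibble(
    factor = group,
    n_groups = length(unique(d$g)),
    n_obs = nrow(d),
    df_between = fit$Df[1],
    df_within = fit$Df[2],
    f_statistic = fit$`F value`[1],
    p_value = fit$`Pr(>F)`[1],
    transformed = log_transform
  )
}

#' Pearson correlation of product weight and abundance
#'
#' Standard product-moment correlation with a two-sided test, used to check
#' whether heavier products carry systematically different microplastic
#' abundances.
#'
#' @param weights Product weights, g.
#' @param abundances Abundances, MPs/100 g (same length, `n >= 3`).
#' @return A one-row tibble: `r`, `statistic`, `p_value`, `n`.
#' @examples
#' pearson_weight_abundance(c(80, 100, 120, 160), c(2, 3, 5, 8))
#' @export
pearson_weight_abundance <- function(weights, abundances) {
  check_number(weights, "weights")
  check_number(abundances, "abundances")
  if (length(weights) != length(abundances) || length(weights) < 3) {
    stop_canmp("`weights` and `abundances` must have equal length >= 3.",
               class = "validation")
  }
  if (stats::sd(weights) == 0 || stats::sd(abundances) == 0) {
    stop_canmp("Correlation is undefined for a zero-variance vector.",
               class = "validation")
  }
  ct <- cor.test(weights, abundances, method = "pearson")
  tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = length(weights))
}

#' Per-can abundances joined with product factors
#'
#' Builds the analysis table for the inferential stage: each can's abundance
#' (MPs/100 g) with the survey factors derived from product metadata —
#' `producer`, `package_type`, `oil_type` (first oil named, or `none`),
#' `water_usage` (whether water appears among the other additives) and
#' `species`.
#'
#' @param products A tibble from [read_products()].
#' @param observations A tibble from [read_observations()].
#' @return A tibble with one row per can.
#' @seealso [survey_anova()]
#' @export
abundance_by_factor <- function(products, observations) {
  check_df_cols(products, c("code", "species", "additive_oil", "other_additives",
                            "product_weight_g", "package_type"), "products")
  obs <- validate_observations(observations)
  oil <- tolower(products$additive_oil)
  oil_type <- dplyr::case_when(
    grepl("sunflower", oil) ~ "sunflower",
    grepl("olive", oil) ~ "olive",
    grepl("canola", oil) ~ "canola",
    TRUE ~ "none"
  )
  meta <- tibble(
    code = products$code,
    producer = producer_of(products$code),
    package_type = products$package_type,
    oil_type = oil_type,
    water_usage = if_else(grepl("water", tolower(products$other_additives)),
                          "water", "no_water"),
    species = products$species,
    product_weight_g = products$product_weight_g
  )
  obs |>
    mutate(abundance_per100g = .data$particle_count / .data$subsample_mass_g * 100) |>
    left_join(meta, by = "code")
}

#' One-way ANOVA across every survey factor
#'
#' Runs [one_way_anova()] of per-can abundance against each survey factor in
#' turn (the inferential stage of a market-basket survey). Analyses per-can
#' values by default; `per_brand = TRUE` aggregates to brand means first,
#' avoiding pseudo-replication of cans within brand at the cost of power.
#'
#' @param products A tibble from [read_products()].
#' @param observations A tibble from [read_observations()].
#' @param factors Factors to test (default all five).
#' @param per_brand Aggregate cans to brand means before testing.
#' @param log_transform Passed to [one_way_anova()].
#' @return A tibble with one row per factor, as in [one_way_anova()].
#' @examples
#' \dontrun{
#' survey <- simulate_survey(survey_config(seed = 1))
#' survey_anova(survey$products, survey$observations)
#' }
#' @export
survey_anova <- function(products, observations,
                         factors = c("producer", "package_type", "oil_type",
                                     "water_usage", "species"),
                         per_brand = FALSE, log_transform = TRUE) {
  d <- abundance_by_factor(products, observations)
  if (per_brand) {
    d <- d |>
      group_by(across(dplyr::all_of(c("code", factors)))) |>
      summarise(abundance_per100g = base::mean(.data$abundance_per100g),
                .groups = "drop")
  }
  purrr::map(factors, function(f) {
    res <- tryCatch(
      withCallingHandlers(
        one_way_anova(d[, c("abundance_per100g", f)],
                      "abundance_per100g", !!f, log_transform = log_transform),
        canmp_dropped_groups = function(w) rlang::cnd_muffle(w)
      ),
      canmp_validation = function(e) {
        tibble(factor = f, n_groups = NA_integer_, n_obs = NA_integer_,
               df_between = NA_integer_, df_within = NA_integer_,
               f_statistic = NA_real_, p_value = NA_real_,
               transformed = log_transform)
      }
    )
    res$factor <- f
    res
  }) |>
    bind_rows()
}
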