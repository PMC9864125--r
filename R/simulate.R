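# Synthetic market-basket survey generator. Every pipeline stage can be
# exercised and parameter-recovery tested without laboratory data.

default_shape_probs <- c(fragment = 0.573, fiber = 0.427)
default_color_probs <- c(blue = 0.348, black = 0.273, white = 0.119,
                         transparent = 0.106, other = 0.154)
# polymer frequencies of confirmed particles (pooled fiber + fragment counts)
default_polymer_probs <- c(
  "Polyolefin" = 14, "Polyacrylonitrile" = 7,
  "Poly(methacrylic acid methyl ester)" = 6, "Polypropylene" = 5,
  "Polyethylene Terephthalate" = 5, "Polyamide - Nylon 6, 6" = 5,
  "Polyvinylidene chloride" = 4, "Polystyrene" = 4, "Polyethylene" = 4,
  "Poly(vinyl acetate)" = 4, "Epoxy" = 2, "Chitin" = 2,
  "Ethylene-vinyl acetate" = 1, "Cellulose" = 1
) / 64

#' Synthetic survey configuration
#'
#' Defines the statistical structure of a generated market-basket survey.
#' The defaults emulate the reference study design: 33 products from 7
#' producers, 3 replicate cans per product, 50 g subsamples, brand
#' intensities spanning 1-17 MPs/100 g, a background contamination rate of
#' 2/3 particles per filter, a true-microplastic probability of 64/79 for
#' counted particles, and shape/colour/polymer/size distributions matching
#' the reference survey's composition results.
#'
#' Counts are Poisson at the can level: can count ~
#' `Poisson(lambda_brand * subsample_mass_g / 100 + blank_rate_per_petri)`,
#' where `lambda_brand` is drawn uniformly from `brand_lambda_range` and
#' multiplied by a log-normal producer effect `exp(N(0, producer_effect_sd))`
#' shared by all brands of a producer. Particle sizes are log-normal,
#' truncated to the observed per-shape ranges (0.06-5.14 mm for fragments,
#' 0.27-5.89 mm for fibers).
#'
#' @param n_producers Number of producers (default 7).
#' @param n_brands Total number of products/brands (default 33), dealt to
#'   producers round-robin.
#' @param replicates_per_brand Cans per brand (default 3).
#' @param subsample_mass_g Digested mass per can, g (default 50).
#' @param brand_lambda_range Range of per-100 g Poisson intensities (default
#'   `c(1, 17)`).
#' @param producer_effect_sd SD of the multiplicative (log-scale) producer
#'   effect (default 0.5: producers differ by roughly +/- 65\%, enough to be
#'   detectable by ANOVA at this survey size; 0 removes the effect).
#' @param blank_rate_per_petri Expected background particles per filter and
#'   per blank dish (default 2/3).
#' @param n_blank_dishes Procedural blank dishes (default 3).
#' @param verification_true_mp_prob Probability a counted particle is truly
#'   plastic (default 64/79).
#' @param analyzed_fraction Fraction of particles randomly selected for
#'   spectroscopy (default 0.3).
#' @param shape_probs,color_probs,polymer_probs Named probability vectors
#'   for particle attributes (defaults: reference composition).
#' @param size_meanlog,size_sdlog Log-normal size parameters, mm scale
#'   (defaults log(0.8) and 0.9: median 0.8 mm, long right tail).
#' @param seed Optional integer seed stored in the config; [simulate_survey()]
#'   uses it when no explicit seed is given.
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(n_producers = 7, n_brands = 33,
                          replicates_per_brand = 3, subsample_mass_g = 50,
                          brand_lambda_range = c(1, 17),
                          producer_effect_sd = 0.5,
                          blank_rate_per_petri = 2 / 3, n_blank_dishes = 3,
                          verification_true_mp_prob = 64 / 79,
                          analyzed_fraction = 0.3,
                          shape_probs = default_shape_probs,
                          color_probs = default_color_probs,
                          polymer_probs = default_polymer_probs,
                          size_meanlog = log(0.8), size_sdlog = 0.9,
                          seed = NULL) {
  check_number(n_producers, "n_producers", min = 1)
  check_number(n_brands, "n_brands", min = 1)
  check_number(replicates_per_brand, "replicates_per_brand", min = 1)
  check_number(subsample_mass_g, "subsample_mass_g")
  if (subsample_mass_g <= 0) {
    stop_canmp("`subsample_mass_g` must be positive.", class = "validation")
  }
  check_number(brand_lambda_range, "brand_lambda_range", min = 0)
  if (length(brand_lambda_range) != 2 || any(brand_lambda_range <= 0) ||
      brand_lambda_range[1] > brand_lambda_range[2]) {
    stop_canmp("`brand_lambda_range` must be two positive increasing bounds.",
               class = "validation")
  }
  check_number(producer_effect_sd, "producer_effect_sd", min = 0)
  check_number(blank_rate_per_petri, "blank_rate_per_petri", min = 0)
  check_number(n_blank_dishes, "n_blank_dishes", min = 1)
  for (p in list(verification_true_mp_prob = verification_true_mp_prob,
                 analyzed_fraction = analyzed_fraction)) {
    if (p < 0 || p > 1) {
      stop_canmp("Probabilities must lie in [0, 1].", class = "validation")
    }
  }
  for (nm in c("shape_probs", "color_probs", "polymer_probs")) {
    pr <- get(nm)
    if (is.null(names(pr)) || any(pr < 0) || abs(sum(pr) - 1) > 1e-6) {
      stop_canmp(sprintf("`%s` must be named, non-negative and sum to 1.", nm),
                 class = "validation")
    }
  }
  structure(
    list(n_producers = as.integer(n_producers), n_brands = as.integer(n_brands),
         replicates_per_brand = as.integer(replicates_per_brand),
         subsample_mass_g = subsample_mass_g,
         brand_lambda_range = brand_lambda_range,
         producer_effect_sd = producer_effect_sd,
         blank_rate_per_petri = blank_rate_per_petri,
         n_blank_dishes = as.integer(n_blank_dishes),
         verification_true_mp_prob = verification_true_mp_prob,
         analyzed_fraction = analyzed_fraction,
         shape_probs = shape_probs, color_probs = color_probs,
         polymer_probs = polymer_probs,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         seed = seed),
    class = "survey_config"
  )
}

sample_levels <- function(n, probs) {
  if (n == 0) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# log-normal truncated to (lo, hi) by inverse-CDF
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  if (n == 0) return(numeric())
  p <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(p, meanlog, sdlog)
}

simulate_survey_impl <- function(config) {
  producers <- LETTERS[rep_len(seq_len(config$n_producers), config$n_brands)]
  codes <- paste0(producers, "-", stats::ave(seq_along(producers), producers,
                                             FUN = seq_along))
  pe <- rnorm(config$n_producers, 0, config$producer_effect_sd)
  lambda0 <- runif(config$n_brands, config$brand_lambda_range[1],
                   config$brand_lambda_range[2])
  lambda <- lambda0 * exp(pe[match(producers, LETTERS)])

  products <- tibble(
    code = codes,
    producer = producers,
    party_no = sprintf("L%04d", seq_along(codes)),
    species = sample(c("Tuna", "Yellowfin Tuna", "Skipjack", "Salmon",
                       "Mackerel", "Anchovy"),
                     length(codes), replace = TRUE,
                     prob = c(0.55, 0.12, 0.15, 0.09, 0.06, 0.03)),
    additive_oil = sample(c("Sunflower oil", "Olive oil", "None"),
                          length(codes), replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)),
    other_additives = sample(c("Salt", "Water, salt"), length(codes),
                             replace = TRUE, prob = c(0.5, 0.5)),
    product_weight_g = sample(c(75, 80, 100, 110, 120, 125, 160, 185),
                              length(codes), replace = TRUE),
    package_type = sample(PACKAGE_TYPES, length(codes), replace = TRUE,
                          prob = c(0.70, 0.06, 0.12, 0.09, 0.03))
  )
  products$package_label <- products$package_type

  reps <- config$replicates_per_brand
  observations <- tibble(
    code = rep(codes, each = reps),
    replicate = rep(seq_len(reps), times = length(codes)),
    subsample_mass_g = config$subsample_mass_g
  )
  signal_mean <- rep(lambda, each = reps) * config$subsample_mass_g / 100
  signal <- rpois(nrow(observations), signal_mean)
  background <- rpois(nrow(observations), config$blank_rate_per_petri)
  observations$particle_count <- as.integer(signal + background)

  n_particles <- sum(observations$particle_count)
  particles <- tibble(
    sample_id = rep(paste0(observations$code, "-r", observations$replicate),
                    times = observations$particle_count),
    shape = sample_levels(n_particles, config$shape_probs),
    color = sample_levels(n_particles, config$color_probs),
    size_mm = NA_real_,
    polymer = NA_character_,
    verified = "not_analyzed"
  )
  is_fiber <- particles$shape == "fiber"
  particles$size_mm[is_fiber] <- rlnorm_trunc(sum(is_fiber), config$size_meanlog,
                                              config$size_sdlog, 0.27, 5.89)
  particles$size_mm[!is_fiber] <- rlnorm_trunc(sum(!is_fiber), config$size_meanlog,
                                               config$size_sdlog, 0.06, 5.14)
  true_mp <- runif(n_particles) < config$verification_true_mp_prob
  n_analyzed <- round(config$analyzed_fraction * n_particles)
  analyzed <- seq_len(n_particles) %in% sample.int(n_particles, n_analyzed)
  particles$verified[analyzed & true_mp] <- "verified_mp"
  particles$verified[analyzed & !true_mp] <- "rejected"
  conf <- analyzed & true_mp
  particles$polymer[conf] <- sample_levels(sum(conf), config$polymer_probs)

  list(
    products = products,
    observations = observations,
    particles = particles,
    truth = list(
      lambda = tibble(code = codes, producer = producers, lambda_per100g = lambda),
      producer_effect = tibble(producer = LETTERS[seq_len(config$n_producers)],
                               log_effect = pe),
      true_mp = true_mp,
      config = config
    )
  )
}

#' Generate a synthetic market-basket survey
#'
#' Draws a complete survey — product metadata, per-can particle counts, and
#' per-particle attributes with latent true-microplastic labels and a random
#' spectroscopy subsample — from a [survey_config()]. Deterministic under a
#' fixed seed.
#'
#' The returned `truth` element records everything needed for parameter
#' recovery: the drawn brand intensities (`lambda_per100g`, background
#' excluded), the producer effects, the latent particle labels, and the
#' config itself.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed; defaults to `config$seed`. `NULL` draws from the
#'   current RNG state.
#' @return A list of class `canmp_survey`: `products`, `observations`,
#'   `particles` (tibbles in the package CSV schemas) and `truth`.
#' @examples
#' survey <- simulate_survey(survey_config(seed = 42))
#' head(survey$observations)
#' @export
simulate_survey <- function(config = survey_config(), seed = config$seed) {
  stopifnot(inherits(config, "survey_config"))
  out <- if (!is.null(seed)) {
    withr::with_seed(seed, simulate_survey_impl(config))
  } else {
    simulate_survey_impl(config)
  }
  out$truth$seed <- seed
  structure(out, class = "canmp_survey")
}

#' @export
print.canmp_survey <- function(x, ...) {
  cat("<canmp_survey> ", nrow(x$products), " products, ",
      nrow(x$observations), " cans, ", nrow(x$particles), " particles\n",
      sep = "")
  invisible(x)
}

#' Generate procedural blank observations
#'
#' Simulates the negative-control dishes: each blank dish receives a
#' Poisson(`blank_rate_per_petri`) background count.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble `dish`, `particle_count`.
#' @examples
#' simulate_blanks(survey_config(seed = 1))
#' @export
simulate_blanks <- function(config = survey_config(), seed = config$seed) {
  stopifnot(inherits(config, "survey_config"))
  draw <- function() {
    tibble(dish = seq_len(config$n_blank_dishes),
           particle_count = rpois(config$n_blank_dishes,
                                  config$blank_rate_per_petri))
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}
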