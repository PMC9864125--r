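test_that("survey generation is deterministic under a fixed seed", {
  cfg <- survey_config(seed = 77)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$particles, b$particles)
  expect_identical(a$truth$lambda, b$truth$lambda)
  c <- simulate_survey(cfg, seed = 78)
  expect_false(identical(a$observations$particle_count,
                         c$observations$particle_count))
})

test_that("generated surveys have the configured design structure", {
  cfg <- survey_config(n_producers = 4, n_brands = 10, replicates_per_brand = 2,
                       seed = 5)
  s <- simulate_survey(cfg)
  expect_equal(nrow(s$products), 10)
  expect_equal(nrow(s$observations), 20)
  expect_equal(sort(unique(s$products$producer)), LETTERS[1:4])
  expect_equal(unique(s$observations$subsample_mass_g), 50)
  # replicates consecutive from 1 (accepted by the validators)
  expect_silent(brand_concentrations(s$observations))
  expect_equal(nrow(s$particles), sum(s$observations$particle_count))
  # sizes respect the shape-specific truncation ranges
  fib <- s$particles$size_mm[s$particles$shape == "fiber"]
  frg <- s$particles$size_mm[s$particles$shape == "fragment"]
  expect_true(all(fib >= 0.27 & fib <= 5.89))
  expect_true(all(frg >= 0.06 & frg <= 5.14))
})

test_that("mean observed concentration matches the Poisson intensity", {
  # lambda fixed at 10 per 100 g, no producer effect, no background:
  # per-can concentration has mean 10
  cfg <- survey_config(n_producers = 1, n_brands = 100, replicates_per_brand = 100,
                       brand_lambda_range = c(10, 10), producer_effect_sd = 0,
                       blank_rate_per_petri = 0, seed = 6)
  s <- simulate_survey(cfg)
  conc <- s$observations$particle_count / s$observations$subsample_mass_g * 100
  expect_equal(mean(conc), 10, tolerance = 0.2 / 10)
})

test_that("latent verification labels drive the observed verification rate", {
  cfg <- survey_config(verification_true_mp_prob = 1, seed = 8)
  s <- simulate_survey(cfg)
  analyzed <- s$particles$verified != "not_analyzed"
  expect_gt(sum(analyzed), 0)
  expect_equal(sum(s$particles$verified == "verified_mp") / sum(analyzed), 1)
  # roughly 30% of particles go to spectroscopy
  expect_equal(mean(analyzed), 0.3, tolerance = 0.02)

  cfg0 <- survey_config(verification_true_mp_prob = 0, seed = 8)
  s0 <- simulate_survey(cfg0)
  expect_equal(sum(s0$particles$verified == "verified_mp"), 0)
})

test_that("blank dishes follow the configured Poisson background", {
  expect_equal(simulate_blanks(survey_config(blank_rate_per_petri = 0, seed = 1))$particle_count,
               c(0L, 0L, 0L))
  big <- simulate_blanks(survey_config(blank_rate_per_petri = 2 / 3,
                                       n_blank_dishes = 30000, seed = 2))
  expect_equal(mean(big$particle_count), 2 / 3, tolerance = 0.02 / (2 / 3))
  expect_identical(simulate_blanks(survey_config(seed = 3)),
                   simulate_blanks(survey_config(seed = 3)))
})

test_that("invalid configurations fail before generating anything", {
  expect_error(survey_config(brand_lambda_range = c(5, 1)), class = "canmp_validation")
  expect_error(survey_config(brand_lambda_range = c(-1, 4)), class = "canmp_validation")
  expect_error(survey_config(verification_true_mp_prob = 1.2), class = "canmp_validation")
  expect_error(survey_config(shape_probs = c(fiber = 0.6, fragment = 0.6)),
               class = "canmp_validation")
  expect_error(survey_config(subsample_mass_g = 0), class = "canmp_validation")
})

test_that("composition of a large particle draw recovers the configured shares", {
  # enough brands that well over 5,000 particles are drawn
  cfg <- survey_config(n_producers = 10, n_brands = 400, producer_effect_sd = 0,
                       seed = 14)
  s <- simulate_survey(cfg)
  expect_gt(nrow(s$particles), 5000)
  shp <- composition_summary(s$particles, "shape")
  expect_equal(shp$share_pct[shp$label == "fragment"], 57.3, tolerance = 2 / 57.3)
  expect_equal(shp$share_pct[shp$label == "fiber"], 42.7, tolerance = 2 / 42.7)
  col <- composition_summary(s$particles, "color")
  expect_equal(col$share_pct[col$label == "blue"], 34.8, tolerance = 2 / 34.8)
})
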