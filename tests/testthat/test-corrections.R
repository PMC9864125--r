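test_that("verification and blank rates are exact ratios", {
  k <- mp_constants()
  expect_equal(verification_rate(k), 64 / 79)
  expect_equal(round(verification_rate(k) * 100), 81)  # displays as 81%
  expect_equal(blank_rate(k), 2 / 3)
  expect_equal(round_half_up(blank_rate(k), 2), 0.67)  # displays as 0.67/petri

  expect_equal(verification_rate(mp_constants(10, 10)), 1)
  expect_equal(verification_rate(mp_constants(10, 0)), 0)
  expect_equal(blank_rate(mp_constants(blank_particles = 6, blank_units = 4)), 1.5)
  expect_equal(blank_rate(mp_constants(blank_particles = 0)), 0)

  expect_error(verification_rate(mp_constants(n_analyzed = 0, n_verified = 0)),
               class = "canmp_undefined_rate")
  expect_error(mp_constants(n_analyzed = 10, n_verified = 12),
               class = "canmp_validation")
  expect_error(mp_constants(blank_units = 0), class = "canmp_validation")
})

test_that("brand concentrations aggregate replicate cans to per-100 g summaries", {
  # counts 5,5,5 at 50 g: each can is 10 per 100 g
  even <- brand_concentrations(make_observations(c(5, 5, 5)))
  expect_equal(even$raw_mean_per100g, 10)
  expect_equal(even$std_error_per100g, 0)

  # counts 1,2,3 at 50 g: per-can values 2,4,6 -> mean 4, SE sd(2,4,6)/sqrt(3)
  hand <- brand_concentrations(make_observations(c(1, 2, 3)))
  expect_equal(hand$raw_mean_per100g, 4)
  expect_equal(hand$std_error_per100g, 2 / sqrt(3))
  expect_equal(hand$n_replicates, 3L)

  zero <- brand_concentrations(make_observations(c(0, 0, 0)))
  expect_equal(zero$raw_mean_per100g, 0)
  expect_equal(zero$std_error_per100g, 0)

  # multiple brands aggregate independently; mass enters the scaling
  two <- dplyr::bind_rows(make_observations(c(2, 2), code = "A-1", mass = 100),
                          make_observations(c(5, 5, 5), code = "B-1"))
  res <- brand_concentrations(two)
  expect_equal(res$raw_mean_per100g[res$code == "A-1"], 2)
  expect_equal(res$n_replicates, c(2L, 3L))
})

test_that("verification correction scales brand means without blank subtraction", {
  conc <- tibble::tibble(code = c("D-C-1", "D-D-3"),
                         raw_mean_per100g = c(10.00, 16.67),
                         std_error_per100g = c(1.89, 2.88))
  out <- correct_concentrations(conc, 64 / 79)
  expect_equal(round_half_up(out$corrected_mean_per100g, 2), c(8.10, 13.50))
  # SE scaled by the same factor; raw means untouched
  expect_equal(out$std_error_per100g, conc$std_error_per100g * 64 / 79)
  expect_equal(out$raw_mean_per100g, conc$raw_mean_per100g)
  expect_true(attr(out, "se_scaled"))

  identity <- correct_concentrations(conc, 1)
  expect_equal(identity$corrected_mean_per100g, conc$raw_mean_per100g)
})

test_that("grand mean scales then subtracts the blank, floored at zero", {
  # derived oracle: two brands raw (10, 20), rate 0.5, blank 1 -> 15*0.5 - 1
  two <- tibble::tibble(code = c("A-1", "B-1"), raw_mean_per100g = c(10, 20))
  g <- grand_mean(two, rate = 0.5, blank = 1)
  expect_equal(g$corrected_mean_per100g, 6.5)
  expect_equal(g$raw_mean_per100g, 15)
  expect_equal(g$code, "grand")

  # blank equal to the scaled signal floors at zero
  one <- tibble::tibble(code = "A-1", raw_mean_per100g = 0.67 * (79 / 64))
  g0 <- grand_mean(one, rate = 64 / 79, blank = 0.67)
  expect_equal(g0$corrected_mean_per100g, 0)

  expect_error(grand_mean(two[0, ], rate = 1, blank = 0),
               class = "canmp_validation")
})

test_that("the reference table's grand summary follows from its raw means", {
  conc <- reference_concentration_fixture()
  g <- grand_mean(conc, rate = 64 / 79, blank = 2 / 3)
  expect_equal(g$raw_mean_per100g, 5.93, tolerance = 0.005 / 5.93)
  expect_equal(g$n_brands, 33L)
  # scale-then-subtract lands near the printed 4.12; the reversed order
  # (subtract-then-scale) would give 4.26 and is clearly distinguishable
  expect_equal(g$corrected_mean_per100g, 4.137, tolerance = 0.001)
  reversed <- (g$raw_mean_per100g - 2 / 3) * 64 / 79
  expect_equal(reversed, 4.263, tolerance = 0.001)
  # SE of the corrected mean is the SD of the scaled brand means over sqrt(33)
  brands <- conc$raw_mean_per100g[conc$code != "grand"] * 64 / 79
  expect_equal(g$std_error_per100g, sd(brands) / sqrt(33))

  # unit-consistent mode subtracts the per-100 g equivalent of one 50 g dish
  strict <- grand_mean(conc, rate = 64 / 79, blank = 2 / 3,
                       blank_mode = "unit_consistent")
  expect_equal(strict$corrected_mean_per100g,
               g$raw_mean_per100g * 64 / 79 - 4 / 3)
})

test_that("corrections are monotone and reduce to the identity at rate 1, blank 0", {
  withr::local_seed(99)
  for (i in 1:20) {
    raw <- sort(runif(5, 0, 20))
    conc <- tibble::tibble(code = paste0("B-", 1:5), raw_mean_per100g = raw)
    rate <- runif(1)
    out <- correct_concentrations(conc, rate)
    # non-decreasing in raw mean
    expect_true(all(diff(out$corrected_mean_per100g) >= 0))
    # non-decreasing in rate
    out_hi <- correct_concentrations(conc, min(1, rate * 1.5))
    expect_true(all(out_hi$corrected_mean_per100g >= out$corrected_mean_per100g))
  }
  conc <- tibble::tibble(code = c("A-1", "B-1"), raw_mean_per100g = c(3.5, 7.25))
  g <- grand_mean(correct_concentrations(conc, 1), rate = 1, blank = 0)
  expect_equal(g$corrected_mean_per100g, mean(conc$raw_mean_per100g))
})
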