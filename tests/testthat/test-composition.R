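test_that("size classification partitions the positive reals with upper-inclusive bounds", {
  expect_equal(as.character(classify_size(c(0.0005, 0.001, 3, 5, 5.89, 20, 25, 150))),
               c("nanoplastic", "microplastic", "microplastic", "microplastic",
                 "mesoplastic", "mesoplastic", "macroplastic", "megaplastic"))
  # lower-inclusive alternative moves the boundary points down a class
  expect_equal(as.character(classify_size(5, upper_inclusive = FALSE)),
               "mesoplastic")
  expect_error(classify_size(0), class = "canmp_validation")
  expect_error(classify_size(-1), class = "canmp_validation")

  # total and piecewise constant: every positive size gets exactly one class
  withr::local_seed(1)
  x <- 10^runif(200, -4, 2.5)
  cl <- classify_size(x)
  expect_false(anyNA(cl))
  bounds <- size_classes()
  expect_equal(bounds$lower_mm[-1], bounds$upper_mm[-nrow(bounds)])
})

test_that("composition summaries compute percentage shares per dimension", {
  p <- dplyr::bind_rows(make_particles(4, shape = "fragment"),
                        make_particles(3, shape = "fiber"))
  s <- composition_summary(p, "shape")
  expect_equal(s$share_pct[s$label == "fragment"], 400 / 7, tolerance = 1e-9)
  expect_equal(round_half_up(s$share_pct, 1), c(57.1, 42.9))
  expect_equal(sum(s$share_pct), 100)

  mono <- composition_summary(make_particles(5, color = "blue"), "color")
  expect_equal(mono$share_pct, 100)

  expect_error(composition_summary(make_particles(0), "shape"),
               class = "canmp_validation")
})

test_that("polymer summaries exclude rejected particles and flag natural polymers", {
  p <- dplyr::bind_rows(
    make_particles(2, polymer = "Polyolefin", verified = "verified_mp"),
    make_particles(1, polymer = "Cellulose", verified = "verified_mp"),
    make_particles(1, polymer = NA_character_, verified = "rejected"),
    make_particles(4, verified = "not_analyzed")
  )
  s <- composition_summary(p, "polymer")
  expect_equal(attr(s, "n"), 3)
  expect_equal(s$share_pct[s$label == "Polyolefin"], 200 / 3)
  expect_true(s$natural_polymer[s$label == "Cellulose"])
  expect_false(s$natural_polymer[s$label == "Polyolefin"])
  # rejected and unanalysed particles still count for shape shares
  expect_equal(sum(composition_summary(p, "shape")$count), 8)
})

test_that("integer counts are reconstructed exactly from printed percentages", {
  poly <- reference_polymer_fixture()

  fib <- reconstruct_counts(shares_vector(poly, "fiber"), total_hint = 64)
  expect_equal(attr(fib, "n_total"), 11)
  expect_equal(sort(fib$count, decreasing = TRUE), c(2, 2, 2, 1, 1, 1, 1, 1))
  expect_equal(fib$count[fib$label == "Chitin"], 2)  # 2/11 = 18.18%

  frag <- reconstruct_counts(shares_vector(poly, "fragment"), total_hint = 64)
  expect_equal(attr(frag, "n_total"), 53)
  expect_equal(frag$count[frag$label == "Polyolefin"], 14)  # 14/53 = 26.42%
  expect_equal(frag$count[frag$label == "Epoxy"], 2)        # 2/53 = 3.77%

  trivial <- reconstruct_counts(c(all = 100))
  expect_equal(attr(trivial, "n_total"), 1)
  expect_equal(trivial$count, 1L)

  # inconsistent shares fail with the nearest miss reported
  err <- expect_error(reconstruct_counts(c(a = 60.07, b = 39.93), total_hint = 10),
                      class = "canmp_reconstruction")
  expect_match(conditionMessage(err), "nearest miss")
  expect_error(reconstruct_counts(c(a = 70, b = 10)), class = "canmp_validation")
})

test_that("counts round-trip through shares and back", {
  withr::local_seed(7)
  for (i in 1:10) {
    n_lab <- sample(2:6, 1)
    counts <- rmultinom(1, sample(20:80, 1), runif(n_lab, 0.5, 2))[, 1]
    counts <- counts[counts > 0]
    shares <- round_half_up(100 * counts / sum(counts), 2)
    names(shares) <- paste0("poly", seq_along(shares))
    rec <- reconstruct_counts(shares, total_hint = sum(counts))
    # the reconstruction reproduces its own shares at printed precision
    expect_equal(round_half_up(rec$share_pct, 2), unname(shares[rec$label]))
    expect_true(attr(rec, "n_total") <= sum(counts))
  }
})

test_that("pooled polymer shares over fibers and fragments match the printed totals", {
  poly <- reference_polymer_fixture()
  fib <- reconstruct_counts(shares_vector(poly, "fiber"), 64)
  frag <- reconstruct_counts(shares_vector(poly, "fragment"), 64)
  tot <- combine_polymer_shares(fib, frag, expected_total = 64)
  expect_equal(attr(tot, "n_total"), 64)
  expect_equal(tot$share_pct[tot$label == "Polyolefin"], 21.875)     # prints 21.88
  expect_equal(tot$count[tot$label == "Polyolefin"], 14)
  expect_equal(round_half_up(tot$share_pct[tot$label == "Polyacrylonitrile"], 2),
               10.94)                                                # 7/64
  # every printed total share is the half-up rounding of the pooled counts
  printed <- shares_vector(poly, "total")
  expect_equal(round_half_up(tot$share_pct[match(names(printed), tot$label)], 2),
               unname(printed))

  expect_error(combine_polymer_shares(fib, frag, expected_total = 79),
               class = "canmp_validation")
  even <- combine_polymer_shares(tibble::tibble(label = "A", count = 1L),
                                 tibble::tibble(label = "B", count = 1L))
  expect_equal(even$share_pct, c(50, 50))
})
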