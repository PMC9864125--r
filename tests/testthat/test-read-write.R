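test_that("the bundled product table parses, normalises vocabulary and carries 33 products", {
  products <- read_products(canmp_example("reference_products.csv"))
  expect_equal(nrow(products), 33)
  expect_true(all(products$package_type %in%
                    c("can", "can_bpa_free", "aluminum", "composite_cpp", "glass")))
  # both spellings of aluminium collapse to one token
  expect_equal(products$package_type[products$code == "D-D-7"], "aluminum")
  expect_equal(products$package_label[products$code == "D-D-7"], "Aluminium")
  expect_equal(products$package_type[products$code == "D-D-1"], "can_bpa_free")
  # producer is the code prefix
  expect_equal(unique(products$producer[startsWith(products$code, "K-")]), "K")
  expect_equal(sort(unique(products$producer)), c("D", "I", "K", "O", "P", "S", "T"))
  # tuna-genus products (tuna, yellowfin, skipjack) dominate the basket
  expect_equal(sum(grepl("tuna|skipjack", tolower(products$species))), 27)
  expect_true(all(products$product_weight_g > 0))
})

test_that("product reading rejects unknown package labels and duplicate codes", {
  products <- read_products(canmp_example("reference_products.csv"))
  tmp <- withr::local_tempfile(fileext = ".csv")

  bad <- products
  bad$package_type[3] <- "Tetra Pak"
  write_products(bad, tmp)
  expect_error(read_products(tmp), class = "canmp_validation")
  expect_error(read_products(tmp), regexp = "Tetra Pak")

  dup <- products
  dup$code[2] <- dup$code[1]
  write_products(dup, tmp)
  expect_error(read_products(tmp), class = "canmp_validation")

  # header-only file yields an empty, correctly-typed tibble
  writeLines("code,party_no,species,additive_oil,other_additives,product_weight_g,package_type",
             tmp)
  expect_equal(nrow(read_products(tmp)), 0)
})

test_that("the bundled concentration table matches its own grand mean", {
  conc <- reference_concentration_fixture()
  brands <- conc[conc$code != "grand", ]
  expect_equal(nrow(brands), 33)
  expect_equal(conc$raw_mean_per100g[conc$code == "D-C-1"], 10.00)
  # fixture integrity: mean of the 33 raw means reproduces the printed grand raw
  expect_equal(mean(brands$raw_mean_per100g), 5.93, tolerance = 0.005 / 5.93)
})

test_that("concentration reading flags malformed and negative cells by row and column", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,raw_mean_per100g", "A-1,1.5", "A-2,oops"), tmp)
  err <- expect_error(read_concentrations(tmp), class = "canmp_validation")
  expect_match(conditionMessage(err), "raw_mean_per100g")
  expect_match(conditionMessage(err), "row 2")

  writeLines(c("code,raw_mean_per100g", "A-1,-0.5"), tmp)
  expect_error(read_concentrations(tmp), class = "canmp_validation")
})

test_that("write then read round-trips every table field-for-field", {
  survey <- simulate_survey(survey_config(n_producers = 3, n_brands = 6, seed = 5))
  tmp <- withr::local_tempdir()

  p <- file.path(tmp, "products.csv")
  write_products(survey$products, p)
  back <- read_products(p)
  cols <- c("code", "party_no", "species", "additive_oil", "other_additives",
            "product_weight_g", "package_type")
  expect_equal(as.data.frame(back[cols]), as.data.frame(survey$products[cols]))

  o <- file.path(tmp, "observations.csv")
  write_observations(survey$observations, o)
  expect_equal(as.data.frame(read_observations(o)),
               as.data.frame(survey$observations))

  q <- file.path(tmp, "particles.csv")
  write_particles(survey$particles, q)
  expect_equal(as.data.frame(read_particles(q)),
               as.data.frame(survey$particles))

  conc <- brand_concentrations(survey$observations)
  cpath <- file.path(tmp, "concentrations.csv")
  write_concentrations(conc, cpath)
  expect_equal(as.data.frame(read_concentrations(cpath)), as.data.frame(conc))
})

test_that("observation validation enforces replicate structure and count types", {
  obs <- make_observations(c(1, 2, 3))
  expect_silent(read_observations_ok <- brand_concentrations(obs))
  gap <- obs
  gap$replicate <- c(1L, 3L, 4L)
  expect_error(brand_concentrations(gap), class = "canmp_validation")
  zero_mass <- obs
  zero_mass$subsample_mass_g <- 0
  expect_error(brand_concentrations(zero_mass), class = "canmp_validation")
})

test_that("particle reading normalises fibre spellings and guards invariants", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,shape,color,size_mm,polymer,verified",
               "s1,fibre,Blue,0.5,,not_analyzed",
               "s2,Fiber/Filament,black,1.2,,not_analyzed",
               "s3,fragment,white,2.0,Polyolefin,verified_mp"), tmp)
  p <- read_particles(tmp)
  expect_equal(p$shape, c("fiber", "fiber", "fragment"))
  expect_equal(p$color[1], "blue")

  # a polymer label without spectroscopy is inconsistent
  writeLines(c("sample_id,shape,color,size_mm,polymer,verified",
               "s1,fiber,blue,0.5,Polyolefin,not_analyzed"), tmp)
  expect_error(read_particles(tmp), class = "canmp_validation")

  writeLines(c("sample_id,shape,color,size_mm,polymer,verified",
               "s1,fiber,blue,-1,,not_analyzed"), tmp)
  expect_error(read_particles(tmp), class = "canmp_validation")
})
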