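test_that("the canonical scenario carries the study parameterization", {
  sc <- us_infant_scenario()
  expect_equal(sc$tox$mrl_acute, 5.0e-3)
  expect_equal(sc$tox$mrl_chronic, 3.0e-4)
  expect_equal(sc$tox$csf, 1.5)
  expect_equal(sc$tox$mcl_w, 0.010)
  expect_equal(sc$tox$ed_days, 620)
  expect_equal(sc$tox$at_days, 25550)
  expect_equal(sc$concentrations$water$params, list(low = 0, high = 0.010))
  expect_equal(sc$concentrations$formula$params, list(mean = 7.48e-6, sd = 6.12e-7))
  expect_equal(sc$concentrations$rice_cereal$params,
               list(a = 2.30e-5, b = 9.10e-5, c = 2.83e-4))
  expect_equal(sc$concentrations$other_solid$params, list(mean = 4.6e-6, sd = 5.6e-6))
  b1 <- sc$bands[[1]]
  expect_equal(b1$body_weight$params, list(mean = 6.95, sd = 0.85))
  expect_equal(b1$v_w$params, list(a = 0, b = 0.148, c = 0.924))
  expect_equal(b1$v_if$grams$params, list(mean = 21.5, sd = 9.7))
  expect_equal(b1$v_if$servings, c(4L, 5L))
  expect_equal(b1$v_rc$params, list(mean = 14.3, sd = 16.1))
  expect_null(b1$v_m)  # meat consumption starts at 6 months
  expect_false(is.null(sc$bands[[2]]$v_m))
  expect_equal(sc$n_iterations, 1e6)
})

test_that("age bands partition the 21 monthly ages 4-24", {
  sc <- us_infant_scenario()
  expect_equal(band_month_weights(sc), c(2L, 3L, 3L, 3L, 4L, 6L))
  expect_equal(sum(band_month_weights(sc)), 21L)
  expect_setequal(unlist(lapply(sc$bands, `[[`, "months")), 4:24)
})

test_that("the bundled fixture equals the in-code canonical scenario", {
  path <- system.file("extdata", "us_infant_scenario.yaml", package = "asirisk")
  expect_true(nzchar(path))
  expect_identical(load_scenario(path), us_infant_scenario())
})

test_that("scenarios round-trip through YAML without loss", {
  sc <- us_infant_scenario(n_iterations = 5000, seed = 42)
  f <- tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  expect_identical(load_scenario(f), sc)
  expect_equal(scenario_digest(load_scenario(f)), scenario_digest(sc))
})

test_that("schema violations are rejected with the offending path named", {
  sc <- us_infant_scenario()
  # dropping the last band leaves months 19-24 uncovered
  sc2 <- sc; sc2$bands <- sc2$bands[1:5]
  expect_error(validate_scenario(sc2), "19, 20, 21, 22, 23, 24")
  # invalid distribution parameter, reported at its path
  sc3 <- sc; sc3$bands[[1]]$body_weight$params$sd <- -1
  expect_error(validate_scenario(sc3), "bands\\[\\[1\\]\\]\\$body_weight.*sd < 0")
  # overlapping months
  sc4 <- sc; sc4$bands[[2]]$months <- 5:8
  expect_error(validate_scenario(sc4), "more than once: 5")
  # non-positive toxicology constant
  sc5 <- sc; sc5$tox$csf <- 0
  expect_error(validate_scenario(sc5), "tox\\$csf")
})

test_that("configuration documents with unknown or missing keys are rejected", {
  f <- tempfile(fileext = ".yaml")
  write_scenario(us_infant_scenario(), f)
  doc <- yaml::read_yaml(f)
  doc$concentrations$typo_key <- list(family = "point", value = 1)
  f2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc, f2)
  expect_error(load_scenario(f2), "concentrations: unknown key.*typo_key")
  doc2 <- yaml::read_yaml(f)
  doc2$age_bands[[1]]$rice_cereal_g_per_day <- NULL
  f3 <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc2, f3)
  expect_error(load_scenario(f3), "age_bands\\[\\[1\\]\\]\\$rice_cereal_g_per_day")
  doc3 <- yaml::read_yaml(f)
  doc3$age_bands[[1]]$formula_g_dry_per_serving$sd <- -2
  f4 <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc3, f4)
  expect_error(load_scenario(f4), "sd < 0")
  expect_error(load_scenario("not: [valid\nbroken:"), "malformed")
})

test_that("household-measure conversions use the published constants", {
  expect_equal(convert_units(1, "tbsp", "dry_cereal"), 4.6)
  expect_equal(convert_units(1, "cup", "dry_cereal"), 73.6)
  expect_equal(convert_units(2, "fl_oz", "formula"), 8.6)
  expect_equal(convert_units(1, "oz", "meat"), 28.35)
  expect_equal(convert_units(3, "tbsp", "fruit_veg"), 48.9)
  expect_error(convert_units(1, "oz", "dry_cereal"), "no conversion")
})
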