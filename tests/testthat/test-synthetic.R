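test_that("zero countries yields empty tables with the full schemas", {
  b <- generate_synthetic(synthetic_config(n_countries = 0))
  expect_equal(nrow(b$standards), 0)
  expect_equal(nrow(b$status), 0)
  expect_named(b$standards,
               c("country", "issue_year", "iodine_form", "iodine_low",
                 "iodine_high", "iodine_value", "basis", "basis_compound",
                 "compounds", "scope"))
  expect_named(b$coverage,
               c("country", "pct_households_any_iodized",
                 "survey_start_year", "survey_end_year"))
})

test_that("the generator is deterministic: same seed, byte-identical files", {
  cfg <- synthetic_config(n_countries = 25, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic(generate_synthetic(cfg), d1)
  p2 <- write_synthetic(generate_synthetic(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
  # a different seed changes the draw
  b3 <- generate_synthetic(synthetic_config(n_countries = 25, seed = 78))
  expect_false(identical(b3$intake$salt_intake_g_day,
                         generate_synthetic(cfg)$intake$salt_intake_g_day))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(generate_synthetic(synthetic_config(n_countries = 5, seed = 9)))
  expect_identical(runif(1), r1)
})

test_that("the noise-free forward model matches its closed form", {
  # compliance 1, multiplier 1, intake 10 g/d:
  # mUIC = 0.90 * (10 * 19.5 * 0.7) / 1.0 = 122.85 ug/L, adequate
  cfg <- synthetic_config(n_countries = 6, seed = 5, salt_intake_mean = 10,
                          salt_intake_sd = 0, multiplier_range = c(1, 1),
                          noise_sigma = 0)
  b <- generate_synthetic(cfg)
  expect_equal(b$status$muic_ug_L, rep(122.85, 6))
  expect_equal(unique(classify_muic(b$status$muic_ug_L)), "adequate")
  # baseline dietary iodine shifts mUIC additively
  cfg_base <- synthetic_config(n_countries = 6, seed = 5,
                               salt_intake_mean = 10, salt_intake_sd = 0,
                               multiplier_range = c(1, 1), noise_sigma = 0,
                               baseline_diet_iodine_ug = 50)
  expect_equal(generate_synthetic(cfg_base)$status$muic_ug_L,
               rep(122.85 + 0.9 * 50, 6))
})

test_that("mUIC is linear in compliance and midpoint (no baseline, no noise)", {
  mk <- function(compliance) generate_synthetic(
    synthetic_config(n_countries = 15, seed = 13, noise_sigma = 0,
                     compliance = compliance))
  full <- mk(1)
  half <- mk(0.5)
  expect_equal(half$status$muic_ug_L, full$status$muic_ug_L / 2)
  expect_equal(stats::median(half$status$muic_ug_L),
               stats::median(full$status$muic_ug_L) / 2)
  # linearity in midpoint: doubling the multiplier doubles mUIC
  dbl <- generate_synthetic(
    synthetic_config(n_countries = 15, seed = 13, noise_sigma = 0,
                     multiplier_range = c(2, 2)))
  one <- generate_synthetic(
    synthetic_config(n_countries = 15, seed = 13, noise_sigma = 0,
                     multiplier_range = c(1, 1)))
  expect_equal(dbl$status$muic_ug_L, 2 * one$status$muic_ug_L)
})

test_that("generated ranges contain their midpoint and invert exactly", {
  b <- generate_synthetic(synthetic_config(n_countries = 40, seed = 17))
  rng <- b$standards[b$standards$iodine_form == "range", ]
  truth <- b$truth[match(rng$country, b$truth$country), ]
  expect_true(all(rng$iodine_low < truth$midpoint_mg_kg))
  expect_true(all(rng$iodine_high > truth$midpoint_mg_kg))
  mids <- mapply(function(lo, hi)
    extract_midpoint(iodine_spec("range", low = lo, high = hi)),
    rng$iodine_low, rng$iodine_high)
  expect_equal(unname(mids), truth$midpoint_mg_kg)
})

test_that("the pipeline inverts the generator exactly when noise is off", {
  b <- generate_synthetic(synthetic_config(n_countries = 30, seed = 19,
                                           noise_sigma = 0))
  rep <- recover_synthetic(b)
  expect_equal(rep$n, 30)
  expect_lt(rep$max_abs_rel_error, 1e-9)
  expect_equal(rep$category_agreement, 1)
})

test_that("the share of standards above 100% matches the closed form", {
  # multiplier ~ U(0.68, 3.50): Pr(m > 1) = 2.5 / 2.82
  p_above <- 2.5 / 2.82
  n <- 110
  b <- generate_synthetic(synthetic_config(n_countries = n, seed = 23))
  rep <- recover_synthetic(b)
  frac <- rep$category_counts[["above"]] / n
  se <- sqrt(p_above * (1 - p_above) / n)
  expect_lt(abs(frac - p_above), 3 * se)
})

test_that("fully compliant populations at the guideline amount are adequate", {
  for (seed in c(101, 202, 303)) {
    b <- generate_synthetic(
      synthetic_config(n_countries = 50, seed = seed,
                       multiplier_range = c(1, 1), compliance = 1))
    frac_adequate <- mean(classify_muic(b$status$muic_ug_L) == "adequate")
    expect_gte(frac_adequate, 0.95)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(compliance = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(excreted_fraction = 0), "\\(0, 1\\]")
  expect_error(synthetic_config(n_countries = -1), "non-negative")
  expect_error(synthetic_config(multiplier_range = c(3, 1)), "low <= high")
  expect_error(synthetic_config(range_halfwidth_frac = 1), "\\[0, 1\\)")
  expect_error(recover_synthetic(structure(list(standards = 1),
                                           class = "synthetic_bundle")),
               "missing generated tables")
})
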