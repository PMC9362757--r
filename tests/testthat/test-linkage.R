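test_that("mUIC classification uses the 100-299 ug/L adequate band", {
  expect_equal(classify_muic(150), "adequate")
  expect_equal(classify_muic(99.9), "insufficient")
  expect_equal(classify_muic(100), "adequate")
  expect_equal(classify_muic(299), "adequate")
  expect_equal(classify_muic(300), "excessive")
  expect_equal(classify_muic(0), "insufficient")
  expect_error(classify_muic(-1), "non-negative")
})

test_that("mUIC classification partitions [0, Inf) totally and exclusively", {
  set.seed(21)
  muic <- c(runif(200, 0, 600), 0, 100 - 1e-9, 100, 299, 300, 1e6)
  cls <- classify_muic(muic)
  expect_true(all(cls %in% c("insufficient", "adequate", "excessive")))
  expect_equal(cls == "insufficient", muic < 100)
  expect_equal(cls == "adequate", muic >= 100 & muic < 300)
  expect_equal(cls == "excessive", muic >= 300)
})

test_that("the worked eligibility example passes all three criteria", {
  std <- salt_standard("XXA", 2000,
                       iodine_spec("range", low = 30, high = 50), "KIO3")
  cov <- coverage_record("XXA", 81.5, 2012, 2013)
  sta <- status_record("XXA", 150, 2017)
  res <- is_eligible(std, cov, sta)
  expect_true(res$eligible)
  expect_length(res$failed_criteria, 0)
})

test_that("boundary perturbations each trip exactly one criterion", {
  std <- salt_standard("XXA", 2000,
                       iodine_spec("range", low = 30, high = 50), "KIO3")
  sta <- status_record("XXA", 150, 2017)

  low_cov <- is_eligible(std, coverage_record("XXA", 69.9, 2012, 2013), sta)
  expect_false(low_cov$eligible)
  expect_equal(low_cov$failed_criteria, "coverage_below_70")

  old_survey <- is_eligible(std, coverage_record("XXA", 81.5, 2010, 2010),
                            sta)
  expect_false(old_survey$eligible)
  expect_equal(old_survey$failed_criteria, "window_violation")

  # survey in the issue year is not > 1 y after the standard
  late_std <- salt_standard("XXA", 2013,
                            iodine_spec("range", low = 30, high = 50),
                            "KIO3")
  pre <- is_eligible(late_std, coverage_record("XXA", 81.5, 2012, 2013),
                     sta)
  expect_false(pre$eligible)
  expect_equal(pre$failed_criteria, "pre_standard_survey")

  # failures accumulate rather than short-circuit
  multi <- is_eligible(late_std, coverage_record("XXA", 50, 2010, 2010),
                       sta)
  expect_setequal(multi$failed_criteria,
                  c("coverage_below_70", "window_violation",
                    "pre_standard_survey"))
  expect_error(
    is_eligible(std, coverage_record("YYB", 81.5, 2012, 2013), sta),
    "same\\s+country")
})

test_that("window endpoints are inclusive and the reference year rule holds", {
  std <- salt_standard("XXA", 2000,
                       iodine_spec("single", value = 25), "KI")
  cov <- coverage_record("XXA", 80, 2012, 2013)
  expect_true(is_eligible(std, cov, status_record("XXA", 150,
                                                  2014))$eligible) # gap 1
  expect_true(is_eligible(std, cov, status_record("XXA", 150,
                                                  2018))$eligible) # gap 5
  expect_false(is_eligible(std, cov,
                           status_record("XXA", 150, 2013))$eligible)
  expect_false(is_eligible(std, cov,
                           status_record("XXA", 150, 2019))$eligible)
  # anchored on the start year instead, the 2018 assessment falls outside
  res_start <- is_eligible(std, cov, status_record("XXA", 150, 2018),
                           reference_year = "start")
  expect_false(res_start$eligible)
  expect_equal(res_start$failed_criteria, "window_violation")
})

test_that("eligibility is monotone in household coverage", {
  std <- salt_standard("XXA", 2000,
                       iodine_spec("single", value = 25), "KI")
  sta <- status_record("XXA", 150, 2016)
  set.seed(31)
  for (i in 1:20) {
    p1 <- runif(1, 0, 100)
    p2 <- runif(1, p1, 100)
    e1 <- is_eligible(std, coverage_record("XXA", p1, 2012, 2013), sta)
    e2 <- is_eligible(std, coverage_record("XXA", p2, 2012, 2013), sta)
    expect_true(e2$eligible >= e1$eligible)
  }
})

test_that("Pearson route matches hand oracles on perfect correlations", {
  scores <- tibble::tibble(country = sprintf("A%02d", 1:6),
                           percent_met = c(110, 150, 200, 90, 130, 250))
  standards <- tibble::tibble(country = scores$country, issue_year = 2000L)
  mk_status <- function(muic) tibble::tibble(
    country = scores$country, muic_ug_L = muic,
    assessment_year = 2015L, population = "school_age_children")

  up <- correlate_muic(scores, mk_status(scores$percent_met),
                       filter = "post_legislation_sac",
                       standards = standards)
  expect_equal(up$r, 1)
  expect_equal(up$n, 6)
  down <- correlate_muic(scores, mk_status(-scores$percent_met + 400),
                         filter = "post_legislation_sac",
                         standards = standards)
  expect_equal(down$r, -1)
})

test_that("correlation equals the brute-force formula to 1e-12", {
  set.seed(41)
  n <- 10
  scores <- tibble::tibble(country = sprintf("B%02d", 1:n),
                           percent_met = runif(n, 68, 350))
  muic <- runif(n, 50, 400)
  standards <- tibble::tibble(country = scores$country, issue_year = 2000L)
  statuses <- tibble::tibble(country = scores$country, muic_ug_L = muic,
                             assessment_year = 2015L,
                             population = "school_age_children")
  res <- correlate_muic(scores, statuses, filter = "post_legislation_sac",
                        standards = standards)
  oracle <- pearson_oracle(scores$percent_met, muic)
  expect_equal(res$r, oracle$r, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$n, oracle$n)
  expect_equal(res$data$muic_class, classify_muic(res$data$muic_ug_L))

  # sign-preserving affine rescaling of either variable leaves r unchanged
  scaled <- correlate_muic(
    dplyr::mutate(scores, percent_met = 3.7 * percent_met + 12),
    dplyr::mutate(statuses, muic_ug_L = 0.5 * muic_ug_L + 40),
    filter = "post_legislation_sac", standards = standards)
  expect_equal(scaled$r, res$r, tolerance = 1e-12)
})

test_that("correlation errors on tiny or degenerate inputs", {
  scores <- tibble::tibble(country = c("AAA", "BBB"),
                           percent_met = c(100, 200))
  standards <- tibble::tibble(country = c("AAA", "BBB"),
                              issue_year = 2000L)
  statuses <- tibble::tibble(country = c("AAA", "BBB"),
                             muic_ug_L = c(100, 200),
                             assessment_year = 2015L,
                             population = "school_age_children")
  expect_error(correlate_muic(scores, statuses,
                              filter = "post_legislation_sac",
                              standards = standards),
               "at least 3")
  scores3 <- tibble::tibble(country = c("AAA", "BBB", "CCC"),
                            percent_met = c(150, 150, 150))
  standards3 <- tibble::tibble(country = scores3$country,
                               issue_year = 2000L)
  statuses3 <- tibble::tibble(country = scores3$country,
                              muic_ug_L = c(100, 150, 200),
                              assessment_year = 2015L,
                              population = "school_age_children")
  expect_error(correlate_muic(scores3, statuses3,
                              filter = "post_legislation_sac",
                              standards = standards3),
               "zero variance")
})

test_that("strict filter applies the eligibility rules on the fixture", {
  tabs <- fixture_tables()
  # extend to 3+ eligible countries for the strict filter
  tabs$standards <- dplyr::bind_rows(
    tabs$standards,
    tibble::tibble(country = "EEE", issue_year = 2001L,
                   iodine_form = "single", iodine_low = NA,
                   iodine_high = NA, iodine_value = 35,
                   basis = "iodine", basis_compound = NA_character_,
                   compounds = "KIO3", scope = "both"))
  tabs$intake <- dplyr::bind_rows(
    tabs$intake, tibble::tibble(country = "EEE", salt_intake_g_day = 8))
  tabs$coverage <- dplyr::bind_rows(
    tabs$coverage,
    tibble::tibble(country = "EEE", pct_households_any_iodized = 88,
                   survey_start_year = 2011L, survey_end_year = 2012L))
  tabs$status <- dplyr::bind_rows(
    tabs$status,
    tibble::tibble(country = "EEE", muic_ug_L = 180,
                   assessment_year = 2015L,
                   population = "school_age_children"))
  res <- run_pipeline(tabs, config = run_config(mode = "table"))
  strict <- res$correlation_strict
  # CCC fails coverage (65%) and BBB fails the window (2014 - 2011 = 3 ok)
  # -> AAA, BBB, DDD, EEE eligible
  expect_equal(sort(strict$data$country), c("AAA", "BBB", "DDD", "EEE"))
  expect_equal(strict$n, 4)
  oracle <- pearson_oracle(strict$data$percent_met, strict$data$muic_ug_L)
  expect_equal(strict$r, oracle$r, tolerance = 1e-12)
})

test_that("relaxed filter keeps post-legislation school-age assessments", {
  tabs <- fixture_tables()
  res <- run_pipeline(tabs, config = run_config(mode = "table"))
  # CCC has no school-age record; AAA/BBB/DDD assessed after issue year
  expect_equal(sort(res$correlation_relaxed$data$country),
               c("AAA", "BBB", "DDD"))
})
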