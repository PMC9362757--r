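# Independent Pearson oracle: textbook covariance / (sd * sd), with the
# two-sided p from the t transform. Deliberately written from the formula,
# not via cor()/cor.test(), so it can cross-check the package's route.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  r <- sxy / (sx * sy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p, n = n)
}

# Published WHO 2014 suggested amounts, salt intake 3..14 g/d.
who_2014_printed <- c(65, 49, 39, 33, 28, 24, 22, 20, 18, 16, 15, 14)

# A tiny clean four-country fixture exercising all three spec forms.
fixture_tables <- function() {
  list(
    standards = tibble::tibble(
      country = c("AAA", "BBB", "CCC", "DDD"),
      issue_year = c(2000L, 2005L, 2010L, 1998L),
      iodine_form = c("range", "single", "minimum", "range"),
      iodine_low = c(30, NA, 30, 20),
      iodine_high = c(50, NA, NA, 40),
      iodine_value = c(NA, 25, NA, NA),
      basis = "iodine",
      basis_compound = NA_character_,
      compounds = c("KIO3;KI", "KIO3", "calcium iodate", "KI;sodium iodide"),
      scope = c("both", "both", "household_only", "processed_only")
    ),
    intake = tibble::tibble(
      country = c("AAA", "BBB", "CCC", "DDD"),
      salt_intake_g_day = c(10, 10, 10, 5)
    ),
    coverage = tibble::tibble(
      country = c("AAA", "BBB", "CCC", "DDD"),
      pct_households_any_iodized = c(81.5, 90, 65, 75),
      survey_start_year = c(2012L, 2010L, 2011L, 2012L),
      survey_end_year = c(2013L, 2011L, 2011L, 2012L)
    ),
    status = tibble::tibble(
      country = c("AAA", "BBB", "CCC", "DDD"),
      muic_ug_L = c(150, 210, 95, 310),
      assessment_year = c(2017L, 2014L, 2013L, 2016L),
      population = c("school_age_children", "school_age_children",
                     "women_reproductive_age", "school_age_children")
    )
  )
}

write_fixture_csvs <- function(tables, dir) {
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}
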