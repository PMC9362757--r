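#' Classify a population's median urinary iodine concentration
#'
#' mUIC (median urinary iodine concentration, ug/L) is the standard
#' population-level indicator of recent iodine intake: values below 100 ug/L
#' indicate insufficient intake, 100-299 ug/L adequate intake, and 300 ug/L
#' or more excessive intake.
#'
#' @param muic mUIC values, ug/L; non-negative numeric vector.
#' @return Character vector: `"insufficient"`, `"adequate"`, or
#'   `"excessive"`.
#' @examples
#' classify_muic(c(99.9, 150, 300))
#' @export
classify_muic <- function(muic) {
  if (length(muic) == 0) return(character(0))
  if (!is.numeric(muic) || anyNA(muic) || any(muic < 0)) {
    stop("`muic` must be non-negative (ug/L)", call. = FALSE)
  }
  ifelse(muic < 100, "insufficient",
         ifelse(muic < 300, "adequate", "excessive"))
}

#' A household iodized-salt coverage survey record
#'
#' @param country ISO3 country code.
#' @param pct_households_any_iodized Percentage of households consuming salt
#'   iodized to any level, 0-100.
#' @param survey_start_year,survey_end_year Calendar years; start <= end.
#' @return An object of class `coverage_record`.
#' @export
coverage_record <- function(country, pct_households_any_iodized,
                            survey_start_year, survey_end_year) {
  pct <- as.numeric(pct_households_any_iodized)
  if (length(pct) != 1 || is.na(pct) || pct < 0 || pct > 100) {
    stop("`pct_households_any_iodized` must lie in [0, 100]", call. = FALSE)
  }
  sy <- as.integer(survey_start_year)
  ey <- as.integer(survey_end_year)
  if (anyNA(c(sy, ey)) || sy > ey) {
    stop("survey years must satisfy start <= end", call. = FALSE)
  }
  structure(
    list(country = toupper(as.character(country)),
         pct_households_any_iodized = pct,
         survey_start_year = sy, survey_end_year = ey),
    class = "coverage_record"
  )
}

#' A population mUIC assessment record
#'
#' @param country ISO3 country code.
#' @param muic_ug_L Median urinary iodine concentration, ug/L; non-negative.
#' @param assessment_year Calendar year of the assessment.
#' @param population Surveyed group: `"school_age_children"`,
#'   `"women_reproductive_age"`, or `"general"`.
#' @return An object of class `status_record`.
#' @export
status_record <- function(country, muic_ug_L, assessment_year,
                          population = c("school_age_children",
                                         "women_reproductive_age",
                                         "general")) {
  population <- match.arg(population)
  muic <- as.numeric(muic_ug_L)
  if (length(muic) != 1 || is.na(muic) || muic < 0) {
    stop("`muic_ug_L` must be non-negative", call. = FALSE)
  }
  structure(
    list(country = toupper(as.character(country)), muic_ug_L = muic,
         assessment_year = as.integer(assessment_year),
         population = population),
    class = "status_record"
  )
}

#' Eligibility of a country for the score-versus-status comparison
#'
#' A country's percent-of-guidelines-met score is compared with its iodine
#' status only when the household coverage survey plausibly reflects salt
#' iodized under the current standard at the time intake was formed. The
#' criteria: at least `coverage_threshold` percent of households consumed
#' iodized salt (default 70); the coverage survey was undertaken 1-5 years
#' (inclusive, configurable) before the mUIC assessment; and the survey took
#' place more than `min_post_standard_gap` years (default 1) after the salt
#' standard was issued. For multi-year surveys the reference year is the
#' survey end year by default (configurable to start or midpoint).
#'
#' All criteria are evaluated (not short-circuited) so every failure is
#' reported.
#'
#' @param standard A [salt_standard()].
#' @param coverage A [coverage_record()].
#' @param status A [status_record()].
#' @param coverage_threshold Minimum household coverage, percent (default 70).
#' @param window Inclusive `[low, high]` window, in years, from the coverage
#'   survey to the mUIC assessment (default `c(1, 5)`).
#' @param min_post_standard_gap The coverage survey must be strictly more
#'   than this many years after the standard was issued (default 1).
#' @param reference_year Which survey year anchors the arithmetic:
#'   `"end"` (default), `"start"`, or `"midpoint"` (rounded half-up).
#' @return A list of class `eligibility_result` with `eligible` (logical)
#'   and `failed_criteria` (character vector drawn from
#'   `coverage_below_70`, `window_violation`, `pre_standard_survey`,
#'   `missing_data`); `eligible` is `TRUE` iff `failed_criteria` is empty.
#' @examples
#' std <- salt_standard("XXA", 2000, iodine_spec("range", low = 30, high = 50),
#'                      "KIO3")
#' cov <- coverage_record("XXA", 81.5, 2012, 2013)
#' sta <- status_record("XXA", 150, 2017)
#' is_eligible(std, cov, sta)
#' @export
is_eligible <- function(standard, coverage, status,
                        coverage_threshold = 70, window = c(1, 5),
                        min_post_standard_gap = 1,
                        reference_year = c("end", "start", "midpoint")) {
  reference_year <- match.arg(reference_year)
  stopifnot(inherits(standard, "salt_standard"),
            inherits(coverage, "coverage_record"),
            inherits(status, "status_record"))
  if (length(unique(c(standard$country, coverage$country,
                      status$country))) != 1) {
    stop("standard, coverage and status records must refer to the same ",
         "country", call. = FALSE)
  }
  ref <- switch(reference_year,
    end = coverage$survey_end_year,
    start = coverage$survey_start_year,
    midpoint = as.integer(round_half_up(
      (coverage$survey_start_year + coverage$survey_end_year) / 2))
  )
  failed <- character(0)
  vals <- c(coverage$pct_households_any_iodized, ref,
            status$assessment_year, standard$issue_year)
  if (anyNA(vals)) {
    failed <- c(failed, "missing_data")
  } else {
    if (coverage$pct_households_any_iodized < coverage_threshold) {
      failed <- c(failed, "coverage_below_70")
    }
    gap <- status$assessment_year - ref
    if (gap < window[1] || gap > window[2]) {
      failed <- c(failed, "window_violation")
    }
    if (ref - standard$issue_year <= min_post_standard_gap) {
      failed <- c(failed, "pre_standard_survey")
    }
  }
  structure(list(eligible = length(failed) == 0, failed_criteria = failed),
            class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  if (x$eligible) {
    cat("<eligibility_result> eligible\n")
  } else {
    cat("<eligibility_result> ineligible:",
        paste(x$failed_criteria, collapse = ", "), "\n")
  }
  invisible(x)
}

# Pick one status record per country by population priority, then by most
# recent assessment year. `statuses` is the tabular form.
select_status <- function(statuses,
                          population_priority = c("school_age_children",
                                                  "women_reproductive_age",
                                                  "general")) {
  statuses |>
    dplyr::mutate(
      .prio = match(.data$population, population_priority)
    ) |>
    dplyr::filter(!is.na(.data$.prio)) |>
    dplyr::group_by(.data$country) |>
    dplyr::arrange(.data$.prio, dplyr::desc(.data$assessment_year),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".prio")
}

#' Correlate percent-of-guidelines-met with iodine status
#'
#' Joins country scores to mUIC assessments, applies one of two eligibility
#' filters, and computes the Pearson correlation between the percent of
#' guidelines met and mUIC, with a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' Filters:
#' * `"strict_eligibility"`: keep countries passing [is_eligible()] — at
#'   least 70% household coverage from a survey 1-5 y before the mUIC
#'   assessment and more than 1 y after the standard was issued. Requires
#'   `coverage` and `standards`.
#' * `"post_legislation_sac"`: keep countries with a school-age-children
#'   mUIC assessed after the standard's issue year. Requires `standards`.
#'
#' Where a country has several mUIC records after filtering, one is chosen
#' by population priority (school-age children, then women of reproductive
#' age, then general) and, within a population, the most recent assessment.
#'
#' @param scores Score table (see [score_countries()]): `country`,
#'   `percent_met`, ...
#' @param statuses Status table: `country`, `muic_ug_L`, `assessment_year`,
#'   `population`.
#' @param filter `"strict_eligibility"` or `"post_legislation_sac"`.
#' @param coverage Coverage table (`country`, `pct_households_any_iodized`,
#'   `survey_start_year`, `survey_end_year`); required for the strict filter.
#' @param standards Standards table with `country` and `issue_year`.
#' @param population_priority Order in which population groups are preferred
#'   when several records exist.
#' @inheritParams is_eligible
#' @return A list of class `correlation_result`: `r`, `p`, `n`, `filter`,
#'   and `data`, the joined per-country table (`country`, `percent_met`,
#'   `muic_ug_L`, `muic_class`, `eligible`, `failed_criteria`).
#' @export
correlate_muic <- function(scores, statuses,
                           filter = c("strict_eligibility",
                                      "post_legislation_sac"),
                           coverage = NULL, standards = NULL,
                           population_priority = c("school_age_children",
                                                   "women_reproductive_age",
                                                   "general"),
                           coverage_threshold = 70, window = c(1, 5),
                           min_post_standard_gap = 1,
                           reference_year = c("end", "start", "midpoint")) {
  filter <- match.arg(filter)
  reference_year <- match.arg(reference_year)
  stopifnot(is.data.frame(scores), is.data.frame(statuses))
  if (is.null(standards)) {
    stop("`standards` (with country, issue_year) is required", call. = FALSE)
  }

  if (filter == "post_legislation_sac") {
    kept <- statuses |>
      dplyr::filter(.data$population == "school_age_children") |>
      dplyr::inner_join(
        dplyr::select(standards, "country", "issue_year"), by = "country") |>
      dplyr::filter(.data$assessment_year > .data$issue_year) |>
      select_status(population_priority = "school_age_children") |>
      dplyr::mutate(eligible = TRUE, failed_criteria = "")
  } else {
    if (is.null(coverage)) {
      stop("`coverage` is required for the strict eligibility filter",
           call. = FALSE)
    }
    cand <- statuses |>
      select_status(population_priority) |>
      dplyr::inner_join(
        dplyr::select(standards, "country", "issue_year"), by = "country") |>
      dplyr::inner_join(coverage, by = "country")
    elig <- purrr::pmap(cand, function(country, muic_ug_L, assessment_year,
                                       population, issue_year,
                                       pct_households_any_iodized,
                                       survey_start_year, survey_end_year,
                                       ...) {
      std <- salt_standard(country, issue_year,
                           iodine_spec("single", value = 1),
                           "potassium_iodate")
      cov <- coverage_record(country, pct_households_any_iodized,
                             survey_start_year, survey_end_year)
      sta <- status_record(country, muic_ug_L, assessment_year, population)
      is_eligible(std, cov, sta, coverage_threshold = coverage_threshold,
                  window = window,
                  min_post_standard_gap = min_post_standard_gap,
                  reference_year = reference_year)
    })
    cand$eligible <- vapply(elig, `[[`, logical(1), "eligible")
    cand$failed_criteria <- vapply(
      elig, function(e) paste(e$failed_criteria, collapse = ";"),
      character(1))
    kept <- dplyr::filter(cand, .data$eligible)
  }

  joined <- scores |>
    dplyr::select("country", "percent_met") |>
    dplyr::inner_join(
      dplyr::select(kept, "country", "muic_ug_L", "eligible",
                    "failed_criteria"),
      by = "country") |>
    dplyr::mutate(muic_class = classify_muic(.data$muic_ug_L)) |>
    dplyr::arrange(.data$country)

  n <- nrow(joined)
  if (n < 3) {
    stop("insufficient data: need at least 3 joined country pairs, got ", n,
         call. = FALSE)
  }
  if (stats::sd(joined$percent_met) == 0 || stats::sd(joined$muic_ug_L) == 0) {
    stop("correlation undefined: zero variance in percent_met or mUIC",
         call. = FALSE)
  }
  ct <- stats::cor.test(joined$percent_met, joined$muic_ug_L,
                        method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = n, filter = filter,
         data = joined),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: r = %.5f, P = %.4f, n = %d\n",
              x$filter, x$r, x$p, x$n))
  invisible(x)
}
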