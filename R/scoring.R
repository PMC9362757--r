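#' Percent of WHO 2014 guidelines met
#'
#' The core comparison statistic: the iodine amount recorded for a country's
#' salt standard (midpoint of the range, or single stated amount) divided by
#' the WHO 2014 suggested amount at the country's estimated salt intake,
#' times 100. 100% means the national requirement equals the guideline
#' amount; 50% means half; 200% means double.
#'
#' @param midpoint Standard's iodine amount, mg iodine/kg salt; positive.
#' @param salt_intake Estimated salt intake, g/d; positive.
#' @param params A [guideline_params()] object.
#' @param mode WHO amount mode, `"continuous"` or `"table"`; see
#'   [who_iodine_amount()].
#' @param country Optional ISO3 label(s) carried into the result.
#' @param scope Optional legislation scope carried into the result.
#' @param meets_tol Half-width of the band around 100% classified as
#'   `"meets"` (default 0: exact equality only, since real standards
#'   virtually never hit 100% exactly).
#' @return A tibble with columns `country`, `salt_intake_g_day`,
#'   `who_amount_mg_kg`, `standard_midpoint_mg_kg`, `percent_met`, and
#'   `category` (`below` / `meets` / `above`), plus `scope` if supplied.
#' @examples
#' # worked example: range 30-50 ppm -> midpoint 40; intake 10 g/d -> 200%
#' percent_guidelines_met(40, 10, mode = "table")
#' @export
percent_guidelines_met <- function(midpoint, salt_intake,
                                   params = guideline_params(),
                                   mode = c("continuous", "table"),
                                   country = NA_character_,
                                   scope = NA_character_,
                                   meets_tol = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(midpoint) || anyNA(midpoint) || any(midpoint <= 0)) {
    stop("`midpoint` must be positive (mg iodine/kg salt)", call. = FALSE)
  }
  if (!is.numeric(salt_intake) || anyNA(salt_intake) ||
      any(salt_intake <= 0)) {
    stop("`salt_intake` must be positive (g/d)", call. = FALSE)
  }
  n <- max(length(midpoint), length(salt_intake))
  midpoint <- rep_len(midpoint, n)
  salt_intake <- rep_len(salt_intake, n)
  who_amt <- who_iodine_amount(salt_intake, params, mode)
  pct <- 100 * midpoint / who_amt
  tibble::tibble(
    country = rep_len(as.character(country), n),
    salt_intake_g_day = salt_intake,
    who_amount_mg_kg = who_amt,
    standard_midpoint_mg_kg = midpoint,
    percent_met = pct,
    category = score_category(pct, meets_tol),
    scope = rep_len(as.character(scope), n)
  )
}

# below / meets / above relative to the 100% line
score_category <- function(percent_met, meets_tol = 0) {
  ifelse(abs(percent_met - 100) <= meets_tol, "meets",
         ifelse(percent_met < 100, "below", "above"))
}

#' Aggregate percent-of-guidelines-met scores
#'
#' Summarises a table of country scores: counts and percentages per category
#' (below / meets / above the 100% line), the extremes with their country
#' labels, and cross-tabulations by legislation scope and (when present) by
#' compound category.
#'
#' @param scores A tibble as produced by [percent_guidelines_met()] or
#'   [score_countries()]; must be non-empty.
#' @return A list of class `score_summary` with elements `n`,
#'   `by_category` (category, n, pct), `range` (min/max percent with
#'   country), `by_scope`, and `by_compound` (NULL if the column is absent).
#' @export
aggregate_scores <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    stop("`scores` must be a non-empty score table", call. = FALSE)
  }
  stopifnot(all(c("country", "percent_met", "category") %in% names(scores)))
  n <- nrow(scores)
  cats <- c("below", "meets", "above")
  counts <- vapply(cats, function(k) sum(scores$category == k), integer(1))
  by_category <- tibble::tibble(category = cats, n = unname(counts),
                                pct = 100 * unname(counts) / nrow(scores))
  i_min <- which.min(scores$percent_met)
  i_max <- which.max(scores$percent_met)
  range_tbl <- tibble::tibble(
    end = c("min", "max"),
    country = c(scores$country[i_min], scores$country[i_max]),
    percent_met = c(scores$percent_met[i_min], scores$percent_met[i_max])
  )
  by_scope <- NULL
  if ("scope" %in% names(scores) && !all(is.na(scores$scope))) {
    by_scope <- scores |>
      dplyr::mutate(
        scope_group = ifelse(.data$scope == "both", "both", "single")
      ) |>
      dplyr::group_by(.data$scope_group) |>
      dplyr::summarise(
        n = dplyr::n(),
        median_percent_met = stats::median(.data$percent_met),
        n_below = sum(.data$category == "below"),
        n_above = sum(.data$category == "above"),
        .groups = "drop"
      )
  }
  by_compound <- NULL
  if ("compound_category" %in% names(scores)) {
    ccats <- c("all_recommended", "mixed", "none_recommended")
    ccounts <- vapply(ccats, function(k)
      sum(scores$compound_category == k, na.rm = TRUE), integer(1))
    by_compound <- tibble::tibble(compound_category = ccats,
                                  n = unname(ccounts),
                                  pct = 100 * unname(ccounts) / nrow(scores))
  }
  structure(
    list(n = n, by_category = by_category, range = range_tbl,
         by_scope = by_scope, by_compound = by_compound),
    class = "score_summary"
  )
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("<score_summary> %d countries\n", x$n))
  for (i in seq_len(nrow(x$by_category))) {
    cat(sprintf("  %-6s %3d (%0.0f%%)\n", x$by_category$category[i],
                x$by_category$n[i], x$by_category$pct[i]))
  }
  cat(sprintf("  range: %0.0f%% (%s) to %0.0f%% (%s)\n",
              x$range$percent_met[1], x$range$country[1],
              x$range$percent_met[2], x$range$country[2]))
  invisible(x)
}

#' Score a table of countries
#'
#' Convenience wrapper for tabular input: takes a standards table already
#' reduced to iodine-basis midpoints joined with salt intakes, and returns
#' the per-country score table. Countries with a missing midpoint or intake
#' must be excluded beforehand (see [run_pipeline()], which also reports the
#' exclusion accounting).
#'
#' @param countries Data frame with columns `country`,
#'   `standard_midpoint_mg_kg`, `salt_intake_g_day`, and optionally `scope`
#'   and `compound_category`.
#' @inheritParams percent_guidelines_met
#' @return Score tibble; one row per input row, original order preserved.
#' @export
score_countries <- function(countries, params = guideline_params(),
                            mode = c("continuous", "table"), meets_tol = 0) {
  mode <- match.arg(mode)
  need <- c("country", "standard_midpoint_mg_kg", "salt_intake_g_day")
  if (!all(need %in% names(countries))) {
    stop("`countries` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- percent_guidelines_met(
    midpoint = countries$standard_midpoint_mg_kg,
    salt_intake = countries$salt_intake_g_day,
    params = params, mode = mode,
    country = countries$country,
    scope = if ("scope" %in% names(countries)) countries$scope else
      NA_character_,
    meets_tol = meets_tol
  )
  if ("compound_category" %in% names(countries)) {
    out$compound_category <- countries$compound_category
  }
  out
}
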