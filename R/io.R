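#' Pipeline run configuration
#'
#' Gathers every tunable threshold of the analysis in one place, with the
#' standard defaults: the 70% household-coverage threshold, the inclusive
#' 1-5 y window from coverage survey to mUIC assessment, the >1 y
#' post-standard gap, the 100-299 ug/L adequate-mUIC band, and the 100%
#' scoring line. Sensitivity analyses are a single config edit.
#'
#' @param params A [guideline_params()] object.
#' @param mode WHO-amount mode, `"continuous"` (default) or `"table"`.
#' @param coverage_threshold Minimum household coverage, percent.
#' @param window Inclusive years from coverage survey to mUIC assessment.
#' @param min_post_standard_gap Coverage survey must be strictly more than
#'   this many years after standard issuance.
#' @param reference_year Survey year anchoring the arithmetic
#'   (`"end"`, `"start"`, `"midpoint"`).
#' @param population_priority Preference order over mUIC population groups.
#' @param meets_tol Band half-width around 100% classified as `"meets"`.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = guideline_params(),
                       mode = c("continuous", "table"),
                       coverage_threshold = 70,
                       window = c(1, 5),
                       min_post_standard_gap = 1,
                       reference_year = c("end", "start", "midpoint"),
                       population_priority = c("school_age_children",
                                               "women_reproductive_age",
                                               "general"),
                       meets_tol = 0,
                       seed = NULL) {
  mode <- match.arg(mode)
  reference_year <- match.arg(reference_year)
  stopifnot(inherits(params, "guideline_params"))
  if (!(coverage_threshold > 0)) {
    stop("`coverage_threshold` must be positive", call. = FALSE)
  }
  if (length(window) != 2 || window[1] > window[2]) {
    stop("`window` must be c(low, high) with low <= high", call. = FALSE)
  }
  if (meets_tol < 0) stop("`meets_tol` must be non-negative", call. = FALSE)
  structure(
    list(params = params, mode = mode,
         coverage_threshold = coverage_threshold, window = window,
         min_post_standard_gap = min_post_standard_gap,
         reference_year = reference_year,
         population_priority = population_priority,
         meets_tol = meets_tol,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config"
  )
}

# ---- CSV readers with row-level validation -------------------------------

.schemas <- list(
  standards = c("country", "issue_year", "iodine_form", "iodine_low",
                "iodine_high", "iodine_value", "basis", "basis_compound",
                "compounds", "scope"),
  intake = c("country", "salt_intake_g_day"),
  coverage = c("country", "pct_households_any_iodized", "survey_start_year",
               "survey_end_year"),
  status = c("country", "muic_ug_L", "assessment_year", "population")
)

read_table_file <- function(path, what) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.schemas[[what]], names(df))
  if (length(missing) > 0) {
    stop(sprintf("malformed %s file %s: missing column(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Validate one table; returns list(data = valid rows, rejected = tibble of
# row/reason diagnostics). Row numbers refer to the input data frame.
validate_table <- function(df, what) {
  n <- nrow(df)
  reasons <- rep("", n)
  add <- function(bad, why) {
    bad <- which(bad)
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], why, sep = "; "), why)
  }
  iso_ok <- grepl("^[A-Za-z]{3}$", as.character(df$country))
  add(!iso_ok, "country is not an ISO3 code")

  if (what == "standards") {
    form <- as.character(df$iodine_form)
    add(!form %in% c("range", "minimum", "single"), "unknown iodine_form")
    is_rng <- form == "range"
    is_min <- form == "minimum"
    is_sgl <- form == "single"
    pos <- function(x) !is.na(x) & x > 0
    add(is_rng & !(pos(df$iodine_low) & pos(df$iodine_high)),
        "range form needs positive iodine_low and iodine_high")
    add(is_rng & pos(df$iodine_low) & pos(df$iodine_high) &
          df$iodine_low >= df$iodine_high,
        "range form needs iodine_low < iodine_high")
    add(is_min & !pos(df$iodine_low),
        "minimum form needs positive iodine_low")
    add(is_sgl & !pos(df$iodine_value),
        "single form needs positive iodine_value")
    add(!as.character(df$basis) %in% c("iodine", "compound"),
        "basis must be iodine or compound")
    add(df$basis == "compound" &
          (is.na(df$basis_compound) | !nzchar(df$basis_compound)),
        "compound basis needs basis_compound")
    add(is.na(df$compounds) | !nzchar(df$compounds),
        "compounds must be non-empty")
    add(!as.character(df$scope) %in% c("both", "household_only",
                                       "processed_only"),
        "unknown scope")
    yr <- suppressWarnings(as.integer(df$issue_year))
    add(is.na(yr) | yr < 1900 | yr > 2100, "implausible issue_year")
  } else if (what == "intake") {
    add(is.na(df$salt_intake_g_day) | df$salt_intake_g_day <= 0,
        "salt_intake_g_day must be positive")
  } else if (what == "coverage") {
    pct <- df$pct_households_any_iodized
    add(is.na(pct) | pct < 0 | pct > 100,
        "pct_households_any_iodized must lie in [0, 100]")
    add(is.na(df$survey_start_year) | is.na(df$survey_end_year) |
          df$survey_start_year > df$survey_end_year,
        "survey years must satisfy start <= end")
  } else if (what == "status") {
    add(is.na(df$muic_ug_L) | df$muic_ug_L < 0,
        "muic_ug_L must be non-negative")
    add(is.na(df$assessment_year), "missing assessment_year")
    add(!as.character(df$population) %in% c("school_age_children",
                                            "women_reproductive_age",
                                            "general"),
        "unknown population group")
  }

  bad <- nzchar(reasons)
  list(
    data = df[!bad, , drop = FALSE],
    rejected = tibble::tibble(table = what, row = which(bad),
                              country = as.character(df$country)[bad],
                              reason = reasons[bad])
  )
}

#' Read and validate the four input tables
#'
#' Reads the standards, salt-intake, coverage and mUIC CSV files, checks
#' every row against the type invariants, and returns the valid rows
#' together with row-numbered diagnostics for every rejected row. Coverage
#' and status tables are optional (the scoring analysis alone needs only
#' standards and intake).
#'
#' @param standards,intake Paths to the standards and salt-intake CSVs.
#' @param coverage,status Optional paths to the coverage and mUIC CSVs.
#' @return A list of class `validated_tables`: tibbles `standards`,
#'   `intake`, `coverage`, `status` (NULL when not supplied), and
#'   `rejected`, the combined diagnostics table.
#' @export
read_tables <- function(standards, intake, coverage = NULL, status = NULL) {
  out <- list()
  rejected <- list()
  paths <- list(standards = standards, intake = intake,
                coverage = coverage, status = status)
  for (what in names(paths)) {
    if (is.null(paths[[what]])) {
      out[[what]] <- NULL
      next
    }
    v <- validate_table(read_table_file(paths[[what]], what), what)
    out[[what]] <- v$data
    rejected[[what]] <- v$rejected
  }
  out$rejected <- dplyr::bind_rows(rejected)
  if (nrow(out$rejected) > 0) {
    message(sprintf("rejected %d invalid row(s) across input tables",
                    nrow(out$rejected)))
  }
  class(out) <- "validated_tables"
  out
}

# Midpoint on iodine basis for one standards row.
row_midpoint <- function(iodine_form, iodine_low, iodine_high, iodine_value,
                         basis, basis_compound) {
  spec <- switch(iodine_form,
    range = iodine_spec("range", low = iodine_low, high = iodine_high,
                        basis = basis, basis_compound = basis_compound),
    minimum = iodine_spec("minimum", low = iodine_low, basis = basis,
                          basis_compound = basis_compound),
    single = iodine_spec("single", value = iodine_value, basis = basis,
                         basis_compound = basis_compound)
  )
  extract_midpoint(to_iodine_basis(spec))
}

#' Run the full comparison pipeline
#'
#' Takes validated tables (from [read_tables()] or a
#' [generate_synthetic()] bundle), reduces each standard to its
#' iodine-basis midpoint, joins salt intakes, scores every country against
#' the WHO 2014 guideline amounts, classifies allowed compounds, and — when
#' coverage and mUIC tables are present — runs the eligibility-filtered and
#' relaxed correlation analyses.
#'
#' Exclusion accounting mirrors the flowchart logic of a country-selection
#' diagram: every input country ends up either in the score table or in the
#' exclusion log with a reason (invalid rows, duplicate standards, missing
#' intake data, unusable iodine specification).
#'
#' @param tables A list with tibbles `standards` and `intake`, optionally
#'   `coverage` and `status` (e.g. from [read_tables()]), and optionally a
#'   `rejected` diagnostics table.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `scores.csv`,
#'   `summary_by_category.csv`, `summary_by_compound.csv`,
#'   `exclusions.csv`, and — when linkage ran — `linkage.csv` and
#'   `correlation.json`. Outputs are byte-identical across re-runs with the
#'   same inputs and config.
#' @return A list of class `pipeline_result`: `scores`, `summary`
#'   (see [aggregate_scores()]), `exclusions`, `correlation_strict`,
#'   `correlation_relaxed` (NULL where not computable, with the reason in
#'   `notes`), `notes`, and `config`.
#' @export
run_pipeline <- function(tables, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!all(c("standards", "intake") %in% names(tables))) {
    stop("`tables` must contain at least `standards` and `intake`",
         call. = FALSE)
  }
  standards <- tables$standards
  intake <- tables$intake
  notes <- character(0)
  exclusions <- list()
  if (!is.null(tables$rejected) && nrow(tables$rejected) > 0) {
    exclusions$invalid <- tables$rejected |>
      dplyr::transmute(country = .data$country,
                       reason = paste0("invalid ", .data$table, " row ",
                                       .data$row, ": ", .data$reason))
  }

  # One standard per country: keep the first, log the duplicates.
  dup <- duplicated(standards$country)
  if (any(dup)) {
    exclusions$duplicates <- tibble::tibble(
      country = standards$country[dup],
      reason = "duplicate standard for country; first occurrence kept")
    notes <- c(notes, sprintf("%d duplicate standard(s) dropped", sum(dup)))
    standards <- standards[!dup, , drop = FALSE]
  }

  # Midpoints on iodine basis; unusable specs are excluded, not fatal.
  mids <- purrr::pmap(
    standards[, c("iodine_form", "iodine_low", "iodine_high",
                  "iodine_value", "basis", "basis_compound")],
    function(...) tryCatch(row_midpoint(...), error = function(e)
      conditionMessage(e)))
  ok <- vapply(mids, is.numeric, logical(1))
  if (any(!ok)) {
    exclusions$bad_spec <- tibble::tibble(
      country = standards$country[!ok],
      reason = paste0("unusable iodine specification: ",
                      unlist(mids[!ok])))
  }
  standards <- standards[ok, , drop = FALSE]
  standards$standard_midpoint_mg_kg <- unlist(mids[ok])

  # Compound classification per country.
  standards$compound_category <- vapply(
    strsplit(standards$compounds, ";", fixed = TRUE),
    function(x) classify_compounds(canonicalize_compound(trimws(x)),
                                   config$params),
    character(1))

  # Join intake; countries lacking intake data are excluded and counted.
  intake1 <- intake[!duplicated(intake$country), , drop = FALSE]
  joined <- dplyr::left_join(standards, intake1, by = "country")
  no_intake <- is.na(joined$salt_intake_g_day)
  if (any(no_intake)) {
    exclusions$no_intake <- tibble::tibble(
      country = joined$country[no_intake],
      reason = "no salt intake data")
  }
  joined <- joined[!no_intake, , drop = FALSE]
  if (nrow(joined) == 0) {
    stop("no country passed validation and joining; nothing to score",
         call. = FALSE)
  }

  scores <- score_countries(joined, params = config$params,
                            mode = config$mode,
                            meets_tol = config$meets_tol)
  scores$compound_category <- joined$compound_category
  summary <- aggregate_scores(scores)

  # Linkage and correlation, when survey tables are available.
  correlation_strict <- NULL
  correlation_relaxed <- NULL
  if (!is.null(tables$coverage) && !is.null(tables$status)) {
    correlation_strict <- tryCatch(
      correlate_muic(scores, tables$status, filter = "strict_eligibility",
                     coverage = tables$coverage, standards = standards,
                     population_priority = config$population_priority,
                     coverage_threshold = config$coverage_threshold,
                     window = config$window,
                     min_post_standard_gap = config$min_post_standard_gap,
                     reference_year = config$reference_year),
      error = function(e) {
        notes <<- c(notes, paste("strict correlation skipped:",
                                 conditionMessage(e)))
        NULL
      })
    correlation_relaxed <- tryCatch(
      correlate_muic(scores, tables$status, filter = "post_legislation_sac",
                     standards = standards),
      error = function(e) {
        notes <<- c(notes, paste("relaxed correlation skipped:",
                                 conditionMessage(e)))
        NULL
      })
  }

  exclusions <- if (length(exclusions) > 0) {
    dplyr::bind_rows(exclusions)
  } else {
    tibble::tibble(country = character(0), reason = character(0))
  }

  res <- structure(
    list(scores = scores, summary = summary, exclusions = exclusions,
         correlation_strict = correlation_strict,
         correlation_relaxed = correlation_relaxed,
         notes = notes, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d countries scored, %d excluded\n",
              nrow(x$scores), nrow(x$exclusions)))
  print(x$summary)
  if (!is.null(x$correlation_strict)) print(x$correlation_strict)
  if (!is.null(x$correlation_relaxed)) print(x$correlation_relaxed)
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Write pipeline outputs as CSV/JSON files
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of paths written, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, progress = FALSE)
    path
  }
  paths <- c(
    w(result$scores, "scores.csv"),
    w(result$summary$by_category, "summary_by_category.csv"),
    w(result$exclusions, "exclusions.csv")
  )
  if (!is.null(result$summary$by_compound)) {
    paths <- c(paths, w(result$summary$by_compound,
                        "summary_by_compound.csv"))
  }
  corr <- list()
  for (nm in c("correlation_strict", "correlation_relaxed")) {
    if (!is.null(result[[nm]])) {
      corr[[nm]] <- list(r = result[[nm]]$r, p = result[[nm]]$p,
                         n = result[[nm]]$n, filter = result[[nm]]$filter)
      paths <- c(paths, w(result[[nm]]$data,
                          paste0(sub("correlation_", "linkage_", nm),
                                 ".csv")))
    }
  }
  if (length(corr) > 0) {
    path <- file.path(out_dir, "correlation.json")
    jsonlite::write_json(corr, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
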