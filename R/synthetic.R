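#' Configuration for the synthetic country-data generator
#'
#' Describes the distributions and forward-model constants used by
#' [generate_synthetic()] to emulate the structure of the real country
#' tables: national salt standards whose iodine midpoints are multiples of
#' the WHO-suggested amounts, salt intakes of roughly 6-14 g/d, household
#' iodized-salt coverage surveys, and mUIC assessments produced by a
#' physiological forward model.
#'
#' The forward model for a country with salt intake `s` (g/d) and standard
#' midpoint `M` (mg iodine/kg salt) is:
#' consumed iodine concentration `c = M * compliance * (1 - loss_fraction)`
#' (ug iodine per g salt); daily iodine intake
#' `I = s * c + baseline_diet_iodine_ug` (ug/d); and
#' `mUIC = excreted_fraction * I / urine_volume_L` (ug/L), times
#' mean-one lognormal noise `exp(sigma * z - sigma^2 / 2)`.
#'
#' @param n_countries Number of countries to simulate (default 110).
#' @param seed Integer RNG seed; same config and seed give byte-identical
#'   output.
#' @param salt_intake_mean,salt_intake_sd Mean and SD (g/d) of the normal
#'   salt-intake distribution before truncation (defaults 10 and 2).
#' @param salt_intake_range Truncation bounds for intake, g/d (default
#'   `c(3, 14)`, the guideline grid).
#' @param multiplier_range Range of the uniform distribution of the ratio
#'   standard midpoint / WHO amount (default `c(0.68, 3.50)`, mirroring the
#'   observed 68%-350% span of national standards).
#' @param range_halfwidth_frac Fraction of the midpoint used to synthesize
#'   the low/high bounds of range-form standards (default 0.25).
#' @param compliance Multiplier in `[0, 1]` scaling actual versus stated
#'   iodine content of salt (default 1: full compliance).
#' @param coverage_range Range of the uniform household-coverage
#'   distribution for eligible countries, percent (default `c(70, 100)`).
#' @param eligible_fraction Fraction of countries generated to satisfy all
#'   eligibility criteria (default 0.5); the remainder violate exactly one
#'   criterion each, chosen at random.
#' @param noise_sigma Lognormal sdlog of the multiplicative mUIC noise
#'   (default 0.08; 0 disables noise exactly). The default is derived from
#'   the generator's adequacy contract: a population consuming salt iodized
#'   exactly at the guideline amount (mUIC centred at 122.85 ug/L) must be
#'   misclassified as insufficient (< 100 ug/L) with probability below about
#'   0.5%, which requires `pnorm((log(100/122.85) + sigma^2/2)/sigma)` small,
#'   i.e. sigma of at most ~0.084.
#' @param urine_volume_L Daily urine volume, L (default 1.0).
#' @param baseline_diet_iodine_ug Non-salt dietary iodine, ug/d (default 0).
#' @param excreted_fraction Fraction of ingested iodine excreted in urine
#'   (default 0.90).
#' @param who_mode Guideline-amount mode used by the generator,
#'   `"continuous"` (default) or `"table"`.
#' @param params A [guideline_params()] object.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 110,
                             seed = 1,
                             salt_intake_mean = 10,
                             salt_intake_sd = 2,
                             salt_intake_range = c(3, 14),
                             multiplier_range = c(0.68, 3.50),
                             range_halfwidth_frac = 0.25,
                             compliance = 1,
                             coverage_range = c(70, 100),
                             eligible_fraction = 0.5,
                             noise_sigma = 0.08,
                             urine_volume_L = 1.0,
                             baseline_diet_iodine_ug = 0,
                             excreted_fraction = 0.90,
                             who_mode = c("continuous", "table"),
                             params = guideline_params()) {
  who_mode <- match.arg(who_mode)
  stopifnot(inherits(params, "guideline_params"))
  n_countries <- as.integer(n_countries)
  if (is.na(n_countries) || n_countries < 0) {
    stop("`n_countries` must be a non-negative integer", call. = FALSE)
  }
  if (!(compliance >= 0 && compliance <= 1)) {
    stop("`compliance` must lie in [0, 1]", call. = FALSE)
  }
  if (!(excreted_fraction > 0 && excreted_fraction <= 1)) {
    stop("`excreted_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (salt_intake_sd < 0 || noise_sigma < 0) {
    stop("`salt_intake_sd` and `noise_sigma` must be non-negative",
         call. = FALSE)
  }
  bad_rng <- function(r) length(r) != 2 || anyNA(r) || r[1] > r[2]
  if (bad_rng(salt_intake_range) || bad_rng(multiplier_range) ||
      bad_rng(coverage_range)) {
    stop("range arguments must be length-2 with low <= high", call. = FALSE)
  }
  if (multiplier_range[1] <= 0) {
    stop("`multiplier_range` must be positive", call. = FALSE)
  }
  if (!(range_halfwidth_frac >= 0 && range_halfwidth_frac < 1)) {
    stop("`range_halfwidth_frac` must lie in [0, 1)", call. = FALSE)
  }
  if (!(eligible_fraction >= 0 && eligible_fraction <= 1)) {
    stop("`eligible_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (urine_volume_L <= 0) {
    stop("`urine_volume_L` must be positive", call. = FALSE)
  }
  if (baseline_diet_iodine_ug < 0) {
    stop("`baseline_diet_iodine_ug` must be non-negative", call. = FALSE)
  }
  structure(
    list(n_countries = n_countries, seed = as.integer(seed),
         salt_intake_mean = salt_intake_mean,
         salt_intake_sd = salt_intake_sd,
         salt_intake_range = salt_intake_range,
         multiplier_range = multiplier_range,
         range_halfwidth_frac = range_halfwidth_frac,
         compliance = compliance,
         coverage_range = coverage_range,
         eligible_fraction = eligible_fraction,
         noise_sigma = noise_sigma,
         urine_volume_L = urine_volume_L,
         baseline_diet_iodine_ug = baseline_diet_iodine_ug,
         excreted_fraction = excreted_fraction,
         who_mode = who_mode,
         params = params),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d countries, seed %d\n",
              x$n_countries, x$seed))
  cat(sprintf("  intake ~ N(%g, %g^2) truncated to [%g, %g] g/d\n",
              x$salt_intake_mean, x$salt_intake_sd,
              x$salt_intake_range[1], x$salt_intake_range[2]))
  cat(sprintf("  midpoint/WHO multiplier ~ U(%g, %g); compliance %g\n",
              x$multiplier_range[1], x$multiplier_range[2], x$compliance))
  cat(sprintf("  mUIC noise sigma %g; excreted fraction %g; urine %g L/d\n",
              x$noise_sigma, x$excreted_fraction, x$urine_volume_L))
  invisible(x)
}

# Deterministic pseudo-ISO3 codes: AAA, AAB, AAC, ...
synthetic_country_codes <- function(n) {
  if (n == 0) return(character(0))
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 676L + 1L],
         LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

# Truncated-normal sampling by inverse-CDF, so each draw consumes exactly one
# uniform and the RNG stream does not depend on rejection counts.
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic country-data bundle with known ground truth
#'
#' Simulates `n_countries` countries. For each, a salt intake `s` and a
#' multiplier `m` are drawn; the standard's iodine midpoint is set to
#' `m` times the WHO-suggested amount at intake `s`, and dressed up as a
#' range, minimum, or single-value specification. Compounds and legislation
#' scope are sampled with frequencies resembling the observed mix of
#' national standards (about 74% only recommended compounds, 25% mixed,
#' 1% none; about 87% of countries covering both household and
#' processed-food salt). Standard issue years, coverage surveys and mUIC
#' assessment years are arranged so that a configurable fraction of
#' countries satisfies the eligibility criteria, with each ineligible
#' country violating exactly one criterion. mUIC is produced by the
#' physiological forward model described in [synthetic_config()].
#'
#' The ground-truth table records the drawn multiplier (so
#' `percent_met = 100 * m` is recoverable exactly when noise is off), the
#' intended eligibility and the violated criterion, and the noise-free mUIC.
#' It is never read by the analysis pipeline.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_bundle` with tibbles `standards`,
#'   `intake`, `coverage`, `status`, and `truth`, plus the `config`.
#' @examples
#' b <- generate_synthetic(synthetic_config(n_countries = 5, seed = 42))
#' b$standards
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_countries
  p <- config$params

  empty <- function() {
    list(
      standards = tibble::tibble(
        country = character(0), issue_year = integer(0),
        iodine_form = character(0), iodine_low = numeric(0),
        iodine_high = numeric(0), iodine_value = numeric(0),
        basis = character(0), basis_compound = character(0),
        compounds = character(0), scope = character(0)),
      intake = tibble::tibble(country = character(0),
                              salt_intake_g_day = numeric(0)),
      coverage = tibble::tibble(
        country = character(0), pct_households_any_iodized = numeric(0),
        survey_start_year = integer(0), survey_end_year = integer(0)),
      status = tibble::tibble(
        country = character(0), muic_ug_L = numeric(0),
        assessment_year = integer(0), population = character(0)),
      truth = tibble::tibble(
        country = character(0), multiplier = numeric(0),
        true_percent_met = numeric(0), true_category = character(0),
        midpoint_mg_kg = numeric(0), muic_noise_free = numeric(0),
        eligible = logical(0), violated_criterion = character(0))
    )
  }

  if (n == 0) {
    out <- empty()
    out$config <- config
    class(out) <- "synthetic_bundle"
    return(out)
  }

  # All randomness inside a private RNG scope; restore the caller's stream.
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  country <- synthetic_country_codes(n)
  s <- rtruncnorm_inv(n, config$salt_intake_mean, config$salt_intake_sd,
                      config$salt_intake_range[1], config$salt_intake_range[2])
  m <- stats::runif(n, config$multiplier_range[1], config$multiplier_range[2])
  who_amt <- who_iodine_amount(s, p, mode = config$who_mode)
  midpoint <- m * who_amt

  # Specification form: mostly ranges, as in real standards.
  form <- sample(c("range", "single", "minimum"), n, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  h <- config$range_halfwidth_frac
  iodine_low <- ifelse(form == "range", midpoint * (1 - h),
                       ifelse(form == "minimum", midpoint, NA_real_))
  iodine_high <- ifelse(form == "range", midpoint * (1 + h), NA_real_)
  iodine_value <- ifelse(form == "single", midpoint, NA_real_)

  # Compound mix per country, drawn by target category.
  ccat <- sample(c("all_recommended", "mixed", "none_recommended"), n,
                 replace = TRUE, prob = c(0.74, 0.25, 0.01))
  rec_choice <- sample(c("potassium_iodate", "potassium_iodide", "both"), n,
                       replace = TRUE, prob = c(0.5, 0.2, 0.3))
  nonrec_choice <- sample(c("calcium_iodate", "sodium_iodide"), n,
                          replace = TRUE)
  compounds <- character(n)
  for (i in seq_len(n)) {
    rec <- if (rec_choice[i] == "both")
      c("potassium_iodate", "potassium_iodide") else rec_choice[i]
    compounds[i] <- switch(ccat[i],
      all_recommended = paste(rec, collapse = ";"),
      mixed = paste(c(rec, nonrec_choice[i]), collapse = ";"),
      none_recommended = nonrec_choice[i]
    )
  }

  scope <- sample(c("both", "household_only", "processed_only"), n,
                  replace = TRUE, prob = c(96, 9, 5) / 110)

  # Year scheme. Eligible countries: coverage >= 70%, survey > 1 y after
  # standard issue, mUIC 1-5 y after the survey. Each ineligible country
  # breaks exactly one of the three criteria.
  eligible <- stats::runif(n) < config$eligible_fraction
  violated <- ifelse(eligible, "",
                     sample(c("coverage_below_70", "window_violation",
                              "pre_standard_survey"), n, replace = TRUE))

  survey_end <- sample(2008:2015, n, replace = TRUE)
  survey_start <- survey_end - sample(0:1, n, replace = TRUE)
  issue_year <- survey_end - sample(2:15, n, replace = TRUE)
  muic_year <- survey_end + sample(1:5, n, replace = TRUE)
  pct_cov <- stats::runif(n, config$coverage_range[1],
                          config$coverage_range[2])

  low_cov <- stats::runif(n, 30, 69.9)
  bad_gap <- sample(6:9, n, replace = TRUE)
  pct_cov[violated == "coverage_below_70"] <-
    low_cov[violated == "coverage_below_70"]
  muic_year[violated == "window_violation"] <-
    survey_end[violated == "window_violation"] +
    bad_gap[violated == "window_violation"]
  issue_year[violated == "pre_standard_survey"] <-
    survey_end[violated == "pre_standard_survey"] -
    sample(0:1, sum(violated == "pre_standard_survey"), replace = TRUE)

  population <- sample(c("school_age_children", "women_reproductive_age",
                         "general"), n, replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))

  # Physiological forward model; noise drawn as standard normals first so
  # the stream is identical across sigma and compliance settings.
  z <- stats::rnorm(n)
  sig <- config$noise_sigma
  noise <- exp(sig * z - sig^2 / 2)
  conc <- midpoint * config$compliance * (1 - p$loss_fraction) # ug I / g salt
  intake_ug <- s * conc + config$baseline_diet_iodine_ug
  muic_clean <- config$excreted_fraction * intake_ug / config$urine_volume_L
  muic <- muic_clean * noise

  out <- list(
    standards = tibble::tibble(
      country = country, issue_year = as.integer(issue_year),
      iodine_form = form, iodine_low = iodine_low,
      iodine_high = iodine_high, iodine_value = iodine_value,
      basis = "iodine", basis_compound = NA_character_,
      compounds = compounds, scope = scope),
    intake = tibble::tibble(country = country, salt_intake_g_day = s),
    coverage = tibble::tibble(
      country = country, pct_households_any_iodized = pct_cov,
      survey_start_year = as.integer(survey_start),
      survey_end_year = as.integer(survey_end)),
    status = tibble::tibble(
      country = country, muic_ug_L = muic,
      assessment_year = as.integer(muic_year), population = population),
    truth = tibble::tibble(
      country = country, multiplier = m, true_percent_met = 100 * m,
      true_category = score_category(100 * m),
      midpoint_mg_kg = midpoint, muic_noise_free = muic_clean,
      eligible = eligible, violated_criterion = violated),
    config = config
  )
  class(out) <- "synthetic_bundle"
  out
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d countries (seed %d)\n",
              nrow(x$standards), x$config$seed))
  cat("  tables: standards, intake, coverage, status, truth\n")
  invisible(x)
}

#' Write a synthetic bundle as CSV files
#'
#' Writes `standards.csv`, `intake.csv`, `coverage.csv`, `status.csv` and
#' `ground_truth.csv` under `dir`. The ground-truth file is for validation
#' only and is never read by the pipeline.
#'
#' @param bundle A [generate_synthetic()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_synthetic <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(standards = "standards.csv", intake = "intake.csv",
             coverage = "coverage.csv", status = "status.csv",
             truth = "ground_truth.csv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (nm in names(files)) {
    readr::write_csv(bundle[[nm]], paths[[nm]], progress = FALSE)
  }
  invisible(paths)
}

#' Recover ground truth from a synthetic bundle through the pipeline
#'
#' Runs the full scoring pipeline on the generated tables (never touching
#' the ground-truth table) and compares: recovered `percent_met` against
#' `100 * m` (exact, to floating-point, when noise is off); recovered
#' category counts against the generator's bookkeeping; and the mUIC
#' classification mix.
#'
#' @param bundle A [generate_synthetic()] result.
#' @param mode WHO-amount mode for the recovery run; defaults to the mode
#'   the generator used.
#' @return A list of class `recovery_report`: `comparison` (per-country
#'   tibble with recovered and true percent), `max_abs_rel_error`,
#'   `category_agreement` (fraction of countries whose recovered category
#'   matches truth), `category_counts`, and `muic_class_counts`.
#' @export
recover_synthetic <- function(bundle, mode = NULL) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  need <- c("standards", "intake", "coverage", "status", "truth")
  if (!all(need %in% names(bundle)) ||
      !all(vapply(bundle[need], is.data.frame, logical(1)))) {
    stop("bundle is missing generated tables", call. = FALSE)
  }
  if (is.null(mode)) mode <- bundle$config$who_mode
  params <- bundle$config$params
  res <- run_pipeline(tables = bundle[c("standards", "intake", "coverage",
                                        "status")],
                      config = run_config(params = params, mode = mode))
  scores <- res$scores
  comparison <- dplyr::inner_join(
    dplyr::select(scores, "country", "percent_met", "category"),
    dplyr::select(bundle$truth, "country", "true_percent_met",
                  "true_category"),
    by = "country")
  rel_err <- abs(comparison$percent_met - comparison$true_percent_met) /
    comparison$true_percent_met
  muic_class <- classify_muic(bundle$status$muic_ug_L)
  structure(
    list(
      comparison = comparison,
      max_abs_rel_error = if (nrow(comparison)) max(rel_err) else NA_real_,
      category_agreement = if (nrow(comparison))
        mean(comparison$category == comparison$true_category) else NA_real_,
      category_counts = table(factor(scores$category,
                                     levels = c("below", "meets", "above"))),
      muic_class_counts = table(factor(muic_class,
                                       levels = c("insufficient", "adequate",
                                                  "excessive"))),
      n = nrow(comparison)
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d countries\n", x$n))
  cat(sprintf("  max |rel. error| in percent_met: %.3g\n",
              x$max_abs_rel_error))
  cat(sprintf("  category agreement with ground truth: %.1f%%\n",
              100 * x$category_agreement))
  invisible(x)
}
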