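# Iodine compound reference: canonical ids, synonyms, and elemental iodine
# mass fractions from atomic masses (K 39.098, I 126.904, O 16.000,
# Na 22.990, Ca 40.078).
.compound_db <- local({
  mI <- 126.904
  tibble::tribble(
    ~id,                 ~molar_mass,                ~n_iodine,
    "potassium_iodate",  39.098 + mI + 3 * 16.000,   1, # KIO3, 214.002
    "potassium_iodide",  39.098 + mI,                1, # KI,   166.002
    "sodium_iodate",     22.990 + mI + 3 * 16.000,   1, # NaIO3
    "sodium_iodide",     22.990 + mI,                1, # NaI
    "calcium_iodate",    40.078 + 2 * (mI + 48.0),   2  # Ca(IO3)2
  ) |>
    dplyr::mutate(iodine_mass_fraction = .data$n_iodine * mI / .data$molar_mass)
})

.compound_synonyms <- c(
  "kio3" = "potassium_iodate",
  "iodate" = "potassium_iodate",
  "potassiumiodate" = "potassium_iodate",
  "ki" = "potassium_iodide",
  "iodide" = "potassium_iodide",
  "potassiumiodide" = "potassium_iodide",
  "naio3" = "sodium_iodate",
  "sodiumiodate" = "sodium_iodate",
  "nai" = "sodium_iodide",
  "sodiumiodide" = "sodium_iodide",
  "caio32" = "calcium_iodate",
  "calciumiodate" = "calcium_iodate"
)

#' Elemental iodine mass fraction of a fortification compound
#'
#' @param compound Canonical compound id(s), e.g. `"potassium_iodate"`.
#' @return Numeric vector: grams of iodine per gram of compound.
#' @examples
#' iodine_mass_fraction("potassium_iodate") # ~0.593
#' @export
iodine_mass_fraction <- function(compound) {
  idx <- match(compound, .compound_db$id)
  if (anyNA(idx)) {
    stop("no iodine mass fraction known for compound(s): ",
         paste(unique(compound[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  .compound_db$iodine_mass_fraction[idx]
}

#' Canonicalize a free-text iodine compound name
#'
#' Maps case- and punctuation-insensitive synonyms ("KIO3", "iodate",
#' "Potassium Iodate", ...) to canonical snake_case ids. Unknown names are
#' preserved as opaque snake_case ids with a warning; they are treated as
#' non-recommended by [classify_compounds()] and have no known iodine mass
#' fraction.
#'
#' @param name Character vector of compound names; empty strings are an error.
#' @return Character vector of canonical compound ids.
#' @examples
#' canonicalize_compound(c("KIO3", "Potassium Iodide"))
#' @export
canonicalize_compound <- function(name) {
  if (length(name) == 0) return(character(0))
  name <- as.character(name)
  if (anyNA(name) || any(!nzchar(trimws(name)))) {
    stop("compound names must be non-empty strings", call. = FALSE)
  }
  key <- gsub("[^a-z0-9]", "", tolower(name))
  out <- unname(.compound_synonyms[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    fallback <- gsub("[^a-z0-9]+", "_", tolower(trimws(name[unknown])))
    fallback <- gsub("^_+|_+$", "", fallback)
    already_canonical <- fallback %in% .compound_db$id
    if (any(!already_canonical)) {
      warning("unrecognized compound name(s) kept as opaque non-recommended ",
              "ids: ", paste(unique(fallback[!already_canonical]),
                             collapse = ", "),
              call. = FALSE)
    }
    out[unknown] <- fallback
  }
  out
}

#' Classify a standard's allowed compounds against the recommended set
#'
#' A country's standard lists the iodine compounds it permits. Relative to the
#' WHO-recommended set (potassium iodate, potassium iodide by default) every
#' non-empty list falls into exactly one of three categories: all compounds
#' recommended, a mix of recommended and non-recommended, or none
#' recommended. The result is invariant to list order and duplicates.
#'
#' @param compounds Non-empty character vector of canonical compound ids (see
#'   [canonicalize_compound()]).
#' @param params A [guideline_params()] object supplying the recommended set.
#' @return One of `"all_recommended"`, `"mixed"`, `"none_recommended"`.
#' @examples
#' classify_compounds(c("potassium_iodate", "potassium_iodide"))
#' classify_compounds(c("potassium_iodate", "calcium_iodate"))
#' @export
classify_compounds <- function(compounds, params = guideline_params()) {
  stopifnot(inherits(params, "guideline_params"))
  compounds <- unique(as.character(compounds))
  compounds <- compounds[!is.na(compounds) & nzchar(compounds)]
  if (length(compounds) == 0) {
    stop("`compounds` must be a non-empty list of compound ids",
         call. = FALSE)
  }
  rec <- compounds %in% params$recommended_compounds
  if (all(rec)) "all_recommended"
  else if (!any(rec)) "none_recommended"
  else "mixed"
}

#' Iodine specification of a salt standard
#'
#' National standards state the required iodine content of fortified salt as
#' a range, a minimum, or a single value, either as elemental iodine (mg
#' iodine per kg salt, i.e. ppm) or as mass of a fortification compound.
#'
#' @param form `"range"`, `"minimum"`, or `"single"`.
#' @param low Lower bound, mg/kg (range and minimum forms).
#' @param high Upper bound, mg/kg (range form only).
#' @param value Stated amount, mg/kg (single form only).
#' @param basis `"iodine"` (default; amounts are elemental iodine) or
#'   `"compound"` (amounts are mass of `basis_compound`).
#' @param basis_compound Canonical compound id; required when
#'   `basis = "compound"`.
#' @return An object of class `iodine_spec`.
#' @examples
#' iodine_spec("range", low = 30, high = 50)
#' iodine_spec("single", value = 33.7, basis = "compound",
#'             basis_compound = "potassium_iodate")
#' @export
iodine_spec <- function(form = c("range", "minimum", "single"),
                        low = NULL, high = NULL, value = NULL,
                        basis = c("iodine", "compound"),
                        basis_compound = NULL) {
  form <- match.arg(form)
  basis <- match.arg(basis)
  num1 <- function(x, what) {
    if (is.null(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number for form '%s'",
                   what, form), call. = FALSE)
    }
    as.numeric(x)
  }
  spec <- switch(form,
    range = {
      low <- num1(low, "low"); high <- num1(high, "high")
      if (low >= high) {
        stop("range form requires low < high", call. = FALSE)
      }
      list(form = form, low = low, high = high)
    },
    minimum = list(form = form, low = num1(low, "low")),
    single = list(form = form, value = num1(value, "value"))
  )
  if (basis == "compound") {
    if (is.null(basis_compound) || length(basis_compound) != 1) {
      stop("basis = 'compound' requires `basis_compound`", call. = FALSE)
    }
    if (!basis_compound %in% .compound_db$id) {
      stop("no iodine conversion known for compound: ", basis_compound,
           call. = FALSE)
    }
    spec$basis_compound <- as.character(basis_compound)
  }
  spec$basis <- basis
  structure(spec, class = "iodine_spec")
}

#' @export
print.iodine_spec <- function(x, ...) {
  amt <- switch(x$form,
    range = sprintf("%g-%g", x$low, x$high),
    minimum = sprintf(">= %g", x$low),
    single = sprintf("%g", x$value)
  )
  basis <- if (x$basis == "iodine") "mg iodine/kg" else
    sprintf("mg %s/kg", x$basis_compound)
  cat(sprintf("<iodine_spec> %s: %s %s\n", x$form, amt, basis))
  invisible(x)
}

#' Convert an iodine specification to elemental-iodine basis
#'
#' Specifications stated as compound mass (e.g. 33.7 mg KIO3 per kg salt) are
#' converted to elemental iodine by the compound's iodine mass fraction;
#' specifications already on iodine basis are returned unchanged, so the
#' operation is idempotent.
#'
#' @param spec An [iodine_spec()].
#' @return An `iodine_spec` with `basis = "iodine"`.
#' @examples
#' sp <- iodine_spec("single", value = 33.7, basis = "compound",
#'                   basis_compound = "potassium_iodate")
#' to_iodine_basis(sp) # ~19.98 mg iodine/kg
#' @export
to_iodine_basis <- function(spec) {
  stopifnot(inherits(spec, "iodine_spec"))
  if (spec$basis == "iodine") return(spec)
  f <- iodine_mass_fraction(spec$basis_compound)
  out <- spec
  for (fld in c("low", "high", "value")) {
    if (!is.null(out[[fld]])) out[[fld]] <- out[[fld]] * f
  }
  out$basis <- "iodine"
  out$basis_compound <- NULL
  out
}

#' Midpoint (or single amount) of an iodine specification
#'
#' Reduces a standard's iodine specification to the one number used in
#' scoring: the midpoint of a range, the single stated amount, or — for
#' minimum-only standards — the minimum treated as the single stated amount.
#' The specification must already be on elemental-iodine basis
#' (see [to_iodine_basis()]).
#'
#' @param spec An [iodine_spec()] with `basis = "iodine"`.
#' @return Iodine amount, mg/kg salt.
#' @examples
#' extract_midpoint(iodine_spec("range", low = 30, high = 50)) # 40
#' @export
extract_midpoint <- function(spec) {
  stopifnot(inherits(spec, "iodine_spec"))
  if (spec$basis != "iodine") {
    stop("spec must be on iodine basis; call to_iodine_basis() first",
         call. = FALSE)
  }
  switch(spec$form,
    range = (spec$low + spec$high) / 2,
    minimum = spec$low,
    single = spec$value
  )
}

#' A national salt-iodization standard
#'
#' One country's current standard: the iodine specification, the allowed
#' fortification compounds, the scope of the legislation (whether household
#' salt, processed-food salt, or both must be iodized), and the year the
#' standard was issued.
#'
#' @param country ISO3 country code.
#' @param issue_year Calendar year the standard was issued (1900–2100).
#' @param spec An [iodine_spec()].
#' @param compounds Non-empty character vector of allowed compounds (free
#'   text accepted; canonicalized on construction).
#' @param scope `"both"`, `"household_only"`, or `"processed_only"`.
#' @return An object of class `salt_standard`.
#' @export
salt_standard <- function(country, issue_year, spec, compounds,
                          scope = c("both", "household_only",
                                    "processed_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(spec, "iodine_spec"))
  country <- toupper(as.character(country))
  if (length(country) != 1 || !grepl("^[A-Z]{3}$", country)) {
    stop("`country` must be a single ISO3 code", call. = FALSE)
  }
  issue_year <- as.integer(issue_year)
  if (length(issue_year) != 1 || is.na(issue_year) ||
      issue_year < 1900 || issue_year > 2100) {
    stop("`issue_year` must be a calendar year in 1900-2100", call. = FALSE)
  }
  if (length(compounds) == 0) {
    stop("`compounds` must be non-empty", call. = FALSE)
  }
  structure(
    list(country = country, issue_year = issue_year, spec = spec,
         compounds = canonicalize_compound(compounds), scope = scope),
    class = "salt_standard"
  )
}

#' @export
print.salt_standard <- function(x, ...) {
  cat(sprintf("<salt_standard> %s (issued %d, scope %s)\n",
              x$country, x$issue_year, x$scope))
  print(x$spec)
  cat("  compounds:", paste(x$compounds, collapse = ", "), "\n")
  invisible(x)
}
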