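#' Round half away from zero
#'
#' Commercial ("round half up") rounding: ties at .5 go away from zero, unlike
#' [base::round()], which rounds half to even. The WHO 2014 suggested iodine
#' amounts are only reproduced under this convention: 195/6 = 32.5 prints as
#' 33 mg/kg, while round-half-to-even would give 32.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(19.5) # 20
#' round_half_up(32.5) # 33
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' WHO 2014 guideline parameters
#'
#' Constants behind the WHO 2014 salt-fortification guideline model: the mean
#' recommended nutrient intake (RNI) for iodine, the assumed proportional loss
#' of iodine between salt production and the household, the iodine
#' bioavailability quoted alongside the guideline table, the salt-intake grid
#' the table is printed over, and the set of WHO-recommended fortification
#' compounds.
#'
#' `bioavailability` is carried for completeness: the printed guideline
#' amounts are reproduced by `RNI * (1 + loss) / intake` alone, so it does not
#' enter [who_table()] or [who_iodine_amount()].
#'
#' @param rni_ug_per_day Mean iodine RNI, micrograms per day (default 150).
#' @param loss_fraction Proportion of iodine lost from production to
#'   household, in (0, 1) (default 0.30).
#' @param bioavailability Proportion of ingested iodine absorbed, in (0, 1]
#'   (default 0.92; recorded, not used in the table formula).
#' @param intake_grid_g_per_day Integer grid of daily salt intakes the
#'   guideline table covers (default 3:14 g/d).
#' @param recommended_compounds Canonical ids of WHO-recommended iodine
#'   compounds (default potassium iodate and potassium iodide).
#' @return An object of class `guideline_params`.
#' @examples
#' guideline_params()
#' @export
guideline_params <- function(rni_ug_per_day = 150,
                             loss_fraction = 0.30,
                             bioavailability = 0.92,
                             intake_grid_g_per_day = 3:14,
                             recommended_compounds = c("potassium_iodate",
                                                       "potassium_iodide")) {
  stopifnot(is.numeric(rni_ug_per_day), length(rni_ug_per_day) == 1)
  if (!(rni_ug_per_day > 0)) {
    stop("`rni_ug_per_day` must be positive", call. = FALSE)
  }
  if (!(is.numeric(loss_fraction) && length(loss_fraction) == 1 &&
        loss_fraction > 0 && loss_fraction < 1)) {
    stop("`loss_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(is.numeric(bioavailability) && length(bioavailability) == 1 &&
        bioavailability > 0 && bioavailability <= 1)) {
    stop("`bioavailability` must lie in (0, 1]", call. = FALSE)
  }
  grid <- as.integer(intake_grid_g_per_day)
  if (length(grid) < 1 || anyNA(grid) || any(diff(grid) <= 0)) {
    stop("`intake_grid_g_per_day` must be strictly increasing integers",
         call. = FALSE)
  }
  if (any(grid <= 0)) {
    stop("salt intakes in the grid must be positive", call. = FALSE)
  }
  if (length(recommended_compounds) < 1) {
    stop("`recommended_compounds` must be non-empty", call. = FALSE)
  }
  structure(
    list(
      rni_ug_per_day = as.numeric(rni_ug_per_day),
      loss_fraction = as.numeric(loss_fraction),
      bioavailability = as.numeric(bioavailability),
      intake_grid_g_per_day = grid,
      recommended_compounds = unique(as.character(recommended_compounds))
    ),
    class = "guideline_params"
  )
}

#' @export
print.guideline_params <- function(x, ...) {
  cat("<guideline_params>\n")
  cat(sprintf("  RNI:             %g ug iodine/d\n", x$rni_ug_per_day))
  cat(sprintf("  loss fraction:   %g (production -> household)\n",
              x$loss_fraction))
  cat(sprintf("  bioavailability: %g (recorded; not in table formula)\n",
              x$bioavailability))
  cat(sprintf("  intake grid:     %d..%d g salt/d\n",
              min(x$intake_grid_g_per_day), max(x$intake_grid_g_per_day)))
  cat(sprintf("  recommended compounds: %s\n",
              paste(x$recommended_compounds, collapse = ", ")))
  invisible(x)
}

#' Read guideline parameters from a YAML or JSON file
#'
#' Any subset of the [guideline_params()] arguments may appear in the file;
#' missing fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `guideline_params` object.
#' @export
read_guideline_params <- function(path) {
  if (!file.exists(path)) {
    stop("guideline parameter file not found: ", path, call. = FALSE)
  }
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(guideline_params))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    warning("ignoring unknown guideline parameter fields: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(guideline_params, vals[intersect(names(vals), known)])
}

#' WHO 2014 suggested iodine amounts, as a table
#'
#' Generates the guideline lookup table mapping estimated daily salt intake
#' (g/d) to the average amount of iodine to add to salt (mg iodine per kg
#' salt). Each entry is `round_half_up(RNI * (1 + loss_fraction) / intake)`;
#' with default parameters this reproduces the published WHO 2014 table
#' (65, 49, 39, 33, 28, 24, 22, 20, 18, 16, 15, 14 mg/kg for 3..14 g/d).
#'
#' @param params A [guideline_params()] object.
#' @return A tibble of class `who_guideline_table` with columns
#'   `salt_intake_g_day` and `iodine_mg_kg`.
#' @examples
#' who_table()
#' @export
who_table <- function(params = guideline_params()) {
  stopifnot(inherits(params, "guideline_params"))
  grid <- params$intake_grid_g_per_day
  amounts <- round_half_up(
    params$rni_ug_per_day * (1 + params$loss_fraction) / grid
  )
  if (any(diff(amounts) >= 0)) {
    stop("guideline amounts are not strictly decreasing in salt intake; ",
         "check the parameter values", call. = FALSE)
  }
  out <- tibble::tibble(salt_intake_g_day = grid, iodine_mg_kg = amounts)
  class(out) <- c("who_guideline_table", class(out))
  out
}

#' Suggested iodine amount for a given salt intake
#'
#' Looks up (or computes) the WHO 2014 suggested iodine concentration for
#' salt, in mg iodine per kg salt, at a given estimated salt intake.
#'
#' Two modes are provided because national salt-intake estimates are
#' real-valued while the guideline table is printed on an integer grid:
#'
#' * `"table"`: rounds the intake half-up to the nearest grid integer,
#'   clamped to the grid range, and returns the printed table value.
#' * `"continuous"` (default): evaluates the generating formula
#'   `RNI * (1 + loss_fraction) / intake` without rounding, which agrees with
#'   the table to within 0.5 mg/kg at every grid point and varies smoothly
#'   between them.
#'
#' A warning is emitted when the intake falls outside the guideline grid
#' range (3–14 g/d by default); the value is still returned (clamped in table
#' mode, extrapolated by the formula in continuous mode).
#'
#' @param salt_intake Estimated salt intake, g/d; positive numeric vector.
#' @param params A [guideline_params()] object.
#' @param mode `"continuous"` or `"table"`.
#' @return Numeric vector of iodine amounts, mg/kg salt.
#' @examples
#' who_iodine_amount(10, mode = "table") # 20
#' who_iodine_amount(10) # 19.5
#' who_iodine_amount(6.5) # 30
#' @export
who_iodine_amount <- function(salt_intake,
                              params = guideline_params(),
                              mode = c("continuous", "table")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "guideline_params"))
  if (length(salt_intake) == 0) return(numeric(0))
  if (!is.numeric(salt_intake) || anyNA(salt_intake) ||
      any(salt_intake <= 0)) {
    stop("`salt_intake` must be positive (g/d)", call. = FALSE)
  }
  grid <- params$intake_grid_g_per_day
  lo <- min(grid)
  hi <- max(grid)
  outside <- salt_intake < lo | salt_intake > hi
  if (any(outside)) {
    warning(sprintf(
      "%d salt intake value(s) outside the guideline grid [%d, %d] g/d",
      sum(outside), lo, hi), call. = FALSE)
  }
  if (mode == "continuous") {
    params$rni_ug_per_day * (1 + params$loss_fraction) / salt_intake
  } else {
    tab <- who_table(params)
    idx <- pmin(pmax(round_half_up(salt_intake), lo), hi)
    tab$iodine_mg_kg[match(idx, tab$salt_intake_g_day)]
  }
}

#' Write the guideline table as CSV
#'
#' @param table A [who_table()] result (any data frame with columns
#'   `salt_intake_g_day`, `iodine_mg_kg`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_who_table <- function(table, path) {
  stopifnot(all(c("salt_intake_g_day", "iodine_mg_kg") %in% names(table)))
  readr::write_csv(table[, c("salt_intake_g_day", "iodine_mg_kg")], path)
  invisible(path)
}
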