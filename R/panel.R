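#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

PANEL_KEY <- c("year", "country", "species", "environment")
ENVIRONMENTS <- c("marine", "brackish", "freshwater", "unknown")
GROUPS <- c("fish", "bivalve", "crustacean", "alga", "other")

#' Construct a production panel
#'
#' A production panel is the substrate of every analysis in this package: a
#' tidy collection of annual production records, one per
#' (year, country, species, environment) combination, with quantities in
#' tonnes live weight and an optional first-sale value in thousand US$.
#'
#' @param records A data frame with columns `year`, `country`, `species`,
#'   `quantity` and optionally `environment`, `group`, `value`. Missing
#'   `environment` is filled with `"unknown"`, missing `group` with
#'   `"other"`.
#' @param provenance Free-text description of where the records came from.
#' @param strict If `TRUE`, duplicated (year, country, species, environment)
#'   keys are an error; if `FALSE` (default) their quantities and values are
#'   summed, as FAO exports sometimes split a series by sub-environment.
#'
#' @return An object of class `production_panel`: a list with elements
#'   `records` (tibble) and `provenance`, plus the derived `year_range`.
#' @export
production_panel <- function(records, provenance = "unspecified", strict = FALSE) {
  records <- as_tibble(records)
  required <- c("year", "country", "species", "quantity")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("panel records lack required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "aquapanel_format_error"
    )
  }
  if (!"environment" %in% names(records)) records$environment <- "unknown"
  if (!"group" %in% names(records)) records$group <- "other"
  has_value <- "value" %in% names(records)

  records$year <- as.integer(records$year)
  records$quantity <- as.numeric(records$quantity)
  for (col in c("country", "species")) {
    records[[col]] <- trimws(as.character(records[[col]]))
    if (any(!is.na(records[[col]]) & records[[col]] == "")) {
      abort(sprintf("empty '%s' label after trimming", col),
            class = "aquapanel_validation_error")
    }
  }

  bad_year <- which(is.na(records$year) | records$year < 1900 | records$year > 2100)
  if (length(bad_year) > 0) {
    abort(sprintf("year outside [1900, 2100] at row(s): %s",
                  paste(utils::head(bad_year, 5), collapse = ", ")),
          class = "aquapanel_validation_error")
  }
  bad_q <- which(!is.na(records$quantity) & records$quantity < 0)
  if (length(bad_q) > 0) {
    abort(sprintf("negative quantity at row(s): %s",
                  paste(utils::head(bad_q, 5), collapse = ", ")),
          class = "aquapanel_validation_error")
  }

  env <- tolower(as.character(records$environment))
  env[grepl("^brackish", env)] <- "brackish"  # FAO exports say "Brackishwater"
  records$environment <- normalise_enum(env, ENVIRONMENTS, "unknown", "environment")
  records$group <- normalise_enum(records$group, GROUPS, "other", "group")

  keep <- c(PANEL_KEY, "group", "quantity", if (has_value) "value")
  records <- records[keep]

  dup <- duplicated(records[PANEL_KEY])
  if (any(dup)) {
    if (strict) {
      abort(sprintf("duplicate (year, country, species, environment) keys at row(s): %s",
                    paste(utils::head(which(dup), 5), collapse = ", ")),
            class = "aquapanel_validation_error")
    }
    records <- dplyr::summarise(
      dplyr::group_by(records, dplyr::across(dplyr::all_of(c(PANEL_KEY, "group")))),
      quantity = if (all(is.na(.data$quantity))) NA_real_ else sum(.data$quantity, na.rm = TRUE),
      dplyr::across(dplyr::any_of("value"),
                    ~ if (all(is.na(.x))) NA_real_ else sum(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  }
  records <- dplyr::arrange(records, .data$year, .data$country, .data$species, .data$environment)

  structure(
    list(records = records, provenance = provenance),
    class = "production_panel"
  )
}

normalise_enum <- function(x, levels, fallback, what) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- fallback
  off <- !(x %in% levels)
  if (any(off)) {
    warn(sprintf("%d record(s) with %s outside {%s}; set to '%s'",
                 sum(off), what, paste(levels, collapse = ", "), fallback))
    x[off] <- fallback
  }
  x
}

#' @export
print.production_panel <- function(x, ...) {
  yr <- panel_years(x)
  cat("<production_panel> ", nrow(x$records), " records",
      if (length(yr)) sprintf(", years %d-%d", min(yr), max(yr)) else "",
      "\n", sep = "")
  cat("  countries: ", length(unique(x$records$country)),
      " | species: ", length(unique(x$records$species)), "\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Years covered by a panel
#'
#' @param panel A `production_panel`.
#' @return Sorted integer vector of distinct record years (empty panel gives
#'   a length-zero vector).
#' @export
panel_years <- function(panel) {
  stopifnot(inherits(panel, "production_panel"))
  sort(unique(panel$records$year))
}

#' Aggregate a panel over a key subset
#'
#' Sums the chosen measure over all records sharing each combination of the
#' requested keys. Missing measures are excluded, so the output total equals
#' the input total of non-missing values for any key subset.
#'
#' @param panel A `production_panel`.
#' @param keys Non-empty character subset of
#'   `c("year", "country", "species", "environment", "group")`.
#' @param measure `"quantity"` (tonnes) or `"value"` (thousand US$).
#' @return A tibble with one row per observed key combination and a summed
#'   measure column.
#' @export
aggregate_panel <- function(panel, keys, measure = c("quantity", "value")) {
  stopifnot(inherits(panel, "production_panel"))
  measure <- match.arg(measure)
  valid <- c("year", "country", "species", "environment", "group")
  if (length(keys) == 0 || !all(keys %in% valid)) {
    abort(sprintf("keys must be a non-empty subset of {%s}", paste(valid, collapse = ", ")),
          class = "aquapanel_domain_error")
  }
  if (!measure %in% names(panel$records)) {
    abort(sprintf("panel has no '%s' column", measure),
          class = "aquapanel_capability_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(panel$records, dplyr::across(dplyr::all_of(keys))),
    !!measure := sum(.data[[measure]], na.rm = TRUE),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
}
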