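#' Persistence of an entity
#'
#' Number of distinct years in which the entity (a species, or a country
#' farming anything) had strictly positive total production. Gap years do
#' not count, so persistence can be smaller than the first-to-last span;
#' `mode = "span"` returns that span instead.
#'
#' @param panel A `production_panel`.
#' @param entity Species or country label.
#' @param axis `"species"` or `"country"`.
#' @param mode `"years"` (count of producing years, default) or `"span"`
#'   (last producing year - first producing year + 1).
#' @return Integer count of years (0 when the entity only has zero or
#'   missing quantities).
#' @export
persistence <- function(panel, entity, axis = c("species", "country"),
                        mode = c("years", "span")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  recs <- lookup_entity(panel, entity, axis)
  totals <- tapply(recs$quantity, recs$year, sum, na.rm = TRUE)
  yrs <- as.integer(names(totals))[!is.na(totals) & totals > 0]
  if (length(yrs) == 0) return(0L)
  if (mode == "years") length(yrs) else max(yrs) - min(yrs) + 1L
}

lookup_entity <- function(panel, entity, axis) {
  stopifnot(inherits(panel, "production_panel"))
  recs <- panel$records[panel$records[[axis]] == entity, , drop = FALSE]
  if (nrow(recs) == 0) {
    abort(sprintf("unknown %s: '%s'", axis, entity), class = "aquapanel_lookup_error")
  }
  recs
}

#' Annual country counts for a species (diffusiveness)
#'
#' For each year of the panel's span, the number of countries with strictly
#' positive production of the species; years without records count 0. The
#' cumulative-ever country count is attached as attribute `C_ever`.
#'
#' @param panel A `production_panel`.
#' @param species Species label.
#' @return A tibble with columns `year` and `n_countries` covering the full
#'   panel year range, with `attr(, "C_ever")` the number of distinct
#'   countries that ever produced the species.
#' @export
diffusiveness_series <- function(panel, species) {
  recs <- lookup_entity(panel, species, "species")
  recs <- recs[!is.na(recs$quantity) & recs$quantity > 0, , drop = FALSE]
  span <- panel_years(panel)
  years <- if (length(span)) seq(min(span), max(span)) else integer(0)
  counts <- vapply(years, function(y) {
    length(unique(recs$country[recs$year == y]))
  }, integer(1))
  out <- tibble(year = years, n_countries = counts)
  attr(out, "C_ever") <- length(unique(recs$country))
  out
}

#' Geographical Expansion Rate
#'
#' Year-over-year percent change of a species' country count, averaged over
#' a trailing window (default the last 10 years). Positive values indicate
#' geographic expansion, negative values contraction. Rates whose previous
#' count is zero are undefined and skipped; if no valid rate falls in the
#' window the result is `NA` with a warning.
#'
#' @param counts Either the tibble from [diffusiveness_series()] or a
#'   numeric vector of annual counts (assumed consecutive years).
#' @param window Number of trailing years of rates to average.
#' @param method `"arithmetic"` (mean of percent changes, default) or
#'   `"geometric"` (annualised compound change over the window).
#' @return GER in percent per year.
#' @export
geographical_expansion_rate <- function(counts, window = 10,
                                        method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (is.data.frame(counts)) {
    years <- counts$year
    c_t <- counts$n_countries
  } else {
    c_t <- as.numeric(counts)
    years <- seq_along(c_t)
  }
  if (length(c_t) < 2) {
    abort("need at least 2 years of counts", class = "aquapanel_domain_error")
  }
  prev <- c_t[-length(c_t)]
  rate <- 100 * (c_t[-1] - prev) / prev
  rate[prev == 0] <- NA_real_
  rate_year <- years[-1]
  in_window <- rate_year > max(rate_year) - window
  valid <- in_window & !is.na(rate)
  if (!any(valid)) {
    warn("no valid expansion rate in the window; GER undefined")
    return(NA_real_)
  }
  if (method == "arithmetic") {
    mean(rate[valid])
  } else {
    100 * (exp(mean(log(1 + rate[valid] / 100))) - 1)
  }
}

#' Persistence/diffusiveness quadrant classification
#'
#' Classifies entities on the two axes the expansion analysis uses: years of
#' farming (persistence) and number of farming countries (diffusiveness).
#' Cuts are strict (`> cut`), defaulting to more than 60 years and more than
#' 20 countries.
#'
#' @param persistence,diffusiveness Numeric vectors, recycled.
#' @param persistence_cut,diffusiveness_cut Strict thresholds.
#' @return Character vector with values `core_widespread` (old and
#'   widespread), `core_localized` (old, few countries), `emergent` (recent
#'   but already widespread) and `transient` (recent, localized).
#' @export
classify_quadrant <- function(persistence, diffusiveness,
                              persistence_cut = 60, diffusiveness_cut = 20) {
  n <- max(length(persistence), length(diffusiveness))
  persistence <- rep_len(persistence, n)
  diffusiveness <- rep_len(diffusiveness, n)
  old <- persistence > persistence_cut
  wide <- diffusiveness > diffusiveness_cut
  dplyr::case_when(
    old & wide ~ "core_widespread",
    old & !wide ~ "core_localized",
    !old & wide ~ "emergent",
    .default = "transient"
  )
}

#' Geographic/temporal profiles for every entity of a panel
#'
#' Convenience wrapper computing, per species (or per country), the
#' cumulative volume, persistence, ever-diffusiveness, trailing-window GER
#' and quadrant class.
#'
#' @param panel A `production_panel`.
#' @param axis `"species"` or `"country"`.
#' @param window Trailing window (years) for the GER.
#' @inheritParams classify_quadrant
#' @return A tibble with one row per entity, sorted by cumulative volume.
#' @export
geo_profiles <- function(panel, axis = c("species", "country"), window = 10,
                         persistence_cut = 60, diffusiveness_cut = 20) {
  axis <- match.arg(axis)
  stopifnot(inherits(panel, "production_panel"))
  entities <- sort(unique(panel$records[[axis]]))
  rows <- lapply(entities, function(e) {
    recs <- panel$records[panel$records[[axis]] == e, , drop = FALSE]
    pers <- persistence(panel, e, axis)
    if (axis == "species") {
      ds <- diffusiveness_series(panel, e)
      dif <- attr(ds, "C_ever")
      ger <- tryCatch(
        suppressWarnings(geographical_expansion_rate(ds, window)),
        aquapanel_domain_error = function(e) NA_real_
      )
    } else {
      dif <- NA_integer_
      ger <- NA_real_
    }
    tibble(
      entity = e,
      cumulative_volume = sum(recs$quantity, na.rm = TRUE),
      persistence = pers,
      diffusiveness_ever = dif,
      GER = ger,
      quadrant = if (axis == "species") {
        classify_quadrant(pers, dif, persistence_cut, diffusiveness_cut)
      } else NA_character_
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$cumulative_volume))
}

#' Relative productivity per country
#'
#' Production (or value) summed over the trailing window, divided by the
#' country's area: tonnes (or thousand US$) per square kilometre. Every
#' producing country in the window must appear in the area table.
#'
#' @param panel A `production_panel`.
#' @param areas Either a named numeric vector (`country = km2`) or a
#'   two-column data frame `country`, `km2`.
#' @param window Number of trailing calendar years to include (default 5).
#' @param measure `"quantity"` or `"value"`.
#' @return A tibble `country`, `total`, `km2`, `productivity`, sorted by
#'   productivity, descending.
#' @export
relative_productivity <- function(panel, areas, window = 5,
                                  measure = c("quantity", "value")) {
  measure <- match.arg(measure)
  stopifnot(inherits(panel, "production_panel"))
  if (is.data.frame(areas)) {
    areas <- stats::setNames(as.numeric(areas$km2), areas$country)
  }
  yrs <- panel_years(panel)
  if (length(yrs) == 0) abort("panel is empty", class = "aquapanel_domain_error")
  keep <- panel$records$year > max(yrs) - window
  recs <- panel$records[keep, , drop = FALSE]
  totals <- aggregate_panel(
    production_panel(recs, provenance = "window"), keys = "country", measure = measure
  )
  missing <- setdiff(totals$country, names(areas))
  if (length(missing) > 0) {
    abort(sprintf("no area for country: %s", paste(missing, collapse = ", ")),
          class = "aquapanel_lookup_error")
  }
  out <- tibble(
    country = totals$country,
    total = totals[[measure]],
    km2 = unname(areas[totals$country]),
    productivity = totals[[measure]] / unname(areas[totals$country])
  )
  dplyr::arrange(out, dplyr::desc(.data$productivity))
}
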