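#' Read a tidy production CSV
#'
#' Reads the package's tidy schema: columns `year`, `country`, `species`,
#' `quantity` (or `quantity_t`), and optionally `environment`, `group`,
#' `value` (or `value_kusd`). Extra columns are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @param strict Passed to [production_panel()]: reject rather than sum
#'   duplicated keys.
#' @param country_filter Optional character vector; when given, only records
#'   whose country is in the vector are kept (e.g. to restrict a basin-wide
#'   extract to the riparian countries of interest).
#' @param species_aliases Optional named character vector mapping raw species
#'   labels to canonical ones (`c("raw label" = "canonical")`), applied
#'   before validation.
#' @return A [production_panel()].
#' @export
read_tidy_panel <- function(path, strict = FALSE, country_filter = NULL,
                            species_aliases = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "aquapanel_io_error")
  }
  # base strtod parsing keeps quantities bitwise-exact on a write/read round trip
  raw <- as_tibble(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
  names(raw) <- tolower(names(raw))
  if ("quantity_t" %in% names(raw) && !"quantity" %in% names(raw)) {
    names(raw)[names(raw) == "quantity_t"] <- "quantity"
  }
  if ("value_kusd" %in% names(raw) && !"value" %in% names(raw)) {
    names(raw)[names(raw) == "value_kusd"] <- "value"
  }
  required <- c("year", "country", "species", "quantity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("malformed header in %s: missing column(s) %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "aquapanel_format_error")
  }
  known <- c(required, "environment", "group", "value")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warn(sprintf("ignoring unrecognised column(s): %s", paste(extra, collapse = ", ")))
    raw <- raw[setdiff(names(raw), extra)]
  }
  if (!is.null(species_aliases)) {
    hit <- raw$species %in% names(species_aliases)
    raw$species[hit] <- unname(species_aliases[raw$species[hit]])
  }
  if (!is.null(country_filter)) {
    raw <- raw[raw$country %in% country_filter, , drop = FALSE]
  }
  production_panel(raw, provenance = sprintf("tidy CSV: %s", path), strict = strict)
}

#' Write a panel in the tidy schema
#'
#' Emits columns `year,country,species,environment,group,quantity_t` and,
#' when present, `value_kusd`. Quantities are written with full double
#' precision so that a write/read round trip reproduces them exactly.
#'
#' @param panel A `production_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tidy_panel <- function(panel, path) {
  stopifnot(inherits(panel, "production_panel"))
  out <- panel$records
  names(out)[names(out) == "quantity"] <- "quantity_t"
  if ("value" %in% names(out)) names(out)[names(out) == "value"] <- "value_kusd"
  out <- out[c("year", "country", "species", "environment", "group",
               intersect(c("quantity_t", "value_kusd"), names(out)))]
  for (col in intersect(c("quantity_t", "value_kusd"), names(out))) {
    # %.17g guarantees the printed decimal reads back to the same double
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.17g", out[[col]]))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a FishStatJ-style wide CSV export
#'
#' FAO FishStatJ exports one row per (country, species, environment) series
#' with one column per calendar year. Cells use sentinel conventions:
#' `"..."` or an empty cell means the datum is missing, `"-"` means a true
#' zero, and a trailing whitespace-separated single-letter flag (such as
#' `F` for a FAO estimate or `E` for an official estimate) annotates an
#' otherwise numeric cell. Flags are stripped before parsing and the flagged
#' cells are reported via a message and retained in the `flags` attribute of
#' the returned panel.
#'
#' @param path Path to the wide CSV. Descriptor columns are recognised by
#'   name (case-insensitive match on "country", "species", "environment");
#'   year columns by a 4-digit name in 1900-2100.
#' @param strict Passed to [production_panel()].
#' @return A [production_panel()] with missing cells carried as `NA`
#'   quantities.
#' @export
read_fishstat_wide <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "aquapanel_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  lower <- tolower(names(raw))
  year_idx <- grepl("^[0-9]{4}$", names(raw)) &
    suppressWarnings(as.integer(names(raw))) >= 1900 &
    suppressWarnings(as.integer(names(raw))) <= 2100
  find_desc <- function(key) {
    i <- which(grepl(key, lower) & !year_idx)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  ci <- find_desc("country")
  si <- find_desc("species")
  ei <- find_desc("environment")
  if (is.na(ci) || is.na(si)) {
    abort("wide export needs descriptor columns matching 'country' and 'species'",
          class = "aquapanel_format_error")
  }
  if (!any(year_idx)) {
    abort("wide export has no 4-digit year columns", class = "aquapanel_format_error")
  }
  years <- as.integer(names(raw)[year_idx])

  long <- tidyr::pivot_longer(
    dplyr::mutate(raw, .row = dplyr::row_number()),
    cols = dplyr::all_of(names(raw)[year_idx]),
    names_to = "year", values_to = "cell"
  )
  long$year <- as.integer(long$year)
  cell <- trimws(ifelse(is.na(long$cell), "", long$cell))

  quantity <- rep(NA_real_, length(cell))
  flag <- rep(NA_character_, length(cell))

  is_missing <- cell %in% c("", "...")
  is_zero <- cell == "-"
  quantity[is_zero] <- 0

  todo <- !(is_missing | is_zero)
  body <- cell
  has_flag <- grepl("\\s+[A-Za-z]$", cell) & todo
  flag[has_flag] <- trimws(sub("^.*\\s+([A-Za-z])$", "\\1", cell[has_flag]))
  body[has_flag] <- trimws(sub("\\s+[A-Za-z]$", "", cell[has_flag]))

  parsed <- suppressWarnings(as.numeric(gsub(" ", "", body[todo])))
  bad <- which(is.na(parsed))
  if (length(bad) > 0) {
    b <- which(todo)[bad[1]]
    abort(sprintf("non-numeric cell '%s' at data row %d, year column %d",
                  cell[b], long$.row[b], long$year[b]),
          class = "aquapanel_parse_error")
  }
  quantity[todo] <- parsed

  records <- tibble(
    year = long$year,
    country = long[[names(raw)[ci]]],
    species = long[[names(raw)[si]]],
    environment = if (!is.na(ei)) long[[names(raw)[ei]]] else "unknown",
    quantity = quantity
  )
  flags <- tibble(
    year = long$year[has_flag],
    country = records$country[has_flag],
    species = records$species[has_flag],
    flag = flag[has_flag],
    quantity = quantity[has_flag]
  )
  panel <- production_panel(records,
                            provenance = sprintf("FishStatJ wide CSV: %s", path),
                            strict = strict)
  if (nrow(flags) > 0) {
    inform(sprintf("%d flagged (estimated) cell(s) parsed; see attr(panel, 'flags')",
                   nrow(flags)))
    attr(panel, "flags") <- flags
  }
  panel
}
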