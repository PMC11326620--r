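#' Shannon diversity of one year's production
#'
#' Treats each entity's share of the annual volume as a proportion `p_i` and
#' returns `H = -sum(p_i * log(p_i))` in nats, together with the richness
#' `S` (entities with strictly positive production; zero-volume entities are
#' excluded from both `S` and `p`).
#'
#' @param volumes Non-negative production quantities (tonnes), optionally
#'   named by entity.
#' @return A list of class `diversity_result` with elements `H`, `S` and `p`
#'   (shares of the retained entities, summing to 1).
#' @export
shannon_index <- function(volumes) {
  volumes <- check_volumes(volumes)
  pos <- volumes[volumes > 0]
  p <- pos / sum(pos)
  structure(
    list(H = -sum(p * log(p)), S = length(p), p = p),
    class = "diversity_result"
  )
}

check_volumes <- function(volumes) {
  volumes <- volumes[!is.na(volumes)]
  if (length(volumes) == 0 || all(volumes == 0)) {
    abort("need at least one strictly positive volume", class = "aquapanel_domain_error")
  }
  if (any(volumes < 0)) {
    abort("volumes must be non-negative", class = "aquapanel_domain_error")
  }
  volumes
}

#' Pareto dominance decomposition of one year's production
#'
#' Partitions the entities producing in a year into *dominant*, *relevant*
#' and *minor* classes. Entities are sorted by volume, descending (ties
#' broken by label so the partition is deterministic). The relevant set is
#' the smallest prefix whose cumulative share reaches `relevant_share` of
#' the annual total (default 99%); the dominant set is the smallest prefix
#' reaching `dominant_share` (default 80%); minor entities are everything
#' outside the relevant set. The Pareto index is the dominant count as a
#' percentage of the relevant count: low values mean production is
#' concentrated in very few of the species (or countries) that matter.
#'
#' By default the dominant prefix is measured against the annual total.
#' `dominant_base = "relevant"` instead measures it against the relevant
#' subset's subtotal.
#'
#' @param volumes Non-negative quantities, named by entity (unnamed vectors
#'   get positional labels).
#' @param relevant_share,dominant_share Cumulative-share thresholds with
#'   `0 < dominant_share < relevant_share <= 1`.
#' @param dominant_base `"total"` or `"relevant"`.
#' @return A list of class `dominance_decomposition`: counts `total`,
#'   `relevant`, `dominant`, `minor`, the `pareto_index` in percent, the
#'   thresholds, and the entity labels of each class.
#' @export
dominance_decompose <- function(volumes, relevant_share = 0.99,
                                dominant_share = 0.80,
                                dominant_base = c("total", "relevant")) {
  dominant_base <- match.arg(dominant_base)
  if (!(dominant_share > 0 && dominant_share < relevant_share && relevant_share <= 1)) {
    abort("thresholds need 0 < dominant_share < relevant_share <= 1",
          class = "aquapanel_domain_error")
  }
  if (is.null(names(volumes))) {
    names(volumes) <- sprintf("entity_%03d", seq_along(volumes))
  }
  volumes <- check_volumes(volumes)
  pos <- volumes[volumes > 0]
  ord <- order(-pos, names(pos))
  pos <- pos[ord]
  total_volume <- sum(pos)
  cum <- cumsum(pos)
  eps <- 1e-9 * total_volume

  n_relevant <- unname(which(cum >= relevant_share * total_volume - eps)[1])
  base <- unname(if (dominant_base == "total") total_volume else cum[n_relevant])
  n_dominant <- unname(which(cum >= dominant_share * base - eps)[1])

  structure(list(
    total = length(pos),
    relevant = n_relevant,
    dominant = n_dominant,
    minor = length(pos) - n_relevant,
    pareto_index = 100 * n_dominant / n_relevant,
    thresholds = c(relevant_share = relevant_share, dominant_share = dominant_share),
    dominant_entities = names(pos)[seq_len(n_dominant)],
    relevant_entities = names(pos)[seq_len(n_relevant)],
    minor_entities = if (n_relevant < length(pos)) {
      names(pos)[seq(n_relevant + 1, length(pos))]
    } else character(0)
  ), class = "dominance_decomposition")
}

#' @export
print.dominance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<dominance_decomposition> total %d | relevant %d | dominant %d | minor %d | Pareto index %.1f%%\n",
    x$total, x$relevant, x$dominant, x$minor, x$pareto_index))
  invisible(x)
}

#' Per-year Pareto decomposition of a panel
#'
#' Aggregates annual volumes over the chosen axis (species or country) and
#' applies [dominance_decompose()] year by year. Years with no positive
#' production are omitted.
#'
#' @param panel A `production_panel`.
#' @param axis `"species"` or `"country"`.
#' @inheritParams dominance_decompose
#' @return A tibble with one row per year: `year`, `total`, `relevant`,
#'   `dominant`, `minor`, `pareto_index`.
#' @export
pareto_series <- function(panel, axis = c("species", "country"),
                          relevant_share = 0.99, dominant_share = 0.80,
                          dominant_base = c("total", "relevant")) {
  axis <- match.arg(axis)
  dominant_base <- match.arg(dominant_base)
  per_year <- annual_axis_volumes(panel, axis)
  rows <- lapply(per_year, function(df) {
    v <- stats::setNames(df$quantity, df[[axis]])
    if (all(is.na(v)) || sum(v, na.rm = TRUE) <= 0) return(NULL)
    d <- dominance_decompose(v, relevant_share, dominant_share, dominant_base)
    tibble(year = df$year[1], total = d$total, relevant = d$relevant,
           dominant = d$dominant, minor = d$minor, pareto_index = d$pareto_index)
  })
  dplyr::bind_rows(rows)
}

#' Per-year Shannon diversity of a panel
#'
#' @inheritParams pareto_series
#' @return A tibble with one row per year holding richness `S` and Shannon
#'   `H` (nats) on the chosen axis; years without positive production are
#'   omitted.
#' @export
diversity_series <- function(panel, axis = c("species", "country")) {
  axis <- match.arg(axis)
  per_year <- annual_axis_volumes(panel, axis)
  rows <- lapply(per_year, function(df) {
    v <- df$quantity
    if (all(is.na(v)) || sum(v, na.rm = TRUE) <= 0) return(NULL)
    d <- shannon_index(v)
    tibble(year = df$year[1], S = d$S, H = d$H)
  })
  dplyr::bind_rows(rows)
}

annual_axis_volumes <- function(panel, axis) {
  stopifnot(inherits(panel, "production_panel"))
  if (nrow(panel$records) == 0) {
    abort("panel is empty", class = "aquapanel_domain_error")
  }
  agg <- aggregate_panel(panel, keys = c("year", axis), measure = "quantity")
  split(agg, agg$year)
}
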