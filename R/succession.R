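#' Species-by-year production matrix
#'
#' The substrate of the succession analysis: one row per species (or
#' country), one column per year of the panel's full span, each cell the
#' total production of that entity in that year. Combinations without
#' records are filled with `fill` (default 0).
#'
#' @param panel A `production_panel`.
#' @param rows Optional subset of row labels (unknown labels are an error).
#' @param fill Value for absent (entity, year) cells.
#' @param axis `"species"` or `"country"`.
#' @return A numeric matrix of class `succession_matrix` with entity row
#'   names and year column names; `attr(, "scaled")` is `FALSE`.
#' @export
species_year_matrix <- function(panel, rows = NULL, fill = 0,
                                axis = c("species", "country")) {
  axis <- match.arg(axis)
  stopifnot(inherits(panel, "production_panel"))
  if (nrow(panel$records) == 0) {
    abort("panel is empty", class = "aquapanel_domain_error")
  }
  agg <- aggregate_panel(panel, keys = c(axis, "year"), measure = "quantity")
  entities <- sort(unique(agg[[axis]]))
  if (!is.null(rows)) {
    unknown <- setdiff(rows, entities)
    if (length(unknown) > 0) {
      abort(sprintf("unknown row label(s): %s", paste(unknown, collapse = ", ")),
            class = "aquapanel_lookup_error")
    }
    entities <- rows
  }
  years <- seq(min(agg$year), max(agg$year))
  m <- matrix(fill, nrow = length(entities), ncol = length(years),
              dimnames = list(entities, years))
  keep <- agg[[axis]] %in% entities
  m[cbind(match(agg[[axis]][keep], entities), match(agg$year[keep], years))] <-
    agg$quantity[keep]
  structure(m, class = c("succession_matrix", class(m)), scaled = FALSE)
}

#' Z-scale matrix rows
#'
#' Standardises each row to `(x - mean) / sd` using the row's own mean and
#' sample standard deviation, so every species' trajectory is expressed in
#' units of its own variability and small and large producers become
#' comparable on one heatmap. Constant rows (sd 0) map to all zeros.
#' Re-scaling an already scaled matrix is an error.
#'
#' @param matrix An unscaled `succession_matrix` (or plain numeric matrix).
#' @return The scaled matrix, with `attr(, "scaled") = TRUE` and
#'   `attr(, "row_stats")`: a tibble of each row's original mean and sd.
#' @export
zscale_rows <- function(matrix) {
  if (isTRUE(attr(matrix, "scaled"))) {
    abort("matrix is already scaled", class = "aquapanel_domain_error")
  }
  mu <- rowMeans(matrix)
  sd <- apply(matrix, 1, stats::sd)
  scaled <- (matrix - mu) / ifelse(sd > 0, sd, 1)
  scaled[sd == 0, ] <- 0
  structure(scaled,
            class = unique(c("succession_matrix", class(scaled))),
            scaled = TRUE,
            row_stats = tibble(row = rownames(matrix), mean = unname(mu), sd = unname(sd)))
}

#' Hierarchical clustering of matrix rows
#'
#' Agglomerative clustering of entity trajectories with Euclidean row
#' distances, using Ward linkage (the squared-distance "ward.D2"
#' convention) or centroid linkage. Ward merge heights are non-decreasing;
#' centroid linkage can show inversions, as usual.
#'
#' @param matrix A `succession_matrix` (raw or scaled) or numeric matrix
#'   with at least 2 rows.
#' @param metric Only `"euclidean"` is supported.
#' @param linkage `"ward"` or `"centroid"`.
#' @return An `hclust` object (subclass `succession_clust`) whose `merge`,
#'   `height` and `order` elements give the merge sequence and the heatmap
#'   leaf order.
#' @export
cluster_rows <- function(matrix, metric = "euclidean",
                         linkage = c("ward", "centroid")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric, "euclidean")
  if (nrow(matrix) < 2) {
    abort("need at least 2 rows to cluster", class = "aquapanel_domain_error")
  }
  d <- stats::dist(unclass(matrix), method = "euclidean")
  hc <- if (linkage == "ward") {
    stats::hclust(d, method = "ward.D2")
  } else {
    # stats::hclust expects squared Euclidean distances for centroid linkage
    h <- stats::hclust(d^2, method = "centroid")
    h$height <- sqrt(pmax(h$height, 0))
    h
  }
  hc$call <- NULL
  class(hc) <- c("succession_clust", "hclust")
  attr(hc, "linkage") <- linkage
  hc
}

#' Export a row dendrogram as Newick
#'
#' @param clust A `succession_clust`/`hclust` object.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
dendrogram_newick <- function(clust, file = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(clust))
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Dominant entity per year
#'
#' For each year (column) of a raw production matrix, the entity with the
#' largest production and its share of that year's total. Ties go to the
#' lexicographically smallest label; all-zero years are labelled `"none"`.
#' Consecutive runs of the same dominant entity — the succession phases that
#' structure the basin's history (for example carp, then trout and mussels,
#' then tilapia with sea bass and sea bream) — are available via
#' [dominance_phases()].
#'
#' @param matrix An unscaled `succession_matrix`.
#' @return A tibble `year`, `label`, `share`.
#' @export
dominant_per_year <- function(matrix) {
  if (isTRUE(attr(matrix, "scaled"))) {
    abort("dominance requires the raw (unscaled) matrix", class = "aquapanel_domain_error")
  }
  lab <- rownames(matrix)
  ord <- order(lab)
  rows <- lapply(seq_len(ncol(matrix)), function(j) {
    col <- matrix[ord, j]
    total <- sum(col)
    if (all(col <= 0) || total <= 0) {
      return(tibble(year = as.integer(colnames(matrix)[j]),
                    label = "none", share = NA_real_))
    }
    i <- which.max(col)  # first max in label order
    tibble(year = as.integer(colnames(matrix)[j]),
           label = lab[ord][i], share = unname(col[i] / total))
  })
  dplyr::bind_rows(rows)
}

#' Succession phases from the dominance timeline
#'
#' @param dominant The tibble from [dominant_per_year()].
#' @return A tibble `start`, `end`, `label`, one row per maximal run of
#'   consecutive years with the same dominant entity.
#' @export
dominance_phases <- function(dominant) {
  r <- rle(dominant$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(
    start = dominant$year[starts],
    end = dominant$year[ends],
    label = r$values
  )
}
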