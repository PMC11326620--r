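#' Construct an annual series
#'
#' @param years Strictly increasing integer years.
#' @param values Numeric values of equal length (tonnes, US$, kg/person or a
#'   dimensionless ratio).
#' @param label Free-text label.
#' @return A tibble of class `annual_series` with columns `year`, `value`.
#' @export
annual_series <- function(years, values, label = "") {
  years <- as.integer(years)
  if (length(years) != length(values)) {
    abort("years and values must have equal length", class = "aquapanel_domain_error")
  }
  if (length(years) > 1 && any(diff(years) <= 0)) {
    abort("years must be strictly increasing", class = "aquapanel_domain_error")
  }
  out <- tibble(year = years, value = as.numeric(values))
  attr(out, "label") <- label
  class(out) <- c("annual_series", class(out))
  out
}

as_annual_series <- function(x, label = "") {
  if (inherits(x, "annual_series")) return(x)
  if (is.data.frame(x)) {
    value_col <- setdiff(names(x), "year")[1]
    return(annual_series(x$year, x[[value_col]], label))
  }
  abort("cannot interpret object as an annual series", class = "aquapanel_domain_error")
}

#' Extract an annual series from a panel
#'
#' @param panel A `production_panel`.
#' @param what `"total"` for the basin-wide annual total, or a single
#'   species/country selected via `species =` / `country =`.
#' @param species,country Optional labels restricting the series.
#' @param measure `"quantity"` or `"value"`.
#' @return An [annual_series()].
#' @export
panel_series <- function(panel, what = "total", species = NULL, country = NULL,
                         measure = c("quantity", "value")) {
  measure <- match.arg(measure)
  stopifnot(inherits(panel, "production_panel"))
  recs <- panel$records
  label <- "total"
  if (!is.null(species)) {
    recs <- recs[recs$species == species, , drop = FALSE]
    label <- species
  }
  if (!is.null(country)) {
    recs <- recs[recs$country == country, , drop = FALSE]
    label <- paste(label, country)
  }
  if (nrow(recs) == 0) {
    abort("no records match the selection", class = "aquapanel_lookup_error")
  }
  agg <- aggregate_panel(production_panel(recs, "selection"), "year", measure)
  annual_series(agg$year, agg[[measure]], label)
}

#' Fit a trend model to an annual series
#'
#' Least-squares trend fits of the kinds used for long-run production
#' series: a straight line, a polynomial of chosen degree, or an exponential
#' (a log-linear fit, requiring positive values). Years are centred at
#' `x_origin` (default: first fitted year) before fitting, so high
#' polynomial powers of calendar years stay well-conditioned.
#'
#' @param series An [annual_series()] (or a data frame with `year` and one
#'   value column).
#' @param kind `"linear"`, `"polynomial"` or `"exponential"`.
#' @param degree Polynomial degree (>= 1); ignored for the other kinds.
#' @param x_origin Year subtracted from calendar years before fitting.
#' @param window Optional `(start, end)` years restricting the fit.
#' @return A `trend_model`: coefficients in descending-power order for
#'   linear/polynomial kinds (so a linear fit is `c(slope, intercept)`), or
#'   `c(rate, scale)` for the exponential kind `scale * exp(rate * x)`;
#'   plus `r2`, `pearson_r` (fitted vs observed on the original scale),
#'   `x_origin` and `fit_window`.
#' @export
fit_trend <- function(series, kind = c("linear", "polynomial", "exponential"),
                      degree = 2, x_origin = NULL, window = NULL) {
  kind <- match.arg(kind)
  series <- as_annual_series(series)
  if (!is.null(window)) {
    series <- series[series$year >= window[1] & series$year <= window[2], , drop = FALSE]
  }
  series <- series[!is.na(series$value), , drop = FALSE]
  degree <- if (kind == "linear") 1L else as.integer(degree)
  if (kind != "exponential" && degree < 1) {
    abort("degree must be >= 1", class = "aquapanel_domain_error")
  }
  n_min <- if (kind == "exponential") 3L else degree + 2L
  if (nrow(series) < n_min) {
    abort(sprintf("need at least %d points for this fit", n_min),
          class = "aquapanel_domain_error")
  }
  if (is.null(x_origin)) x_origin <- min(series$year)
  x <- series$year - x_origin
  y <- series$value

  if (kind == "exponential") {
    if (any(y <= 0)) {
      abort("exponential fit requires strictly positive values",
            class = "aquapanel_domain_error")
    }
    fit <- stats::lm(log(y) ~ x)
    co <- stats::coef(fit)
    coefficients <- c(rate = unname(co[2]), scale = exp(unname(co[1])))
    fitted_orig <- exp(stats::fitted(fit))
    r2 <- exact_safe_r2(fit)
  } else {
    fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    coefficients <- rev(unname(co))  # descending powers: a_d, ..., a_1, a_0
    names(coefficients) <- paste0("x^", seq(degree, 0))
    fitted_orig <- unname(stats::fitted(fit))
    r2 <- exact_safe_r2(fit)
  }
  pearson_r <- if (stats::sd(y) > 0 && stats::sd(fitted_orig) > 0) {
    stats::cor(fitted_orig, y)
  } else NA_real_

  structure(list(
    kind = kind,
    degree = if (kind == "exponential") NA_integer_ else degree,
    coefficients = coefficients,
    r2 = r2,
    pearson_r = pearson_r,
    x_origin = x_origin,
    fit_window = range(series$year),
    n = nrow(series)
  ), class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("<trend_model> %s (fit %d-%d, origin %d)\n",
              x$kind, x$fit_window[1], x$fit_window[2], x$x_origin))
  print(round(x$coefficients, 6))
  cat(sprintf("  R^2 = %.4f | Pearson r = %.4f\n", x$r2, x$pearson_r))
  invisible(x)
}

# summary.lm warns on numerically exact fits; an exact fit is a legitimate
# input here (noise-free trajectories), so muffle that specific warning.
exact_safe_r2 <- function(fit) {
  withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Evaluate / extrapolate a fitted trend
#'
#' Evaluates the model at the requested years (centred at the model's
#' `x_origin`); at observed years this equals the fitted value. A warning is
#' issued when extrapolating beyond the fitted window; values are never
#' clamped.
#'
#' @param model A `trend_model` from [fit_trend()].
#' @param year Integer year(s).
#' @return Numeric vector of predictions.
#' @export
forecast <- function(model, year) {
  stopifnot(inherits(model, "trend_model"))
  x <- year - model$x_origin
  if (any(year < model$fit_window[1] | year > model$fit_window[2])) {
    warn(sprintf("extrapolating beyond the fitted window %d-%d",
                 model$fit_window[1], model$fit_window[2]))
  }
  if (model$kind == "exponential") {
    unname(model$coefficients["scale"] * exp(model$coefficients["rate"] * x))
  } else {
    co <- model$coefficients  # descending powers
    vapply(x, function(xi) sum(co * xi^seq(length(co) - 1, 0)), numeric(1))
  }
}

#' Year-over-year growth rates
#'
#' @param series An [annual_series()].
#' @return An [annual_series()] of percent changes
#'   `100 * (v_t - v_[t-1]) / v_[t-1]`, one entry per consecutive-year pair;
#'   pairs whose earlier value is zero are skipped.
#' @export
growth_rate_series <- function(series) {
  series <- as_annual_series(series)
  if (nrow(series) < 2) {
    abort("need at least 2 years", class = "aquapanel_domain_error")
  }
  prev <- series$value[-nrow(series)]
  rate <- 100 * (series$value[-1] - prev) / prev
  yr <- series$year[-1]
  keep <- !is.na(rate) & prev != 0
  annual_series(yr[keep], rate[keep],
                paste0("growth rate of ", attr(series, "label")))
}

#' Mean annual growth rate
#'
#' Averages growth over the trailing `window` calendar years of the series,
#' either as the arithmetic mean of year-over-year percent changes or as the
#' compound annual growth rate
#' `100 * ((v_end / v_start)^(1 / (year_end - year_start)) - 1)`.
#'
#' @param series An [annual_series()].
#' @param window Trailing number of calendar years to include (`NULL` = all).
#' @param method `"arithmetic"` or `"cagr"`.
#' @return Percent per year.
#' @export
mean_growth_rate <- function(series, window = NULL,
                             method = c("arithmetic", "cagr")) {
  method <- match.arg(method)
  series <- as_annual_series(series)
  if (!is.null(window)) {
    series <- series[series$year > max(series$year) - window, , drop = FALSE]
  }
  if (nrow(series) < 2) {
    abort("window must contain at least 2 years of data", class = "aquapanel_domain_error")
  }
  if (method == "arithmetic") {
    mean(growth_rate_series(series)$value)
  } else {
    v0 <- series$value[1]
    v1 <- series$value[nrow(series)]
    gap <- series$year[nrow(series)] - series$year[1]
    if (v0 <= 0) {
      abort("CAGR needs a positive start value", class = "aquapanel_domain_error")
    }
    100 * ((v1 / v0)^(1 / gap) - 1)
  }
}

#' Carrying capacity as a long-run mean
#'
#' The long-run average of a capture-fishery landings series over a stated
#' window, interpreted as the ceiling of wild extraction against which
#' aquaculture growth is compared. Defaults to the 1985-2020 window.
#'
#' @param series An [annual_series()] of landings.
#' @param window Closed `(start, end)` year window.
#' @return Arithmetic mean of the values inside the window.
#' @export
carrying_capacity <- function(series, window = c(1985, 2020)) {
  series <- as_annual_series(series)
  keep <- series$year >= window[1] & series$year <= window[2] & !is.na(series$value)
  if (!any(keep)) {
    abort("window does not overlap the series", class = "aquapanel_domain_error")
  }
  mean(series$value[keep])
}

#' Element-wise ratio of two annual series
#'
#' @param numerator,denominator [annual_series()] objects; the ratio is
#'   taken on their year intersection. Years where the denominator is zero
#'   are skipped with a warning.
#' @return An [annual_series()] of ratios.
#' @export
ratio_series <- function(numerator, denominator) {
  numerator <- as_annual_series(numerator)
  denominator <- as_annual_series(denominator)
  yrs <- intersect(numerator$year, denominator$year)
  if (length(yrs) == 0) {
    abort("series have no overlapping years", class = "aquapanel_domain_error")
  }
  num <- numerator$value[match(yrs, numerator$year)]
  den <- denominator$value[match(yrs, denominator$year)]
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warn(sprintf("skipping %d year(s) with zero denominator", sum(zero)))
  }
  keep <- !zero & !is.na(num) & !is.na(den)
  annual_series(yrs[keep], num[keep] / den[keep],
                paste0(attr(numerator, "label"), " / ", attr(denominator, "label")))
}

#' Pearson correlation of two aligned series
#'
#' @param x,y [annual_series()] objects (aligned on their year intersection)
#'   or plain numeric vectors of equal length.
#' @return The product-moment correlation coefficient.
#' @export
pearson_cor <- function(x, y) {
  if (inherits(x, "annual_series") || is.data.frame(x)) {
    x <- as_annual_series(x); y <- as_annual_series(y)
    yrs <- intersect(x$year, y$year)
    xv <- x$value[match(yrs, x$year)]
    yv <- y$value[match(yrs, y$year)]
  } else {
    xv <- as.numeric(x); yv <- as.numeric(y)
  }
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) {
    abort("need at least 3 aligned points", class = "aquapanel_domain_error")
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    abort("zero variance; correlation undefined", class = "aquapanel_domain_error")
  }
  stats::cor(xv, yv)
}

#' Pairwise correlation matrix over entities
#'
#' Pairwise-complete Pearson correlations between indicator columns of an
#' entities-by-indicators table (for example countries against production,
#' persistence, diversity and socio-economic covariates). Pairs with fewer
#' than `min_pairs` complete observations are reported as `NA`. An exclusion
#' list drops outlier entities (the canonical use is excluding a single
#' dominant producer whose scale swamps every correlation).
#'
#' @param table A data frame; non-numeric columns identify entities (the
#'   first one is used for `exclude`), numeric columns are indicators.
#' @param exclude Entity labels to drop before correlating.
#' @param min_pairs Minimum complete pairs per correlation (default 3).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, exclude = NULL, min_pairs = 3) {
  table <- as.data.frame(table)
  is_num <- vapply(table, is.numeric, logical(1))
  if (!is.null(exclude)) {
    id <- which(!is_num)[1]
    if (!is.na(id)) table <- table[!(table[[id]] %in% exclude), , drop = FALSE]
  }
  m <- as.matrix(table[is_num])
  p <- ncol(m)
  if (p < 2) abort("need at least 2 numeric indicators", class = "aquapanel_domain_error")
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  diag(out) <- 1
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) >= min_pairs &&
          stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
        out[i, j] <- out[j, i] <- stats::cor(m[ok, i], m[ok, j])
      }
    }
  }
  out
}
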