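#' Read a pipeline run configuration
#'
#' Run configurations are plain YAML key-value files mirroring the pipeline
#' arguments: `input` (tidy CSV path) or `simulate: {n_species, n_countries,
#' years, noise_cv, ...}`, `analyses` (subset of diversity, expansion,
#' trends, succession), thresholds (`relevant_share`, `dominant_share`,
#' `persistence_cut`, `diffusiveness_cut`, `ger_window`,
#' `capacity_window`), `fit` (`kind`, `degree`, `forecast_year`), `seed`,
#' and `out_dir`.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "aquapanel_io_error")
  }
  run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config Named list of settings (as from YAML).
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    input = NULL,
    simulate = NULL,
    analyses = c("diversity", "expansion", "trends", "succession"),
    axis = "species",
    relevant_share = 0.99,
    dominant_share = 0.80,
    persistence_cut = 60,
    diffusiveness_cut = 20,
    ger_window = 10,
    capacity_window = c(1985, 2020),
    fit = list(kind = "polynomial", degree = 2, forecast_year = NULL),
    seed = 1L,
    out_dir = "."
  )
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$dominant_share > 0 && cfg$dominant_share < cfg$relevant_share &&
        cfg$relevant_share <= 1)) {
    abort("thresholds need 0 < dominant_share < relevant_share <= 1",
          class = "aquapanel_domain_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) abort("seed must be an integer", class = "aquapanel_domain_error")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a panel, runs the selected analysis stages with the
#' configured thresholds, writes each stage's tables as CSV/JSON under the
#' output directory, and records a machine-readable manifest
#' (`manifest.json`) with the package version, configuration, seed and input
#' checksums. Identical configuration and inputs give identical outputs.
#'
#' @param config A `run_config` (or plain list of settings).
#' @return Named list of written file paths, invisibly; the loaded panel and
#'   stage results are attached as attribute `results`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  results <- list()

  if (!is.null(config$input)) {
    panel <- read_tidy_panel(config$input)
    input_md5 <- unname(tools::md5sum(config$input))
  } else {
    sim <- config$simulate %||% list()
    sim$seed <- sim$seed %||% config$seed
    cfg <- do.call(synthetic_config, sim)
    panel <- generate_panel(cfg)
    files$panel <- file.path(config$out_dir, "panel.csv")
    write_tidy_panel(panel, files$panel)
    input_md5 <- NA_character_
  }
  results$panel <- panel

  if ("diversity" %in% config$analyses) {
    div <- dplyr::full_join(
      diversity_series(panel, config$axis),
      pareto_series(panel, config$axis,
                    relevant_share = config$relevant_share,
                    dominant_share = config$dominant_share),
      by = "year"
    )
    files$diversity <- file.path(config$out_dir, "diversity.csv")
    readr::write_csv(div, files$diversity, progress = FALSE)
    results$diversity <- div
  }

  if ("expansion" %in% config$analyses) {
    prof <- geo_profiles(panel, config$axis, window = config$ger_window,
                         persistence_cut = config$persistence_cut,
                         diffusiveness_cut = config$diffusiveness_cut)
    files$profiles <- file.path(config$out_dir, "profiles.csv")
    readr::write_csv(prof, files$profiles, progress = FALSE)
    results$profiles <- prof
  }

  if ("trends" %in% config$analyses) {
    total <- panel_series(panel, "total")
    model <- fit_trend(total, kind = config$fit$kind,
                       degree = config$fit$degree %||% 2)
    fy <- config$fit$forecast_year
    trend <- list(
      kind = model$kind,
      coefficients = as.list(model$coefficients),
      r2 = model$r2,
      pearson_r = model$pearson_r,
      x_origin = model$x_origin,
      fit_window = model$fit_window,
      growth_rate_last10 = tryCatch(
        mean_growth_rate(total, window = 10),
        aquapanel_domain_error = function(e) NA_real_
      ),
      long_run_mean = tryCatch(
        carrying_capacity(total, config$capacity_window),
        aquapanel_domain_error = function(e) NA_real_
      ),
      forecast = if (!is.null(fy)) {
        list(year = fy, value = suppressWarnings(forecast(model, fy)))
      }
    )
    files$trend <- file.path(config$out_dir, "trend.json")
    jsonlite::write_json(trend, files$trend, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    results$trend <- trend
  }

  if ("succession" %in% config$analyses) {
    m <- species_year_matrix(panel, axis = config$axis)
    files$matrix <- file.path(config$out_dir, "succession_matrix.csv")
    readr::write_csv(
      tibble::rownames_to_column(as.data.frame(unclass(m)), "entity"),
      files$matrix, progress = FALSE)
    dom <- dominant_per_year(m)
    files$phases <- file.path(config$out_dir, "phases.csv")
    readr::write_csv(dominance_phases(dom), files$phases, progress = FALSE)
    if (nrow(m) >= 2) {
      hc <- cluster_rows(zscale_rows(m), linkage = "ward")
      files$dendrogram <- file.path(config$out_dir, "dendrogram.nwk")
      dendrogram_newick(hc, files$dendrogram)
    }
    results$succession <- list(matrix = m, dominant = dom)
  }

  manifest <- list(
    package = "aquapanel",
    version = as.character(utils::packageVersion("aquapanel")),
    seed = config$seed,
    config = unclass(config),
    input_md5 = input_md5,
    outputs = lapply(files, basename)
  )
  files$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  out <- structure(files, results = results)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
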