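#' Configuration for the synthetic panel generator
#'
#' The generator emulates the statistical regularities of long-run
#' aquaculture production panels: a heavy-tailed species-share distribution
#' (a handful of species carrying most of the volume), per-species logistic
#' growth with staggered introduction years, a country-adoption process that
#' makes diffusiveness rise over time, and multiplicative log-normal noise.
#'
#' Defaults describe a Mediterranean-like basin: a 1950-2020 horizon, 15
#' species across 20 countries, geometric rank-abundance with decay 0.6
#' (so 3-4 species carry ~80% of the volume), a basin-wide carrying level
#' of 2.8 million tonnes shared among species, logistic growth at
#' 0.12 per year with the inflection 25 years after introduction,
#' introduction years staggered across the first 70% of the horizon, an
#' expected 0.5 newly adopting countries per species-year, and 5%
#' multiplicative noise.
#'
#' @param n_species,n_countries Entity counts (>= 1).
#' @param years Length-2 integer `(start, end)` horizon.
#' @param share_model `"geometric"` (shares proportional to `k^i`) or
#'   `"lognormal"` (shares from evenly spaced log-normal quantiles).
#' @param share_param Decay ratio `k` in (0,1) for geometric, log-sd
#'   `sigma > 0` for lognormal.
#' @param K_total Basin-wide carrying level in tonnes; each species' logistic
#'   ceiling is its share of `K_total` unless `K` is given.
#' @param K Optional per-species carrying levels (tonnes), recycled.
#' @param growth_rate Per-species logistic rate `r` (per year), recycled.
#' @param midpoint_offset Years from introduction to the logistic midpoint
#'   `t0`, recycled.
#' @param intro_years Optional per-species first farming years; default
#'   staggers them evenly over the first 70% of the horizon.
#' @param adoption_rate Expected newly adopting countries per year (> 0),
#'   recycled per species.
#' @param country_share_param Geometric decay of country weights among
#'   adopters (earlier adopters produce more).
#' @param noise_cv Coefficient of variation of the mean-one multiplicative
#'   log-normal noise (0 disables noise).
#' @param seed Integer seed; the generator derives independent sub-streams
#'   per species so adding a species does not perturb existing series.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 15, n_countries = 20,
                             years = c(1950L, 2020L),
                             share_model = c("geometric", "lognormal"),
                             share_param = 0.6,
                             K_total = 2.8e6, K = NULL,
                             growth_rate = 0.12, midpoint_offset = 25,
                             intro_years = NULL,
                             adoption_rate = 0.5,
                             country_share_param = 0.6,
                             noise_cv = 0.05, seed = 1L) {
  share_model <- match.arg(share_model)
  n_species <- as.integer(n_species)
  n_countries <- as.integer(n_countries)
  years <- as.integer(years)
  if (is.na(n_species) || n_species < 1 || is.na(n_countries) || n_countries < 1) {
    abort("n_species and n_countries must be >= 1", class = "aquapanel_domain_error")
  }
  if (length(years) != 2 || years[1] > years[2]) {
    abort("years must be (start, end) with start <= end", class = "aquapanel_domain_error")
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0", class = "aquapanel_domain_error")
  if (any(adoption_rate <= 0) || any(growth_rate <= 0)) {
    abort("rates must be > 0", class = "aquapanel_domain_error")
  }
  shares <- rank_abundance_shares(n_species, share_model, share_param)
  if (is.null(K)) K <- shares * K_total
  K <- rep_len(K, n_species)
  if (any(K <= 0)) abort("carrying levels must be > 0", class = "aquapanel_domain_error")
  if (is.null(intro_years)) {
    span <- years[2] - years[1]
    intro_years <- years[1] +
      floor((seq_len(n_species) - 1) * 0.7 * span / max(1, n_species - 1))
  }
  intro_years <- as.integer(rep_len(intro_years, n_species))

  structure(list(
    n_species = n_species, n_countries = n_countries, years = years,
    share_model = share_model, share_param = share_param,
    shares = shares, K = K,
    growth_rate = rep_len(growth_rate, n_species),
    midpoint_offset = rep_len(midpoint_offset, n_species),
    intro_years = intro_years,
    adoption_rate = rep_len(adoption_rate, n_species),
    country_share_param = country_share_param,
    noise_cv = noise_cv, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Rank-abundance shares
#'
#' Deterministic descending shares for a rank-abundance distribution, used
#' for species volumes and country weights. The geometric model gives shares
#' proportional to `param^i`; the lognormal model takes the `(i - 0.5)/n`
#' quantiles of a log-normal with log-sd `param`, sorted descending. Both are
#' normalised to sum to one.
#'
#' @param n_species Number of entities (>= 1).
#' @param model `"geometric"` or `"lognormal"`.
#' @param param Decay ratio in (0,1), or log-sd > 0.
#' @return Numeric vector of positive shares, non-increasing, summing to 1.
#' @export
rank_abundance_shares <- function(n_species, model = c("geometric", "lognormal"),
                                  param = 0.6) {
  model <- match.arg(model)
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 1) {
    abort("n_species must be >= 1", class = "aquapanel_domain_error")
  }
  raw <- switch(model,
    geometric = {
      if (param <= 0 || param >= 1) {
        abort("geometric decay must lie in (0, 1)", class = "aquapanel_domain_error")
      }
      param^seq_len(n_species)
    },
    lognormal = {
      if (param <= 0) abort("lognormal sigma must be > 0", class = "aquapanel_domain_error")
      sort(stats::qlnorm((seq_len(n_species) - 0.5) / n_species, 0, param),
           decreasing = TRUE)
    }
  )
  raw / sum(raw)
}

#' Logistic production trajectory
#'
#' The saturating growth curve `K / (1 + exp(-r (t - t0)))`, used as the
#' deterministic skeleton of each species' production series.
#'
#' @param K Carrying level (tonnes, > 0).
#' @param r Growth rate per year (> 0).
#' @param t0 Midpoint year (value `K/2`).
#' @param years Integer vector of years to evaluate.
#' @return Named numeric vector (names are years), strictly increasing and
#'   bounded above by `K`.
#' @export
logistic_trajectory <- function(K, r, t0, years) {
  if (K <= 0 || r <= 0) abort("K and r must be > 0", class = "aquapanel_domain_error")
  if (length(years) == 0) abort("empty year range", class = "aquapanel_domain_error")
  v <- K / (1 + exp(-r * (years - t0)))
  stats::setNames(v, years)
}

#' Seeded country-adoption years
#'
#' Generates the year in which each country starts farming a species. The
#' first adopter starts exactly at `intro_year`; subsequent inter-adoption
#' gaps are exponential waiting times with the given rate, so the expected
#' gap is `1/rate` years. Years are returned un-rounded; values beyond a
#' study horizon mean the country never adopts within it.
#'
#' @param n_countries Number of potential adopters.
#' @param intro_year First farming year.
#' @param rate Expected adoptions per year (> 0).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return Numeric vector of length `n_countries`, non-decreasing.
#' @export
adoption_years <- function(n_countries, intro_year, rate, seed) {
  if (rate <= 0) abort("adoption rate must be > 0", class = "aquapanel_domain_error")
  n_countries <- as.integer(n_countries)
  gaps <- with_local_seed(seed, stats::rexp(max(0L, n_countries - 1L), rate))
  intro_year + c(0, cumsum(gaps))
}

# Run code under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-species sub-seed below 2^31.
species_subseed <- function(seed, s, salt = 0L) {
  (as.double(seed) * 48271 + s * 7919 + salt * 104729) %% 2147483587
}

#' Generate a synthetic production panel
#'
#' Builds a seeded panel from a [synthetic_config()]: species `s` has records
#' only from its introduction year onward and only in countries that have
#' adopted it, with national quantity
#' `logistic_s(t) * weight_c * noise`, where `logistic_s` has ceiling equal
#' to the species' share of the basin carrying level, country weights are a
#' geometric rank-abundance over adopters in adoption order, and the noise is
#' mean-one multiplicative log-normal. With `noise_cv = 0` the panel is the
#' exact deterministic product; equal seeds give identical panels.
#'
#' @param config A [synthetic_config()].
#' @return A [production_panel()].
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must come from synthetic_config()", class = "aquapanel_domain_error")
  }
  years <- seq(config$years[1], config$years[2])
  countries <- sprintf("country_%02d", seq_len(config$n_countries))
  species <- sprintf("species_%02d", seq_len(config$n_species))
  envs <- rep_len(c("marine", "freshwater", "brackish"), config$n_species)
  groups <- rep_len(c("fish", "fish", "fish", "bivalve", "fish", "crustacean"),
                    config$n_species)
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  out <- vector("list", config$n_species)
  for (s in seq_len(config$n_species)) {
    intro <- config$intro_years[s]
    yrs <- years[years >= intro]
    if (length(yrs) == 0) next
    t0 <- intro + config$midpoint_offset[s]
    traj <- logistic_trajectory(config$K[s], config$growth_rate[s], t0, yrs)

    adopt <- adoption_years(config$n_countries, intro, config$adoption_rate[s],
                            species_subseed(config$seed, s, 1L))
    ord <- order(adopt)
    weights <- rank_abundance_shares(config$n_countries, "geometric",
                                     config$country_share_param)
    grid <- expand.grid(ci = seq_len(config$n_countries), ti = seq_along(yrs))
    active <- adopt[ord][grid$ci] <= yrs[grid$ti]
    grid <- grid[active, , drop = FALSE]
    if (nrow(grid) == 0) next

    q <- traj[grid$ti] * weights[grid$ci]
    if (config$noise_cv > 0) {
      noise <- with_local_seed(
        species_subseed(config$seed, s, 2L),
        stats::rlnorm(config$n_countries * length(yrs), -sdlog^2 / 2, sdlog)
      )
      q <- q * noise[(grid$ti - 1L) * config$n_countries + grid$ci]
    }
    out[[s]] <- tibble(
      year = yrs[grid$ti],
      country = countries[ord][grid$ci],
      species = species[s],
      environment = envs[s],
      group = groups[s],
      quantity = unname(q)
    )
  }
  recs <- dplyr::bind_rows(out)
  production_panel(
    recs,
    provenance = sprintf("synthetic panel (seed %d, %d species, %d countries, %d-%d)",
                         config$seed, config$n_species, config$n_countries,
                         config$years[1], config$years[2])
  )
}
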