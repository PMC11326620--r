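gap_panel <- function() {
  production_panel(tibble::tribble(
    ~year, ~country, ~species, ~quantity,
    1990, "A", "carp", 10,
    1991, "A", "carp", 12,
    1995, "A", "carp", 9,
    1990, "A", "eel", 0,
    1991, "B", "carp", 3,
    1992, "B", "carp", 4
  ), "gaps")
}

test_that("persistence counts producing years, not spans", {
  p <- gap_panel()
  expect_equal(persistence(p, "carp", "species"), 4)        # 1990,91,92,95
  expect_equal(persistence(p, "carp", "species", mode = "span"), 6)
  expect_equal(persistence(p, "eel", "species"), 0)         # only zero records
  expect_equal(persistence(p, "B", "country"), 2)
  expect_error(persistence(p, "tilapia", "species"),
               class = "aquapanel_lookup_error")
})

test_that("diffusiveness series counts countries per year with zeros for gaps", {
  p <- production_panel(tibble::tribble(
    ~year, ~country, ~species, ~quantity,
    2000, "A", "carp", 1,
    2001, "A", "carp", 1,
    2001, "B", "carp", 1,
    2002, "B", "carp", 1,
    2003, "C", "eel", 5
  ), "hand")
  ds <- diffusiveness_series(p, "carp")
  expect_equal(ds$year, 2000:2003)
  expect_equal(ds$n_countries, c(1, 2, 1, 0))
  expect_equal(attr(ds, "C_ever"), 2)
  expect_gte(attr(ds, "C_ever"), max(ds$n_countries))
})

test_that("GER reproduces hand-computed rates and is ratio invariant", {
  expect_equal(geographical_expansion_rate(c(5, 5, 5, 5)), 0)
  expect_equal(geographical_expansion_rate(c(10, 11), window = 1), 10)

  counts <- 10:20
  hand <- mean(100 * diff(counts) / counts[-11])
  expect_equal(geographical_expansion_rate(counts, window = 10), hand)
  expect_equal(round(hand, 2), 7.19)

  expect_equal(geographical_expansion_rate(2 * counts, window = 10),
               geographical_expansion_rate(counts, window = 10))

  # zero previous counts are skipped; all-invalid windows warn and return NA
  expect_equal(geographical_expansion_rate(c(0, 4, 6), window = 10), 50)
  expect_warning(r <- geographical_expansion_rate(c(0, 0, 0)), "undefined")
  expect_true(is.na(r))
  expect_error(geographical_expansion_rate(3), class = "aquapanel_domain_error")
})

test_that("quadrant classification uses strict cuts and is monotone", {
  expect_equal(classify_quadrant(65, 25), "core_widespread")
  expect_equal(classify_quadrant(65, 3), "core_localized")
  expect_equal(classify_quadrant(10, 25), "emergent")
  expect_equal(classify_quadrant(10, 3), "transient")
  expect_equal(classify_quadrant(60, 25), "emergent")  # exactly at the cut is not core

  rank <- function(q) match(q, c("transient", "emergent", "core_localized",
                                 "core_widespread"))
  set.seed(14)
  for (i in 1:50) {
    pe <- sample(0:80, 1); di <- sample(0:30, 1)
    q0 <- classify_quadrant(pe, di)
    q_up_p <- classify_quadrant(pe + sample(1:20, 1), di)
    q_up_d <- classify_quadrant(pe, di + sample(1:20, 1))
    expect_true(grepl("core", q_up_p) >= grepl("core", q0))
    expect_true((q_up_d %in% c("core_widespread", "emergent")) >=
                  (q0 %in% c("core_widespread", "emergent")))
  }
})

test_that("geo profiles recover the generator's structural ground truth", {
  cfg <- synthetic_config(n_species = 4, n_countries = 5, years = c(1950L, 2020L),
                          intro_years = c(1950L, 1968L, 1990L, 2005L),
                          adoption_rate = 1e6, noise_cv = 0, seed = 6)
  p <- generate_panel(cfg)
  prof <- geo_profiles(p, "species", diffusiveness_cut = 4)
  prof <- prof[order(prof$entity), ]
  expect_equal(prof$persistence, 2020 - c(1950, 1968, 1990, 2005) + 1)
  expect_equal(prof$diffusiveness_ever, rep(5, 4))
  expect_equal(prof$quadrant,
               c("core_widespread", "emergent", "emergent", "emergent"))
})

test_that("relative productivity divides window totals by area", {
  p <- production_panel(tibble::tribble(
    ~year, ~country, ~species, ~quantity,
    2016, "Malta", "seabream", 200,
    2017, "Malta", "seabream", 300,
    2017, "Egypt", "tilapia", 500,
    2010, "Egypt", "tilapia", 99999   # outside the 5-year window
  ), "hand")
  rp <- relative_productivity(p, c(Malta = 100, Egypt = 1000), window = 5)
  expect_equal(rp$productivity[rp$country == "Malta"], 5)
  expect_equal(rp$productivity[rp$country == "Egypt"], 0.5)
  expect_equal(rp$country[1], "Malta")  # sorted descending

  # equal volumes, 10x area ratio -> 10x productivity ratio
  q <- production_panel(tibble::tribble(
    ~year, ~country, ~species, ~quantity,
    2017, "A", "x", 500, 2017, "B", "x", 500), "hand")
  r <- relative_productivity(q, c(A = 10, B = 100))
  expect_equal(r$productivity[r$country == "A"] / r$productivity[r$country == "B"], 10)

  expect_error(relative_productivity(p, c(Malta = 100)), "Egypt",
               class = "aquapanel_lookup_error")
})
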