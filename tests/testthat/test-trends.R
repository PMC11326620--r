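test_that("exact polynomials are recovered with r2 = 1", {
  lin <- fit_trend(annual_series(2000:2010, 2 * (0:10) + 1), "linear")
  expect_equal(unname(lin$coefficients), c(2, 1), tolerance = 1e-10)
  expect_equal(lin$r2, 1, tolerance = 1e-12)

  quad <- fit_trend(annual_series(2000:2004, (0:4)^2), "polynomial", degree = 2)
  expect_equal(unname(quad$coefficients[1]), 1, tolerance = 1e-9)
  expect_equal(quad$r2, 1, tolerance = 1e-12)

  cubic_y <- 2 - 3 * (0:8) + 0.5 * (0:8)^2 - 0.03 * (0:8)^3
  cub <- fit_trend(annual_series(1990:1998, cubic_y), "polynomial", degree = 3)
  expect_equal(unname(cub$coefficients), c(-0.03, 0.5, -3, 2), tolerance = 1e-9)

  expect_error(fit_trend(annual_series(2000:2002, 1:3), "polynomial", degree = 2),
               class = "aquapanel_domain_error")
  expect_error(fit_trend(annual_series(2000:2005, c(1, 2, -1, 3, 4, 5)), "exponential"),
               class = "aquapanel_domain_error")
})

test_that("forecast evaluates the model and matches an independent lm fit", {
  m <- list(kind = "linear", degree = 1L,
            coefficients = c(`x^1` = 2, `x^0` = 1), r2 = 1, pearson_r = 1,
            x_origin = 2000, fit_window = c(2000, 2005), n = 6)
  class(m) <- "trend_model"
  expect_warning(v <- forecast(m, 2010), "extrapolating")
  expect_equal(v, 21)

  set.seed(17)
  yrs <- 1990:2010
  vals <- 50 + 3 * (yrs - 1990) + 0.2 * (yrs - 1990)^2 + rnorm(21, sd = 4)
  model <- fit_trend(annual_series(yrs, vals), "polynomial", degree = 2)
  ref <- stats::lm(vals ~ stats::poly(yrs - 1990, 2, raw = TRUE))
  expect_equal(forecast(model, yrs), unname(stats::fitted(ref)), tolerance = 1e-8)

  # exponential: yearly factor 1.05 gives x1.6289 over 10 years
  g <- annual_series(2000:2010, 100 * 1.05^(0:10))
  em <- fit_trend(g, "exponential")
  expect_equal(forecast(em, 2010) / forecast(em, 2000), 1.05^10, tolerance = 1e-9)
  expect_equal(round(1.05^10, 4), 1.6289)
})

test_that("growth rates match hand computation and skip zero denominators", {
  expect_equal(growth_rate_series(annual_series(1:4, rep(3, 4)))$value, rep(0, 3))
  expect_equal(growth_rate_series(annual_series(1:2, c(100, 105)))$value, 5)
  gr <- growth_rate_series(annual_series(1:3, c(0, 10, 20)))
  expect_equal(nrow(gr), 1)  # the 0 -> 10 step is skipped
  expect_equal(gr$value, 100)
})

test_that("mean growth rate of a geometric series is its common ratio under both methods", {
  s <- annual_series(2000:2020, 100 * 1.05^(0:20))
  expect_equal(mean_growth_rate(s, method = "arithmetic"), 5, tolerance = 1e-9)
  expect_equal(mean_growth_rate(s, method = "cagr"), 5, tolerance = 1e-9)
  expect_equal(mean_growth_rate(s, window = 5, method = "arithmetic"), 5,
               tolerance = 1e-9)
  expect_equal(mean_growth_rate(s, window = 10, method = "cagr"), 5,
               tolerance = 1e-9)

  expect_equal(mean_growth_rate(annual_series(1:3, c(100, 110, 99))), 0,
               tolerance = 1e-12)
  expect_equal(mean_growth_rate(annual_series(c(2000, 2002), c(100, 121)),
                                method = "cagr"), 10, tolerance = 1e-9)
  expect_error(mean_growth_rate(annual_series(1:2, c(0, 5)), method = "cagr"),
               class = "aquapanel_domain_error")
})

test_that("carrying capacity is the windowed mean", {
  expect_equal(carrying_capacity(annual_series(1985:2020, rep(4.15, 36))), 4.15)
  expect_equal(carrying_capacity(annual_series(2000:2001, c(3, 5)),
                                 window = c(2000, 2001)), 4)
  set.seed(5)
  v <- runif(10, 1, 9)
  s <- annual_series(1991:2000, v)
  expect_equal(carrying_capacity(s, c(1993, 1997)), mean(v[3:7]))
  expect_error(carrying_capacity(s, c(2050, 2060)), class = "aquapanel_domain_error")
})

test_that("ratio series divides on the year intersection", {
  aq <- annual_series(c(1950, 2020), c(1, 2))
  fi <- annual_series(c(1950, 2020), c(130, 4))
  expect_equal(ratio_series(fi, aq)$value, c(130, 2))
  same <- annual_series(1:5, 2:6)
  expect_equal(ratio_series(same, same)$value, rep(1, 5))
  expect_warning(r <- ratio_series(annual_series(1:2, c(1, 1)),
                                   annual_series(1:2, c(0, 2))), "zero")
  expect_equal(r$value, 0.5)
  expect_error(ratio_series(annual_series(1:2, 1:2), annual_series(3:4, 1:2)),
               class = "aquapanel_domain_error")
})

test_that("pearson correlation matches hand covariance and flags degenerate input", {
  x <- annual_series(1:4, 1:4)
  expect_equal(pearson_cor(x, annual_series(1:4, 3 * (1:4) + 2)), 1)
  expect_equal(pearson_cor(x, annual_series(1:4, -(1:4))), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_cor(c(1, 2, 3), c(5, 5, 5)), class = "aquapanel_domain_error")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), class = "aquapanel_domain_error")
})

test_that("correlation matrix is symmetric, unit-diagonal and affine invariant", {
  tab <- data.frame(country = letters[1:6],
                    a = c(1, 4, 2, 6, 3, 5),
                    b = c(2, 8, 4, 12, 6, 10),
                    c = c(9, 1, 7, 2, 8, 3))
  m <- correlation_matrix(tab)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], 1)  # b is an affine image of a
  expect_equal(m["a", "c"], pearson_cor(tab$a, tab$c))

  tab2 <- tab
  tab2$c <- -3 * tab2$c + 7
  expect_equal(abs(correlation_matrix(tab2)), abs(m))

  # exclusion list drops an outlier before correlating
  tab3 <- rbind(tab, data.frame(country = "egypt", a = 100, b = -5, c = 0))
  expect_equal(correlation_matrix(tab3, exclude = "egypt"), m)

  # sparse pairs are flagged undefined
  tab4 <- data.frame(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2), c = 1:4)
  expect_true(is.na(correlation_matrix(tab4)["a", "b"]))
})

test_that("panel series extraction feeds the trend stack", {
  p <- tiny_panel()
  tot <- panel_series(p, "total")
  expect_equal(tot$value, c(180, 150, 20))
  sb <- panel_series(p, species = "seabass")
  expect_equal(sb$value, c(130, 150))
  expect_error(panel_series(p, species = "tilapia"),
               class = "aquapanel_lookup_error")
})
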