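test_that("species-by-year matrix matches hand-aggregated cells and fills gaps", {
  p <- tiny_panel()
  m <- species_year_matrix(p)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["seabass", ], c(`2000` = 130, `2001` = 150, `2002` = 0))
  expect_equal(m["trout", ], c(`2000` = 50, `2001` = 0, `2002` = 20))

  sub <- species_year_matrix(p, rows = "trout")
  expect_equal(dim(sub), c(1, 3))
  expect_error(species_year_matrix(p, rows = "tilapia"),
               class = "aquapanel_lookup_error")
})

test_that("row z-scaling standardises with sample sd and guards constant rows", {
  m <- matrix(c(1, 2, 3, 7, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), 2000:2002))
  z <- zscale_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_true(attr(z, "scaled"))
  expect_equal(attr(z, "row_stats")$sd, c(1, 0))

  set.seed(12)
  big <- matrix(rexp(60), 6)
  zb <- zscale_rows(big)
  expect_equal(unname(rowMeans(zb)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 6), tolerance = 1e-9)

  # idempotent in effect: scaling already-standardised values changes nothing
  again <- zscale_rows(matrix(zb, nrow = nrow(zb), dimnames = dimnames(zb)))
  expect_equal(unclass(again), unclass(zb), ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(zscale_rows(z), class = "aquapanel_domain_error")
})

test_that("ward clustering merges tight pairs first with non-decreasing heights", {
  m <- rbind(a = c(0, 0, 0), b = c(0.1, 0, 0),
             c = c(10, 10, 10), d = c(10.1, 10, 10))
  hc <- cluster_rows(m)
  expect_s3_class(hc, "hclust")
  expect_true(!is.unsorted(hc$height))
  first_two <- lapply(1:2, function(i) sort(hc$labels[-hc$merge[i, ]]))
  expect_true(setequal(first_two, list(c("a", "b"), c("c", "d"))))
  expect_lt(hc$height[2], hc$height[3])

  dup <- rbind(a = 1:3, b = 1:3, c = c(9, 9, 9))
  hd <- cluster_rows(dup)
  expect_equal(hd$height[1], 0)

  expect_error(cluster_rows(m[1, , drop = FALSE]), class = "aquapanel_domain_error")
})

test_that("ward merge structure equals the naive agglomerative oracle", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 5), n, dimnames = list(paste0("r", 1:n), NULL))
    hc <- cluster_rows(x)
    o <- ward_oracle(x)
    expect_equal(sort(hc$height), sort(o$heights), tolerance = 1e-9)
    expect_equal(unname(as.matrix(stats::cophenetic(hc))), o$coph, tolerance = 1e-9)
    expect_true(all(sort(hc$order) == 1:n))  # leaf order is a permutation
  }
})

test_that("newick export carries all leaves", {
  set.seed(2)
  x <- matrix(rnorm(20), 4, dimnames = list(c("carp", "trout", "mussel", "tilapia"), NULL))
  txt <- dendrogram_newick(cluster_rows(x))
  expect_match(txt, "^\\(")
  for (lab in rownames(x)) expect_match(txt, lab)
  tr <- ape::read.tree(text = txt)
  expect_setequal(tr$tip.label, rownames(x))
})

test_that("dominance timeline extracts argmax runs and planned handovers", {
  m <- matrix(c(5, 5, 5, 1, 1, 1,
                1, 1, 1, 9, 9, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), 1991:1996))
  dom <- dominant_per_year(m)
  expect_equal(dom$label, c(rep("A", 3), rep("B", 3)))
  expect_equal(dom$share[1], 5 / 6)
  ph <- dominance_phases(dom)
  expect_equal(ph, tibble::tibble(start = c(1991, 1994), end = c(1993, 1996),
                                  label = c("A", "B")))

  # column scale invariance and tie/zero handling
  m2 <- m; m2[, 3] <- m2[, 3] * 100
  expect_equal(dominant_per_year(m2)$label, dom$label)
  tie <- matrix(2, 2, 2, dimnames = list(c("b", "a"), 2000:2001))
  expect_equal(dominant_per_year(tie)$label[1], "a")
  zero <- matrix(0, 2, 1, dimnames = list(c("a", "b"), 2005))
  expect_equal(dominant_per_year(zero)$label, "none")

  one <- matrix(1:3, 1, dimnames = list("only", 2000:2002))
  expect_equal(nrow(dominance_phases(dominant_per_year(one))), 1)
})

test_that("a planned dominance handover in the generator is recovered exactly", {
  cfg <- synthetic_config(
    n_species = 2, n_countries = 1, years = c(1990L, 2010L),
    K = c(100, 5000), growth_rate = c(0.3, 0.8),
    midpoint_offset = c(5, 15), intro_years = c(1990L, 1990L),
    adoption_rate = 1e6, noise_cv = 0, seed = 4)
  m <- species_year_matrix(generate_panel(cfg))
  ph <- dominance_phases(dominant_per_year(m))
  # crossover where the slow small-K and fast large-K logistics intersect
  traj1 <- logistic_trajectory(100, 0.3, 1995, 1990:2010)
  traj2 <- logistic_trajectory(5000, 0.8, 2005, 1990:2010)
  expected_first_b <- (1990:2010)[which(traj2 > traj1)[1]]
  expect_equal(nrow(ph), 2)
  expect_equal(ph$label, c("species_01", "species_02"))
  expect_equal(ph$start[2], expected_first_b)
})
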