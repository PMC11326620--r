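# Shared fixtures and independent oracles used across the suite.

# Minimal hand-written panel: 2 species, 2 countries, 3 years.
tiny_panel <- function() {
  production_panel(tibble::tribble(
    ~year, ~country, ~species, ~environment, ~quantity,
    2000, "Italy", "seabass", "marine", 100,
    2000, "Italy", "trout", "freshwater", 50,
    2000, "Greece", "seabass", "marine", 30,
    2001, "Italy", "seabass", "marine", 110,
    2001, "Greece", "seabass", "marine", 40,
    2002, "Greece", "trout", "freshwater", 20
  ), provenance = "hand-built fixture")
}

write_temp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Independent brute-force dominance oracle: recompute every prefix sum from
# scratch and take the smallest prefix crossing each threshold.
brute_decompose <- function(volumes, relevant_share = 0.99, dominant_share = 0.80) {
  volumes <- volumes[volumes > 0]
  ord <- order(-volumes, names(volumes))
  v <- volumes[ord]
  total <- sum(v)
  eps <- 1e-9 * total
  smallest_prefix <- function(th) {
    for (k in seq_along(v)) {
      if (sum(v[seq_len(k)]) >= th * total - eps) return(k)
    }
    length(v)
  }
  rel <- smallest_prefix(relevant_share)
  dom <- smallest_prefix(dominant_share)
  list(total = length(v), relevant = rel, dominant = dom,
       minor = length(v) - rel, pareto_index = 100 * dom / rel)
}

# Independent direct-summation Shannon oracle.
brute_shannon <- function(volumes) {
  v <- volumes[volumes > 0]
  p <- v / sum(v)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

# Naive O(n^3) agglomerative Ward oracle: at every step recompute the
# Ward (D2 convention) merge cost between all active cluster pairs from the
# cluster centroids and merge the cheapest. Returns merge heights and the
# full cophenetic matrix, which pins down the merge sequence.
ward_oracle <- function(x) {
  n <- nrow(x)
  centroid <- lapply(seq_len(n), function(i) x[i, ])
  size <- rep(1, n)
  members <- lapply(seq_len(n), function(i) i)
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n)
  for (m in seq_len(n - 1)) {
    act <- which(!is.na(size)); best <- Inf; bi <- bj <- NA
    for (a in seq_along(act)) for (b in seq_along(act)) if (b > a) {
      i <- act[a]; j <- act[b]
      d2 <- sum((centroid[[i]] - centroid[[j]])^2)
      cost <- sqrt(2 * size[i] * size[j] / (size[i] + size[j]) * d2)
      if (cost < best) { best <- cost; bi <- i; bj <- j }
    }
    heights[m] <- best
    coph[members[[bi]], members[[bj]]] <- best
    coph[members[[bj]], members[[bi]]] <- best
    centroid[[bi]] <- (size[bi] * centroid[[bi]] + size[bj] * centroid[[bj]]) /
      (size[bi] + size[bj])
    members[[bi]] <- c(members[[bi]], members[[bj]])
    size[bi] <- size[bi] + size[bj]; size[bj] <- NA
  }
  list(heights = heights, coph = coph)
}
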