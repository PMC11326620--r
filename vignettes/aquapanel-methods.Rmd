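---
title: "Methods: diversity, expansion and succession analysis of production panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, expansion and succession analysis of production panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquapanel)
```

`aquapanel` analyses annual production panels — year × country × species
tables of farmed volumes in tonnes, the form in which FAO FishStatJ exports
national aquaculture statistics. This vignette describes the statistical
procedures, the choices behind their defaults, and what the bundled
synthetic generator does and does not emulate.

## The dominance decomposition

The central statistic partitions one year's producing entities (species, or
countries) into three classes. Sort entities by volume, descending, ties
broken by label so the partition is deterministic. With cumulative share
$C_k = \sum_{i \le k} p_i$ of the annual total:

- **relevant** entities: the smallest prefix with $C_k \ge 0.99$;
- **dominant** (main) entities: the smallest prefix with $C_k \ge 0.80$;
- **minor** entities: everything outside the relevant set
  (`total − relevant`), i.e. the long tail jointly contributing under 1%.

The **Pareto index** is `100 × dominant/relevant`. It tracks the 80/20
structure of the sector: an index near 20–30% means a handful of the
species that matter produce four fifths of the volume.

Two readings of "80% of production" are possible: against the annual total
or against the relevant subset's subtotal. The canonical ten-species
example (shares 50, 30, 8, 4, 3, 2, 2, 0.4, 0.3, 0.3 percent → 7 relevant,
2 dominant, 3 minor, index 28.6%) is reproduced by the total-based reading,
which is therefore the default; `dominant_base = "relevant"` selects the
subset-based rule. Similarly, "minor" is defined operationally as
`total − relevant`, not by a per-entity `< 1%` test — the two disagree
whenever the prefix overshoots the 99% threshold, and the difference rule
is the one the worked example uses. Threshold comparisons use a relative
tolerance of `1e-9` so that shares like five exact 20% entries cross their
threshold regardless of floating-point accumulation order.

## Shannon diversity

`shannon_index()` computes $H = -\sum_i p_i \ln p_i$ in nats, with $p_i$
the *proportions* of annual volume (percentages inside the logarithm would
break the $0 \le H \le \ln S$ bound). Zero-volume entities are excluded
from both richness $S$ and the shares. `H` complements the Pareto index:
richness counts species, `H` weighs them by their functional contribution.

## Expansion profiling

- **Persistence** is the count of years with strictly positive production
  (gap years do not count); a `mode = "span"` option returns first-to-last
  span for sensitivity analyses.
- **Diffusiveness** is the number of countries with positive production of
  a species, per year ($C_t$) and cumulative-ever. Quadrant classification
  defaults to the *ever* count; both are exposed because "currently
  farmed" is an equally defensible reading.
- **GER** (Geographical Expansion Rate) is the arithmetic mean of
  year-over-year percent changes of $C_t$ over a trailing window, default
  10 years; a geometric-mean option annualises the compound change
  instead. Rates with a zero previous count are undefined and skipped; a
  window with no valid rate yields `NA` with a warning rather than an
  error, since flat early series are common.
- **Quadrants** use strict cuts (`> 60` years, `> 20` countries by
  default), so an entity exactly at a cut is not "core": the cuts are read
  as "more than".
- **Relative productivity** is the window total (default: last 5 calendar
  years) divided by national area in km². Areas are user-supplied — a demo
  table ships under `inst/extdata/` for examples and tests.

## Trend machinery

`fit_trend()` fits linear, polynomial (default degree 2 — degrees beyond 3
are rarely interpretable for annual series) or exponential (log-linear)
models by least squares after centering years at the first fitted year;
centering keeps high powers of calendar years (e.g. $2020^3$)
well-conditioned. Coefficients are reported in descending powers;
exponential fits report `(rate, scale)` for `scale·exp(rate·x)`.
`forecast()` evaluates the model without clamping and warns when
extrapolating outside the fitted window; no uncertainty band is attached
by default.

Growth is summarised two ways: the arithmetic mean of year-over-year
percent changes, and the compound rate
$100\,[(v_{end}/v_{start})^{1/(y_{end}-y_{start})} - 1]$. The exponent uses
the calendar-year gap, which coincides with "number of observations minus
one" for contiguous annual series but stays correct across gaps.
`carrying_capacity()` is simply the long-run mean of a capture-fishery
landings series over a stated window (default 1985–2020), used as the
ceiling of wild extraction against which aquaculture growth is read.
Correlation analyses (`pearson_cor()`, `correlation_matrix()`) are
standard product-moment correlations on pairwise-complete data, with an
entity-exclusion list because a single outlier producer can swamp every
between-country correlation; pairs with fewer than 3 complete observations
are reported `NA`.

## Succession analysis

`species_year_matrix()` spreads the panel into a species × year matrix
covering the full year span (absent cells default to 0).
`zscale_rows()` standardises each row by its own mean and *sample*
standard deviation, so a row `(1, 2, 3)` becomes `(−1, 0, 1)`; constant
rows map to zeros rather than `NaN`. Scaling makes small and large
producers comparable, which is what reveals the temporal succession of
dominant species that raw volumes hide behind the largest producer.

`cluster_rows()` performs agglomerative clustering of rows on Euclidean
distances with Ward linkage in the squared-distance ("ward.D2")
convention — the widely used reading of "Ward clustering" — or centroid
linkage (whose heights are reported on the Euclidean scale; centroid
inversions are possible, as usual). Ward heights are non-decreasing. The
dendrogram exports to Newick with merge heights as branch lengths.

`dominant_per_year()` is deliberately simple: per year, the argmax entity
and its share of the column total, ties to the lexicographically smallest
label, all-zero years labelled `"none"`. Consecutive runs of the same
label (`dominance_phases()`) are the succession phases; any ecological
interpretation (pioneer → intermediate → climax stages) is a reading laid
over this output, not a separate algorithm, and no formal changepoint test
is attempted.

## The synthetic generator

`generate_panel()` produces panels with the regularities the analyses
assume, so the whole stack is testable offline:

- **Species shares** follow a geometric rank-abundance (decay 0.6 by
  default), giving the heavy-tailed dominance structure in which 3–4 of 15
  species carry ~80% of volume; a log-normal alternative uses evenly
  spaced quantiles so it stays deterministic.
- **Trajectories** are logistic, $K_s/(1+e^{-r_s(t-t_{0,s})})$, with each
  species' ceiling its share of a basin-wide 2.8 million tonne carrying
  level, rate 0.12/yr and midpoint 25 years after introduction — a
  saturating history on the scale of a 1950–2020 horizon.
- **Introductions** are staggered evenly across the first 70% of the
  horizon, so early "pioneer" species coexist with late arrivals.
- **Adoption** by countries is an exponential waiting-time process
  (expected 0.5 new countries/yr), the simplest memoryless model of
  innovation diffusion that yields rising diffusiveness; country weights
  are themselves a geometric rank-abundance over adopters, mirroring the
  dominance of 2–3 producer countries.
- **Noise** is multiplicative log-normal with mean one (production data
  are positive and right-skewed), default CV 5%, so expected totals equal
  the deterministic skeleton and `noise_cv = 0` gives it exactly.
- **Seeding**: one global seed; per-species sub-streams are derived
  arithmetically, so adding a species never perturbs existing series, and
  the caller's RNG state is preserved.

What it does *not* emulate: real species turnover (extinctions and
re-entries), value/price dynamics, reporting artefacts (the FishStatJ
sentinels are exercised by hand-written fixtures instead), correlated
country shocks, or any geography beyond adoption order. Tests passing on
generated panels therefore validate the analysis pipeline's arithmetic and
invariances, not the empirical adequacy of any fitted model for real FAO
data.

## Numerical choices and degenerate inputs

- Dominance thresholds compared with relative tolerance `1e-9`; volume
  ties broken by label.
- All-zero or empty volume vectors, empty year ranges, non-overlapping
  series and insufficient fit points raise classed errors
  (`aquapanel_domain_error` etc.) rather than returning silent `NA`s; the
  one deliberate exception is the GER window with no valid rate (`NA` +
  warning), which is a normal occurrence, not a misuse.
- `write_tidy_panel()` prints doubles with `%.17g`, and `read_tidy_panel()`
  parses with base R's strtod path, so a write/read round trip is
  bitwise exact.
- Duplicate panel keys are summed by default (FAO splits some series by
  sub-environment); `strict = TRUE` turns them into errors for QC.
- FishStatJ sentinels: `"..."`/empty → missing, `"-"` → 0, one trailing
  letter flag stripped and logged. The decimal separator is `"."`
  throughout; comma-decimal exports must be converted beforehand.

## Problem sizes

The test suite and examples run on panels of 1–15 species, up to 20
countries and up to 71 years, on randomized dominance vectors up to 50
entities (1000 replicates against a brute-force prefix oracle) and on
5–8-row clustering problems (100 replicates against a naive $O(n^3)$
agglomeration oracle) — sizes at which the independent oracles are exact
and fast. All analysis functions are vectorised over years and entities
and handle the full FishStatJ scale (hundreds of species × decades)
without special handling.

## Known limitations

- The 99%/80%/60-year/20-country defaults are conventions of the
  analysis, not estimated quantities; sensitivity to them is the user's
  responsibility (all are arguments).
- Trend forecasts are deterministic extrapolations; they carry no
  uncertainty and polynomial extrapolation far beyond the window is
  dominated by the leading term.
- National production cannot be split sub-nationally (e.g. by coastline);
  a country include/exclude filter is the only instrument offered.
- Correlation analyses accept covariates only as user-supplied aligned
  tables; no retrieval, no causal claims.
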