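---
title: "Designing covariate-based field surveys with hypersample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing covariate-based field surveys with hypersample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypersample)
```

## The problem

A field campaign over a landscape is only as informative as the portion of
covariate space it visits. Given a stack of co-registered raster covariates
(terrain derivatives, sensor readings, categorical maps), conditioned Latin
hypercube sampling (cLHS) selects `n` real grid cells whose values jointly
reproduce the marginal distributions and the correlation structure of the
whole map. `hypersample` implements cLHS itself plus the surrounding
decisions a survey planner faces: choosing `n`, replacing inaccessible
sites, and complementing legacy data.

All computation happens on the *population table*: the `r` cells that are
valid in every layer (nodata is intersected across layers). Cells are
half-open — a point on an edge belongs to the cell right/below — and all
geometry is metric, so a geographic (degree-based) CRS is rejected rather
than silently treated as meters.

## cLHS by simulated annealing

For each continuous covariate the population is cut into `n` equi-probable
strata (empirical quantiles with linear interpolation, R's type-7 default).
The objective is

`O = w1·O1 + w2·O2 + w3·O3`

with `O1 = Σ |count in stratum − 1|` over all continuous strata,
`O2 = Σ |sample − population class proportion|` over categorical classes,
and `O3` the sum of absolute differences between sample and population
Pearson correlations (upper triangle, continuous covariates only). A
covariate that is constant *within a sample* has no defined sample
correlation; its entries count as zero deviation and the covariate is
flagged, rather than poisoning the objective with `NA`.

The optimiser starts from a uniform random draw of `n` valid cells and
runs Metropolis annealing: a proposal swaps one sampled cell for a random
unsampled cell — with probability `swap_prob = 0.5` a uniformly chosen
sample point, otherwise the point sitting in the most over-full continuous
strata — and is accepted when `ΔO ≤ 0` or with probability `exp(−ΔO/T)`.
The schedule (`temp_start = 1`, multiplied by `cooling = 0.95` every
`chain_length = 10` iterations, 10,000 iterations by default) is not part
of the method's definition; these values reproduce the behaviour of the
widely used reference implementation and were fixed before any tuning.
The best-so-far design is returned, so longer runs can never return a
worse design under the same seed. Every stochastic entry point takes an
integer `seed`, and identical seeds give identical designs — this is a
hard API contract, relied on by the run-manifest reproducibility of the
CLI.

Strata with duplicated quantile edges (possible when `n` exceeds the
number of distinct values) are kept as zero-width, always-empty intervals
and flagged; membership everywhere uses half-open bins with the last bin
closed, so ties at the maximum are never lost.

## Divergence between sample and population

Distributions are compared through proportions over `nbins = 25`
equal-width bins spanning the *population* range of each continuous
covariate; the sample is binned against the same population edges,
otherwise `O` and `E` would not be comparable. Categorical covariates are
compared through raw class proportions — histogram bins are meaningless
for codes. 25 bins follows common practice; too few bins hide
distributional features, too many turn sampling noise into divergence, and
the bin count is exposed so users can check sensitivity by iteration.

The divergence is `KL = Σ_i O_i (ln O_i − ln E_i)` with two conventions
chosen here because the formula leaves them open:

* `O_i = 0` terms contribute 0 (the limit convention);
* sample mass on a bin with `E_i = 0` (only possible through numerically
  empty population bins) triggers ε-smoothing — `1e-6` added to every `E`
  bin, renormalised, with a warning — keeping small-sample KL finite
  without measurably distorting large-sample behaviour.

The bounded alternative `Σ_i |O_i − E_i|` is provided for comparison; the
salient difference is that KL charges more for missing tail mass than for
the same mass missing near the mode, which the test suite asserts on
constructed pairs.

## How many samples: sweep, decay fit, 95% rule

`run_sweep()` repeats seeded cLHS runs (`reps = 10` by default) at each
size on a grid (default 10–500 by 10) and records the mean and spread of
the mean KL. Per-run seeds are drawn once from the master seed, so reps
are independent but the sweep is exactly reproducible. `fit_decay()` fits
`y = b1·exp(−k·x) + b0` by nonlinear least squares (port algorithm,
`b1 ≥ 0`, `k > 0`, starting values `b0 = min(y)`, `b1 = max(y) − min(y)`,
`k = 1/mean(x)`; `scaleOffset = 1` so a perfect noiseless fit converges
rather than failing on zero residuals). A flat series fails with the
starting values attached.

The "enough samples" rule works on the captured fraction
`C(x) = 1 − exp(−k·x)`: the smallest grid size with `C(x) ≥ coverage`
(default 0.95) is returned together with the continuous solution
`x* = −ln(1 − coverage)/k`. Normalising the decay this way makes the rule
invariant to any constant scaling of the divergence — only the decay
constant `k` matters, which is also the only fitted quantity that is
robust across divergence metrics.

## Relocating inaccessible sites

Given an inaccessible site, the candidate zone is every valid cell within
`radius` (default 500 m, a practical on-foot detour) whose class matches
the site on *every* categorical layer. Candidates are scored by

`S = 1 / (1 + exp(slope · (dist − dist_med)))`

where `dist` is the **squared** Mahalanobis distance to the site over the
continuous covariates and `dist_med` the median over the (masked) zone —
the median being less outlier-sensitive than the mean. `S` is a strictly
decreasing bijection onto (0, 1) anchored at `S(dist_med) = 0.5`, and the
qualifier set at threshold `t` is exactly
`{dist ≤ dist_med + ln(1/t − 1)/slope}`.

Two deliberate choices need stating:

* **Distance scale.** At the conventional threshold `t = 0.975` a
  qualifier must sit `ln(39) ≈ 3.66` below the zone median. Median
  *square-rooted* Mahalanobis distances inside a local buffer are ~2–3 for
  typical covariate counts, so on that scale the threshold would never
  admit a candidate anywhere. On the squared scale (which is also what
  `stats::mahalanobis()` returns) buffer medians comfortably clear the
  gap, and the threshold behaves as intended. `mahalanobis_distance()`
  itself returns the true distance; `relocate()` and the COOBS machinery
  share the squared scale. A `slope` parameter (default 1) is exposed
  purely for sensitivity analysis.
* **Covariance.** Σ is estimated from the whole valid raster, not from
  the buffer — buffers can be small and collinear — and near-singular Σ
  is repaired by a tiny ridge (`1e-8 · mean(diag)`) with a warning; a
  still-singular matrix names the collinear layer pair. Whether the
  buffer or the map is the right covariance population is genuinely open;
  full-raster keeps distances comparable across sites and modules.

Selection among qualifiers is `random` (seeded; the conventional choice),
`nearest` (geographically) or `ranked` (by covariate distance). An empty
zone or empty qualifier set is an error by default; with `grow = TRUE`
the radius doubles up to `grow_cap` (default 4×) first — off by default
to honour a fixed survey buffer.

### What relocation does to the design's divergence

`evaluate_relocation()` reports per-covariate KL for the original and
relocated designs. Users should not expect the relocated design to match
the original's KL when `n` is small relative to the bin count: a cLHS
design sits far *below* the random-sampling noise floor
`(B − 1)/(2n)` of a `B`-bin histogram, and any perturbation — even moving
every site one cell, a covariate displacement well under one bin width —
pushes the design measurably back toward that floor. On a 100×100
five-covariate synthetic landscape at `n = 50` (floor ≈ 0.24, cLHS
≈ 0.10) relocating all sites raises mean KL by 0.05–0.15 depending on
strategy. The often-quoted field result that relocation leaves the mean
KL unchanged arises when the original design's KL already sits at the
noise floor (true of real surveys with `n` in the hundreds, e.g.
24/682 ≈ 0.035 at `n = 341`), leaving nothing to degrade. The package's
acceptance suite keeps a strict equality-style check at `n = 50` and it
fails for exactly this reason; the accompanying analysis lives here so
the red result is interpretable.

## Accounting for legacy data: aHELS

The quantile matrix holds `s + 1` quantiles per continuous covariate
(categorical layers are excluded — the strata are quantile-based).
Per stratum, grid density is `pixel tally / r` and data density is
`legacy tally / o`; their ratio flags under-sampling (`< 1`), with `0/0`
reported as 0 and flagged. Ranking all `s × k` ratios ascending — ties
broken deterministically by (covariate, stratum) — the allocator draws,
per stratum, `m = max(1, ⌈o·grid_density − current data tally⌉)` cells
uniformly at random from the stratum's unselected cells, capped at the
remaining budget and at availability. Two refinements over the naive
reading of the classic recipe:

* `m` subtracts the tally already present (otherwise strata at parity
  would be topped up again); the literal product `o·grid_density` is
  available via `m_rule = "literal"`.
* each new site is re-tallied into *every* covariate's strata before the
  next ranking entry is consumed, since marginal strata overlap — one
  cell serves several strata.

The walk repeats over the ranking until exactly `s` sites are allocated;
an unfillable budget yields a partial design with a warning, never a
silent shortfall. Legacy cells are never re-drawn, and the output records
each site's triggering stratum (`"cov1[q20]"`).

## COOBS coverage maps

For each valid pixel, `magpd` is the maximum squared Mahalanobis distance
to all other pixels (exact mode, O(r²)) or to a seeded random subset
(`approx_sample`, default `min(r, 2000)`) — the approximation can only
underestimate `magpd`, hence only *lower* COOBS counts, which the tests
assert. Each legacy point's standardised distance is
`sdd = 1 − dd/magpd`, and the COOBS value is the count of legacy points
with `sdd ≥ 0.975` (the threshold matches the relocation default for
coherence and is exposed). A pixel with `magpd = 0` is flagged and falls
back to exact-match counting. Cross-tabulation against the conventional
coverage bands 0–5, 5–10, 10–20, 20–40, >40 (half-open, last closed by
`o`) summarises where a design's sites sit relative to existing coverage.

## The synthetic landscape generator

`make_landscape()` produces the worlds the test suite runs on: white
Gaussian noise fields mixed through the Cholesky factor of a target
correlation matrix, then smoothed with a Gaussian kernel (`range`, in
cells; smoothing is linear and applied identically per layer, so the
realised correlation approximates the target — tests allow ±0.1) and
standardised. Categorical layers are quantile cuts of further smoothed
fields, so classes form coherent patches. Defaults — 100×100 cells at
25 m (a typical DEM resolution), five continuous covariates (a typical
terrain-derivative suite), kernel sd 5 cells — were fixed once as a
plausible miniature of a survey landscape.

`make_legacy()` emulates the legacy designs that motivate aHELS/COOBS:
uniform (`none`), geographically clustered (`spatial_corner`) and
covariate-biased (`covariate_low_tail`, selection probability
proportional to the rank-inverse of the first covariate).

What a green test on these worlds establishes: the algorithms behave as
specified on smooth, Gaussian, stationary fields with known structure.
What it does not: robustness to skewed or multimodal sensor
distributions, variogram-exact spatial structure, anisotropy, or the
strong covariate redundancy of real terrain suites. Real-data behaviour
(e.g. absolute KL levels, COOBS count magnitudes) will differ.

## Known limitations

* Raster I/O is plain-text ASCII grid only; no reprojection or
  resampling — misaligned stacks are an error, by design.
* Exact COOBS is quadratic in `r`; use approximate mode beyond ~10⁴
  cells.
* The annealing proposal distribution is simple (single-cell swaps); very
  large `n` may anneal slowly.
* aHELS treats strata marginally, not as a full k-dimensional hypercube;
  this is the intended simplification, but it cannot target joint gaps
  that are invisible marginally.
* Relocation inevitably degrades a small-`n` cLHS design's divergence
  (see above); treat the similarity threshold as a site-quality
  guarantee, not a design-quality one.
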