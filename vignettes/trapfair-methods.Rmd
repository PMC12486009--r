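---
title: "Auditing area-level traffic exposure aggregation: methods and design"
author: "trapfair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing area-level traffic exposure aggregation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological studies routinely assign traffic-related air pollution
(TRAP) exposure to people through area-level summaries — a census block
group, tract or ZIP code tabulation area (ZCTA) gets one number, and every
resident inherits it.  How the road network is collapsed into that one
number matters.  `trapfair` implements three aggregation measures in common
use and audits two of them against the third, parcel-based one, asking two
questions:

* **Accuracy** — do the cheap measures rank neighborhoods the way the
  parcel-based reference does?
* **Fairness** — when they misrank, is the error systematically related to
  who lives there (racial composition, material deprivation)?  An exposure
  proxy whose error is correlated with demographics will bias any
  downstream health model that uses it, even if the average error is small.

## The three measures

All geometry is planar, in projected meters; distances are 2-D Euclidean.
For an areal unit $U$ with polygon centroid $c$, road segments $i$ with
annual average daily traffic $\mathrm{AADT}_i$ and truck component
$\mathrm{tAADT}_i$:

**EJ-Screen-style centroid proximity.**
$$E(U) = \sum_{i \,:\, d_i \le r_e} \frac{\mathrm{AADT}_i}{\max(d_i, d_0)},$$
where $d_i$ is the distance from $c$ to the nearest point of arterial
segment $i$, $r_e = 500$ m and $d_0 = 1$ m.  The published EPA indicator
this emulates is described only as a "distance-weighted" sum; we adopt the
inverse-distance form with a 1 m floor so a road through the centroid
cannot contribute an unbounded weight.  A segment qualifies whole or not at
all — proximity is a point-distance concept, so no length clipping is
applied here.

**AADT density.**
$$D(U) = \frac{1}{|U|} \sum_i \mathrm{AADT}_i \cdot \ell_i(U),$$
where $\ell_i(U)$ is the length of segment $i$'s geometric intersection
with $U$.  Every road class counts, and clipping conserves length exactly
across a partition (a segment crossing $k$ units contributes its full
in-county length in total).

**Parcel truck-traffic proximity (the reference).**  Each residential
parcel $p$ in $U$ receives a score $s_p$: the sum (default; a median
variant is available) of $\mathrm{tAADT}_i$ over arterial segments within
$r_p = 400$ m of the parcel point, 0 if none.  $P(U)$ is the
household-size-weighted median of $\{s_p\}$: the smallest score at which
the cumulative household weight reaches half the total.  The weighting
reflects that the measure is about where people actually live, not about
land area.

Units with no qualifying roads or no residential parcels receive exposure
0, not missing: the decile transform downstream needs complete vectors, and
a unit nobody's measure can see is genuinely at the bottom of the exposure
ranking.  The `n_parcels_used` column flags empty units for sensitivity
checks.

The reference's verbal definition admits two readings — a median of truck
AADT versus a fraction of parcels near arterials; we implement the
truck-AADT median as the primary definition, with the per-parcel reducer
switchable, and make no claim about which variant any particular published
analysis used.

## Agreement and fairness statistics

Within each geographic level, each measure's values are transformed to
deciles by average rank then `ceiling(10 r / n)` — rank-based rather than
value-based binning, so the transform is reproducible under ties and
invariant to monotone transforms (tie handling in published analyses is
rarely stated; this is the package's choice).  Agreement of a candidate
with the reference is summarized three ways:

* **good agreement**: fraction of units whose deciles differ by at most 1;
* **Cohen's kappa**: unweighted chance-corrected exact-match agreement
  (a linear-weighted variant is behind a flag, not the default);
* **Kendall's tau-b**: tie-corrected rank correlation — the tie correction
  matters because decile vectors are heavily tied.

Fairness is operationalized on the *error* scale: for each unit,
`error = candidate decile − reference decile` (an integer in $[-9, 9]$ —
the only scale on which the three measures are commensurable).  Errors are
regressed on each covariate by ordinary least squares with an intercept and
the classical homoskedastic 95% t-interval; a CI excluding zero flags a
systematic association.  Covariates are z-scored by default so slopes are
in decile-errors per covariate SD and comparable across covariates
(raw-scale fitting is a flag).  No robust or spatial error structure and no
multiple-testing adjustment are applied: the audit reports 12 unadjusted
CIs (3 levels × 2 measures × 2 covariates) and leaves their joint
interpretation to the reader.  Kendall's tau-b between error and covariate
accompanies every regression.

## The synthetic county generator

`generate_county()` exists so that the whole pipeline is testable without
any external geodata.  It emulates the *structure* the analysis relies on,
not any particular place:

* **Nested partitions.**  Block groups, tracts and ZCTAs are built by
  recursive rectangular subdivision, so nesting is exact and `parent_id` is
  well-defined.  (Real ZCTAs only approximately nest in nothing; since each
  level is analyzed independently, exact nesting is a harmless
  simplification.)  The tract count is `ceiling(n_block_groups / f^2)` and
  the ZCTA count `ceiling(n_tracts / f^2)` with `f = tracts_per_side_factor`;
  the defaults (697 block groups, f = 2 → 175 tracts, 44 ZCTAs) give a
  county of the same order as a mid-size U.S. urban county's 697/222/57
  grid without reproducing it exactly — arbitrary exact counts at three
  levels are incompatible with grid subdivision.
* **Roads.**  A few long wiggly highways crossing the county plus ~2,100
  short random chords.  AADT is log-normal
  (`aadt_log_mean = 10.92`, `sd = 0.9`, i.e. a mean of roughly 75,000
  vehicles/day, matching the heavy-tailed volumes of a primary-road
  inventory whose county total is on the order of $1.7 \times 10^8$);
  per-segment truck fractions are Beta around `truck_fraction_mean = 0.08`,
  a typical urban truck share.  Road sparsity is deliberate: many units
  have no arterial within radius, exercising the zero-exposure path.
* **Parcels.**  20,000 points from a truncated mixture of 40 Gaussian
  clusters (σ = 1,200 m), ~92% residential, household sizes
  `1 + Poisson(1.5)` — sizes are kept ≥ 1 so no residential parcel drops
  silently out of the weighted median.
* **Demographics.**  Per-unit fraction non-Hispanic Black and a material
  deprivation index are tied to the unit's road-length density through a
  Gaussian copula: with target Spearman correlation $r$, the latent normal
  correlation is $2\sin(\pi r / 6)$, and marginals are Beta(1.6, 4.8) and
  Beta(4, 6) — unimodal, bounded shapes with means near 0.25 and 0.4.  The
  knob `demographic_road_correlation` (default 0.45) is the injection
  mechanism for fairness experiments: at 0 demographics are independent of
  traffic, and the audit's significance rate must be nominal.  The joint
  demographic distribution is synthetic-only machinery — no claim is made
  that any real county's covariates follow a Gaussian copula against road
  density.

What the generator does **not** emulate: street topology and routing,
population density gradients within units, spatially autocorrelated
covariates beyond the road-density link, geodesic coordinates, or the
block-versus-block-group distinction in pre-computed EJ-Screen products.
Passing tests on synthetic counties therefore validates the *computational
pipeline and its statistical calibration*, not the substantive conclusions
one would draw from any real county.

## Numerical and degenerate-input choices

* Point-to-segment distances are exact (projection onto the segment,
  clamped); clipped lengths are exact (parametric intersection of each road
  edge with every polygon edge, midpoint-in-polygon classification of the
  pieces).  Both are verified in the test suite against independent
  point-sampling oracles to 0.1% relative tolerance.
* A polygon with fewer than 3 vertices or zero area is a hard geometry
  error; a unit with no parcels is not an error (zero-exposure convention).
* A fully tied decile vector makes tau-b's denominator zero: the package
  returns `NaN` with a warning rather than failing, so a degenerate
  (e.g. roadless) run completes with the degeneracy visible.  Kappa with
  both raters constant and equal returns 1 (agreement is perfect).
* Deciles with `n < 10` simply occupy a subset of the 10 bins; the
  ceiling map keeps every output in 1..10.
* GeoJSON and demographics CSV are written at 17 significant digits, so a
  write/read cycle is bit-exact and a file-driven run (`run_real`)
  reproduces the in-memory run exactly.
* Geographic-looking coordinates (every point inside ±180 × ±90) are
  rejected with an instruction to project: metric buffers on degrees would
  be silently wrong.
* Demographics provided at only some levels are completed by convention:
  coarser units take the area-weighted mean of their children; finer units
  inherit their parent's record (the realistic case of a tract-level
  deprivation index applied to block groups).

## Validation sizes

The shipped validation uses problem sizes chosen to make Monte-Carlo error
small relative to the tolerances tested: spatial oracles on 24 hand-built
geometries of ≤ 10 segments; rank-statistic oracles on 100 random vectors
of n ≤ 50; null calibration of the fairness CI at n = 222 units × 500
replicates (nominal 5% exclusion; a 222-unit vector is the tract-scale
case); slope-injection recovery at n = 222 × 200 replicates (±0.03
tolerance on a −0.15 slope ≈ 6 standard errors of the replicate mean).
End-to-end determinism and round-trip checks run on a 48-block-group
county — large enough to exercise every level, small enough to re-run in
seconds.

## Known limitations

* The EJ-Screen emulation computes proximity at the reporting unit's own
  centroid; pre-computed national products are built from finer (block)
  centroids and possibly population weighting, which this package does not
  replicate.
* OLS with homoskedastic errors ignores spatial autocorrelation among
  units; flagged associations are descriptive, not causal.
* The geometry engine handles simple polygons without holes; multipolygon
  units must be supplied as their largest ring or pre-dissolved.
* GeoJSON is the only geometry format read or written.
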