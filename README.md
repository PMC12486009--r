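# trapfair

Fairness audit of area-level traffic-related air pollution (TRAP)
exposure aggregation.

## What problem this addresses

Health studies usually cannot measure TRAP at each residence, so they
assign every person the exposure of their census block group, tract or
ZCTA.  That one number per areal unit can be built several ways, and the
choice is not neutral: different aggregations rank the same neighborhoods
differently, and if the *error* of a cheap aggregation is correlated with
who lives in a neighborhood, the proxy quietly builds demographic bias
into every downstream model.

`trapfair` is for exposure-assessment and environmental-justice
methodologists.  It implements three common aggregations and audits two of
them against the third:

* **EJ-Screen-style centroid proximity** — inverse-distance-weighted sum
  of AADT (annual average daily traffic) over arterial segments within
  500 m of the unit centroid:
  `E(U) = Σ_i AADT_i / max(d_i, 1 m)` for segments with `d_i ≤ 500 m`;
* **AADT density** — AADT weighted by clipped segment length per unit
  area: `D(U) = Σ_i AADT_i · ℓ_i(U) / |U|`;
* **parcel truck-traffic proximity** (the reference) — household-size
  weighted median, over residential parcels in the unit, of each parcel's
  summed truck AADT on arterial segments within 400 m.

Measures are transformed to within-level deciles; agreement with the
reference is summarized by the fraction of units within one decile
("good agreement"), unweighted Cohen's kappa, and Kendall's tau-b.
Fairness is the regression of decile errors (candidate − reference) on
the unit's fraction of non-Hispanic Black residents and on a material
deprivation index, with 95% CIs; a CI excluding zero flags a
demographically patterned error.

A seeded synthetic county generator (nested rectangular census geography,
heavy-tailed road traffic, clustered parcels, and a Gaussian-copula knob
linking demographics to road density) makes the whole pipeline testable
and calibratable without any external geodata.  See the methods vignette
(`vignettes/trapfair-methods.Rmd`) for the model, its assumptions and the
design decisions.

## Worked example

```r
library(trapfair)

cfg <- county_config(county_width = 16000, county_height = 14000,
                     n_block_groups = 96, n_road_segments = 300,
                     n_parcels = 3000, parcel_cluster_count = 12,
                     parcel_cluster_sd = 900, seed = 2026)
audit <- run_pipeline(cfg)
print(audit)
```

```
Traffic exposure aggregation audit (trapfair 0.1.0)
Levels: block_group, tract, zcta 

Agreement with the parcel truck-traffic proximity (deciles):
       level      measure good_agreement_fraction  kappa   tau n_units
 block_group    ej_screen                   0.490  0.042 0.323      96
 block_group aadt_density                   0.396 -0.027 0.362      96
       tract    ej_screen                   0.375  0.123 0.107      24
       tract aadt_density                   0.458  0.106 0.356      24
        zcta    ej_screen                   0.500  0.200 0.000       6
        zcta aadt_density                   0.500  0.000 0.149       6

Fairness: decile-error regressions on demographics (slope per covariate SD):
       level      measure         covariate  slope ci_low ci_high    tau
 block_group    ej_screen deprivation_index  0.320 -0.323   0.963  0.083
 block_group aadt_density deprivation_index  0.836  0.251   1.421  0.214
 ...
1 of 12 error regressions have a 95% CI excluding zero
```

Reading this: at the block-group level 49% of units land within one decile
of the reference under the EJ-Screen-style measure; kappa near 0 says
exact decile matches are no better than chance; and one of the twelve
error regressions (AADT density vs deprivation, 0.84 decile-errors per
covariate SD, CI 0.25–1.42) is flagged — in this synthetic county the
density measure over-ranks exposure in more deprived block groups.
`summary(audit)` adds zero-exposure diagnostics and `plot(audit)` draws
the error-vs-covariate scatters with tau annotations.  With
`output_dir =` set, `run_pipeline()` writes all exposure, decile, error,
agreement and fairness tables as CSV, byte-identically across reruns of
the same config.  `run_real()` runs the identical audit on your own
GeoJSON/CSV county files (projected meters only); `write_county()` /
`read_county()` round-trip a synthetic county through those formats
exactly.

A thin command-line front end with verbs `simulate`, `measure`, `agree`,
`fairness`, `run` and `run-real` is installed at
`system.file("cli", "trapfair.R", package = "trapfair")`.

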