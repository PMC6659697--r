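# issaconn

Competing hypotheses of functional landscape connectivity — **corridors**,
**least-cost paths**, and **stepping stones** — on GPS movement tracks with
integrated step selection analysis (iSSA).

`issaconn` is aimed at movement ecologists who want to ask not just *what
habitat an animal selects* but *which theory of connectivity best explains
its movement* across a heterogeneous working landscape containing a
protected-area network. Because high-frequency telemetry from such studies
is rarely public, the package ships a complete synthetic counterpart: a
seeded landscape generator with a 15-class feature schema (natural,
anthropogenic, and protected-area features of polygonal and linear
geometry), and a biased correlated random-walk simulator whose candidate
choice is the exact generative dual of the fitted model — so the whole
pipeline, including hypothesis recovery, is testable end to end.

## The model

Movement is decomposed into steps between consecutive GPS fixes (nominally 5
minutes apart). Each observed ("used") step is matched with k = 10 random
"available" steps drawn from the individual's fitted log-normal step-length
distribution and uniform turning angles, forming a stratum. Habitat is
summarized at every candidate end point by two covariate families over the
15 feature classes: truncated distance-to-feature (cap 1000 m) and density
in a 106-m buffer (raster pixels per m², the mean step length setting the
radius). Conditional logistic regression maximizes the stratified partial
likelihood

    l(beta) = sum_s [ beta' x_used(s) - log sum_{j in s} exp(beta' x_j) ]

with the movement kernel itself (ln step length, cosine turn angle) entering
as model terms — the "integrated" part of iSSA. Five candidate models are
fitted per individual and competed by AIC:

| model | terms beyond the core |
|---|---|
| core | cosTurnAngle + lnStepLength + forest distance/density + wetland distance |
| corridor | density × previous-step density (forests), distance × previous-step distance (linear features) |
| least-cost paths | forest density × lnStepLength, forest density × cosTurnAngle |
| stepping stone | protected-area distance/density, PA density × movement kernel, PA density × previous PA density |
| global | union of all terms, screened at pairwise |r| ≥ 0.7 |

Akaike weights, per-individual ranks, and rank-1/rank-2 tallies per
hypothesis summarize the competition. "Previous step" effects appear only as
current × previous interactions: a lagged main effect is constant within a
stratum and structurally inestimable under exact conditioning.

The conditional-logistic engine (Newton–Raphson on the partial likelihood
with step halving, Wald inference, AIC, within-stratum concordance) is
implemented in the package and cross-checked against `survival::clogit` in
the test suite.

## Worked example

Simulate three animals under corridor-style selection on a synthetic
landscape, build the case-control design, and compete the five models:

```r
library(issaconn)

cfg <- run_config(
  seed = 42, n_individuals = 3, n_fixes = 1500, framework = "corridor",
  landscape = landscape_config(extent_m = c(8100, 8100),
                               seed = derive_seed(42, "landscape")),
  output_dir = file.path(tempdir(), "demo")
)
res <- run_pipeline(cfg, verbose = FALSE)
res$competition
#> <competition_result> 3 individual(s), 0 excluded
#>            model rank1 rank2
#> 1           core     0     0
#> 2       corridor     3     0
#> 3            lcp     0     0
#> 4 stepping_stone     0     1
#> 5         global     0     2
```

The corridor model is the top-ranked model for all three simulated
individuals. For one individual:

```r
subset(res$competition$table, individual_id == "sim01",
       c(model, n_terms, aic, delta_aic, akaike_weight, concordance, rank))
#>           model n_terms  aic delta_aic akaike_weight concordance rank
#>            core       9 6336      74.8      5.59e-17       0.717    3
#>        corridor      15 6262       0.0      1.00e+00       0.723    1
#>             lcp      15 6338      76.5      2.39e-17       0.717    4
#>  stepping_stone      14 6330      68.7      1.23e-15       0.717    2
#>          global      17 6372     110.0      1.27e-24       0.712    5
```

The corridor model takes essentially all of the Akaike weight (Δ AIC ≈ 75
over the core habitat model); its concordance (share of used/available
pairs the linear predictor ranks correctly) is about 0.72. All artifacts —
ASCII-grid rasters, telemetry CSV, the case-control table, per-model fit
JSONs, competition and tally CSVs, and a manifest — are written under
`output_dir`, and a rerun with the same config is bit-identical. Real
telemetry read with `read_telemetry()` can replace the simulation step via
`run_pipeline(cfg, tracks = ...)`.

A thin command-line front-end over the same pipeline lives at
`inst/scripts/run_pipeline.R`.

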