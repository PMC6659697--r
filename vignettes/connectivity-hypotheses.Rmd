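---
title: "Competing connectivity hypotheses with integrated step selection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing connectivity hypotheses with integrated step selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the statistical core

Functional connectivity — the degree to which a landscape facilitates or
impedes movement among resource patches — is usually inferred from outcomes
(gene flow, occupancy). High-frequency GPS telemetry lets us test the
*process* instead: given where an animal was and where it could have
stepped, which theory of connectivity best predicts where it actually went?

`issaconn` frames three classic theories as candidate models in an
integrated step selection analysis (iSSA) and competes them per individual
by AIC:

* **Corridor**: movement follows structurally self-similar features, so
  habitat covariates of consecutive steps correlate positively.
* **Least-cost paths (LCP)**: the landscape is a continuum of movement
  costs; step length increases, and tortuosity decreases, with the local
  density of costly features.
* **Stepping stone**: discrete patches (here, protected areas) anchor
  residency — short tortuous steps inside, long linear transits between.

Every used step is matched to `k = 10` available steps sharing its start
point, and selection is estimated by conditional logistic regression on the
strata. The partial likelihood

$$\ell(\beta)=\sum_s\left[\beta^\top x_{\text{used}(s)}
  -\log\sum_{j\in s}\exp(\beta^\top x_j)\right]$$

conditions out everything constant within a stratum. Two consequences shape
the package design:

1. The movement kernel must enter as covariates (`ln_step_length`,
   `cos_turn_angle`) — this is what makes the analysis *integrated* rather
   than a plain step selection function.
2. "Previous step" effects are representable **only** as current-by-previous
   interactions. A lagged covariate alone is constant within its stratum and
   structurally inestimable under exact conditioning; `fit_clogit()` drops
   such columns with a warning rather than returning meaningless huge
   standard errors.

## Covariate engineering

Two covariate families are computed at candidate end points for each of the
15 feature classes:

* `dist_<class>`: Euclidean distance (m) from the point to the nearest cell
  *center* of the class, capped at 1000 m (`distance_truncation_m`); a point
  whose own cell belongs to the class is at distance 0. Distances are
  point-to-cell-center rather than point-to-edge because cell centers make
  the computation unambiguous and exactly checkable against an exhaustive
  scan; the choice only shifts distances by a sub-cell offset.
* `dens_<class>`: number of class cells whose centers fall within the 106-m
  buffer, divided by the area represented by *all* in-extent cell centers in
  the buffer (cell count × cell area). The 106-m radius is the mean observed
  step length at a 5-minute interval, so the buffer covers roughly one step
  of habitat. The cell-count denominator (rather than the geometric circle
  area) keeps two identities exact everywhere, including at the raster
  edge: a saturated buffer has density exactly $1/\text{res}^2$, and density
  is always within $[0, 1/\text{res}^2]$.

Before fitting, `scale_covariates()` standardizes every distance/density
column (current and lagged) to zero mean and unit variance *per individual*,
since models are fitted per individual; zero-variance columns are set to 0
and flagged instead of producing NaNs. The movement-kernel transforms are
left raw — they are part of the iSSA kernel, not habitat measurements.

Both covariate routines are exact: the test suite compares them against
brute-force enumeration over all cells on grids up to 50 × 50 and requires
equality to numerical precision.

## The synthetic landscape

The generator stands in for a GIS land-cover inventory of a working
landscape with a protected-area network. It emulates:

* a categorical cover partition over 11 polygonal classes (forest types,
  wetlands, grasslands, lakes, shrubs, bare ground, development, crops,
  forage) with contiguous patches, produced by thresholding smoothed
  Gaussian random fields with greedy exact-count assignment so realized
  fractions land within rounding error of their targets;
* 1-cell-wide connected linear features (streams, roads, rail lines)
  rasterized from persistent random walks to a target length density
  (km/km²);
* a protected-area overlay of log-normally sized discs and rectangles that
  may cover any land class — protected areas in working landscapes contain
  development, so the overlay is deliberately independent of cover.

Defaults: 30-m cells (satellite-inventory scale), 16.2 × 10.2 km extent (a
desk-scale analog; the tests use 5–8 km squares), patch correlation length
240 m, aspen-parkland-like composition (28% deciduous, 12% wetlands, 20%
agriculture/development), 12 protected areas of mean 1.6 km² (~12% of the
landscape). What it does **not** emulate: real geodesy or projections,
landscape gradients (climate, elevation), temporal habitat change, or the
spatial point patterns of any particular region. Passing recovery tests on
these landscapes therefore demonstrates statistical correctness of the
pipeline, not that any particular field system behaves this way.

## The movement simulator and its framework kernels

Tracks are biased correlated random walks on the landscape: per fix, `K =
20` candidate steps are drawn (log-normal lengths; wrapped-normal turns
around a small positive mean), and one is chosen with probability
proportional to `exp(utility)`. Softmax choice over candidates makes the
simulator the exact generative dual of the conditional logistic likelihood,
so hypothesis recovery is a well-posed estimation problem rather than a
hopeful analogy.

Movement defaults calibrate the null (selection-free) walk to the observed
movement statistics of a forest mustelid at 5-minute fixes: marginal mean
step 105.47 m (with `sdlog = 1`, `meanlog` is back-solved as
$\log(105.47)-\tfrac12$), mean turn 0.08 rad, turn SD 1.2 rad. One caveat
worth stating: the *signed* mean of a wrapped normal is slightly below its
pre-wrap mean (mass beyond $+\pi$ re-enters at $-\pi$); at SD 1.2 the
analytic bias is about $-0.011$ rad, which the calibration tests account
for.

The framework kernels, with `alpha` the selection strength:

* **corridor** — $u=\alpha\sum_f z_f(\text{end})\,z_f(\text{prev end})$
  over the forest densities and linear-feature distances, with $z$
  standardized by landscape-wide moments (`landscape_moments()`). The
  corridor prediction is a *positive correlation between consecutive
  steps*; its exact softmax dual is this product form — the corridor
  model's own interaction terms are the generating utility. An
  absolute-difference ("stay similar") kernel was considered and rejected:
  it is non-monotone (peaked at the previous value) in every linear model
  term, so no conditional-logistic term list detects it, and it breaks the
  generative duality the simulator is built on. Default `alpha = 0.5` per
  standardized product term.
* **lcp** — $u=-\alpha\sum_f c_f\,\text{dens}_f(\text{end})$ with signed
  class costs (default: forests $-0.5$, i.e. preferred high-residency
  cover; open and anthropogenic classes $+0.3$ to $+1$), plus movement
  modulation by the local cost-weighted density $R$: `meanlog` gains
  `lcp_len_gain * R` and the turn SD scales by `exp(-lcp_turn_calm * R)` —
  fast, straight transit through resistant cover, slow tortuous residency
  in preferred cover. The modulation is what the LCP model's
  density-by-movement interactions detect; a pure endpoint-cost utility is
  nested in the core model's density main effects and would make LCP
  recovery impossible by construction. Forest costs stronger than $-0.5$
  trap simulated animals inside patches and drain the design of contrast,
  which is why the default is moderate. Default `alpha = 2000` on the raw
  pixels/m² density scale (densities are at most $1/900$ px/m² on a 30-m
  grid, so utilities span roughly $\pm 2$).
* **stepping stone** — $u=\alpha\,\mathbf 1[\text{end in PA}]$ (default
  `alpha = 2`), plus residency modulation inside protected areas: length
  proposals scale by `pa_step_scale = 0.5` and turn SD by `pa_turn_widen =
  2`.
* **null** — $u=0$; with `alpha = 0` every framework reduces to the same
  unbiased correlated random walk (tested by a Kolmogorov–Smirnov check on
  step lengths across frameworks).

Candidates that would leave the landscape are redrawn (up to 100 rounds)
and then truncated to the boundary with a warning; the same policy (redraw,
then clamp) keeps the 1:k design intact for available steps. The collar's
movement-triggered duty cycle is not simulated; an optional `dropout_rate`
produces missing fixes to exercise burst splitting.

## Step sampling conventions

* Bursts: a gap exceeding 1.5× the nominal interval invalidates the
  spanning step and starts a new burst; the first step of every burst has
  no turn angle and is excluded from strata — matching the removal of
  steps without a preceding step.
* Zero-length steps are dropped with a warning (their log length and
  heading are undefined); observed telemetry of a moving animal at this fix
  rate has essentially none.
* The per-individual step-length distribution is the log-normal MLE on used
  steps, with the sample (n−1) SD on the log scale.
* Available turn angles are uniform offsets from the previous *used*
  heading, mirroring how the used turn is defined.

## Numerical choices in the estimator

* Newton–Raphson with step halving; convergence when the log-likelihood
  change is below 1e−8 *and* the score norm below 1e−6; at most 100
  iterations.
* Within-stratum-constant columns are dropped (warning), then a greedy
  in-order rank screen drops collinear columns, so earlier-listed terms win
  ties — deterministic and order-faithful to the model specification.
* Standard errors from the inverse observed information; two-sided Wald
  p-values per term, matching how selection coefficients are conventionally
  reported.
* Complete separation is an error naming the term, detected by a
  standardized coefficient exceeding 15 or a condition number above 1e12 of
  the *correlation-normalized* information matrix (the raw condition number
  is scale-dependent and would flag mere unit disparity).
* AIC counts only estimated (non-dropped) terms; AIC ties in the
  competition break toward parsimony, then model name order.
* Concordance is the within-stratum pair statistic: the share of
  used/available pairs the linear predictor orders correctly, ties counting
  one half — the matched-design analog of the survival c-index.

## Problem sizes and what the tests show

The suite fits in minutes on one CPU by construction: landscapes of 5–8 km
at 30 m, tracks of 1000–2000 fixes, 10 replicate individuals per framework
in the recovery experiment, 200 replicates of 500 strata for coefficient
coverage, and brute-force oracle grids up to 50 × 50. These sizes are
statistical choices — large enough that each check has power (e.g. 2
reported-SE coverage close to its nominal ~95%, decisive AIC margins under
each generating framework), small enough to iterate on. The key recovery
property — data generated under each of corridor/LCP/stepping-stone rules
selects its own model rank-1 by AIC in the majority of replicates, while
null data never promotes a hypothesis over the core model by more than 2
AIC in most replicates — is the package's central validity claim, and it is
a claim about the pipeline, not about any real animal.

## Known limitations

* The landscape generator produces stationary, isotropic patch structure;
  no riparian alignment between streams and forest, no road networks with
  topology.
* The simulator has no home range attractor, no inter-individual
  interactions, and no habitat-dependent mortality; tracks are single
  unbroken bursts unless dropout is requested.
* The corridor and LCP kernels act through the same covariate families the
  models use; a field system whose connectivity operates through unmeasured
  structure would not be recoverable, which is a property of iSSA itself,
  not of this implementation.
* No mixed-effects (population-level) conditional logistic model: fits are
  strictly per individual, and evidence is aggregated by AIC tallies.
* Rasters are plain planar-meter grids; georeferencing is limited to an
  origin and cell size (ESRI ASCII grid I/O), with no CRS handling.
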