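---
title: "Historical proximity variables for invasive species distribution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Historical proximity variables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hpvSDM)
```

## The problem

Classical species distribution models (SDMs) assume the modelled species is
at equilibrium with its environment: every suitable site is equally
accessible. A spreading invader violates this premise badly. During the
*space infilling* phase of an invasion, the species occupies only the part
of the suitable area it has managed to reach, and its patchy distribution
is strongly spatially autocorrelated — driven by propagule pressure from
nearby populations, not by habitat alone. Models fitted to environmental
predictors only therefore confuse "unsuitable" with "not yet reached".

Historical proximity variables (HPVs) address this by injecting the
species' own past distribution into the predictor set. An HPV is a raster
that summarizes the state of the invasion a fixed number of years before
the response snapshot, at one of three information capacities:

* **Presence (P)** — 1 where a population already existed in the cell (low
  capacity);
* **Count (C)** — the number of populations in the cell (moderate);
* **Distance (D)** — great-circle distance from the cell to the nearest
  population (high capacity, and the carrier of the dispersal signal).

The time lag between the response data and the HPV's source distribution is
the **minimal recentness** (5, 10 or 25 years here). Crossing the four
capacity codes {P, C, D, CD} with the six usable period combinations
{5}, {10}, {25}, {10,5}, {25,10}, {25,10,5} yields 24 HPV predictor-set
variants, plus a "No HPV" control with environmental predictors only
(`enumerateVariants()`). Because a model with a distance HPV effectively
estimates occurrence probability as a function of habitat *and* of distance
to the earlier distribution — a site dispersal curve — the approach is
quasi semi-mechanistic: the time lag is explicit, so the fitted spatial
dependence has a rate-of-spread interpretation.

## Building HPVs from dated records

The unit of observation is a dated population record: location, the
**onset year** (earliest known existence) and the census year in which the
site was verified. Three rules govern the bookkeeping
(`occurrence_history` functions):

* records whose exact onset is unknown get a decennial estimate, the middle
  year of the decade (`decennialOnset(1970)` is 1975);
* populations within 500 m of one another are one population:
  single-linkage clusters at that radius are merged, keeping the earliest
  onset, the latest census year and the centroid (`dedupePopulations()`);
* the period-*p* subset holds the records with
  `onset_year <= response_year - p` (`subsetByRecentness()`); these subsets
  are nested, so distance layers increase and count layers decrease
  pointwise with growing recentness — a property the tests assert.

Rasterization uses a regular lon/lat grid of 1/120 degree (~1 km) cells,
half-open so a point on a shared edge belongs to the cell to its
east/south, row 0 north. All distances, everywhere in the package, are
haversine great-circle distances on a sphere of radius 6,371,008.8 m,
measured from cell centers. The source material did not record which
metric its raster toolchain used; great-circle from centers is the
unambiguous choice for an unprojected grid and is frozen here as the
package's convention. Rasters travel as ESRI ASCII grids (plain text,
`writeAsciiGrid()`), points as CSV or GeoJSON.

## Models, evaluation, ensembles

Seven single-model algorithms run behind one scorer contract
(`fitAlgorithm()`): random forest, gradient boosting, a classification
tree, a feed-forward neural network, an adaptive hinge-basis (MARS-family)
logistic lasso, a flexible discriminant realized as a linear discriminant
on the same hinge basis, and the surface range envelope (SRE), the
classical presence-quantile envelope that scores 0/1. Algorithms with
restrictive error-distribution assumptions (GLM, GAM) and MAXENT are
deliberately out of scope. The MARS and FDA members are functional
stand-ins built from hinge bases plus penalized/discriminant fits: the
study treats algorithms as interchangeable black boxes whose evaluation
score is the object of interest, so the model *family* matters, not a
particular implementation's internals.

Quality is the **true skill statistic**, TSS = sensitivity + specificity −
1, maximized over a threshold grid of step 0.001 with the smallest
threshold taken on ties; ROC AUC (rank formulation, ties averaged) is the
companion measure. Evaluation uses stratified random splits (default 80/20,
3 repetitions — the split protocol is a package default, configurable,
since the source protocol is not fully documented). Single models with
held-out TSS ≥ 0.7 enter the ensemble; six combination statistics are
computed (`buildEnsemble()`): mean, TSS-proportional weighted mean, median,
committee averaging (member predictions binarized at each member's optimal
threshold, then averaged), and the lower/upper normal-approximation
confidence bounds of the member mean (mean ∓ 1.96·sd/√m, clipped to
[0, 1]). The weighted-mean weights and the CI construction are package
decisions where the original toolkit's exact formulas are undocumented.

## The meta-model

To ask *what drives model quality*, all evaluations are melted into a long
table (`meltResults()`): one row per model run, annotated with the
algorithm, the capacity code, the minimal recentness, the number of
periods, and the single/ensemble group, with TSS z-scored within group so
the two groups share a scale. A shadow-feature importance analysis
(`borutaImportance()`) then classifies each attribute: per iteration, a
permuted copy of every attribute is appended, a random-forest regressor is
fitted, and an attribute scores a "hit" when its importance Z-score (mean
permutation importance over trees / its sd) exceeds the best shadow's.
Hit counts are tested against Binomial(iterations, ½) at p = 0.01:
significantly high is Confirmed, significantly low Rejected, else
Tentative. Categorical attributes are passed to the forest natively as
factors, which yields one importance score per attribute directly; a
one-hot encoding with per-attribute aggregation was considered and dropped
as an unnecessary indirection. Attributes still Tentative after the
iteration budget are reported as such, never forced.

Power is a design parameter here: the forest size per iteration sets the
smallest association the procedure can distinguish from sampling noise.
The package default (200 trees) suits real melted-results tables, where
effects of interest are large; the planted-signal checks in the test suite
use deliberately small forests (8 trees × 100 iterations) so that a
correlation of 0.9 is confirmed while the spurious sample correlations
(|r| ≈ 0.05–0.1 at n = 500) that any fixed noise draw contains stay below
the detection threshold and are rejected.

## The synthetic study generator

No occurrence data are shipped; `makeStudy()` generates a complete study
in the spirit of the motivating system (a persistent riparian invader
censused over ~116,000 km², 101 dated localities in a 2007 field census,
628 presences in a 2012 snapshot):

* **Landscape** (`generateLandscape()`): eight spatially autocorrelated
  standardized fields on a 200 × 200 cell grid (1/120°, centered near
  52° N) — white noise smoothed with a separable Gaussian kernel
  (sd = half the 15-cell autocorrelation scale), then z-scored. True
  suitability is logistic in a weighted sum of the first four layers
  (weights 0.4, −0.3, 0.2, 0.15; four layers are pure nuisance).
* **Invasion** (`simulateInvasion()`): five foci seeded in 1980 in
  high-suitability cells (sampled suitability-weighted from the top
  quintile); each extant site emits 3 propagules/year with exponential
  dispersal (mean 2 km) and a 1% chance of a uniform long-distance jump
  (≤ 100 km); a propagule establishes with probability equal to the
  suitability of its landing cell; sites persist indefinitely by default
  (the emulated species holds sites for > 50 years). The grid boundary is
  absorbing. Onsets before 1997 are decennially coarsened, emulating
  dated-by-decade historical records. The 2007 occupancy is the census,
  the 2012 occupancy the response; simulation continues five further years
  so forecasts can be scored against ground truth.

The intercept (−3.5, a baseline establishment probability of ~0.03) was
fixed once so that the census-year analogue holds on the order of a
hundred sites and the response snapshot a few hundred — the scale of the
motivating data. This puts the simulation in the regime the method is
about: habitat is broadly adequate and only weakly variable, so occupancy
is governed by dispersal history, and most suitable area is still empty at
the census.

What the generator does *not* emulate: observation error and uneven survey
effort, landscape anisotropy (rivers, roads), extinction–recolonization
dynamics, and the coarse, partly categorical nature of real environmental
rasters. Two consequences matter for interpreting test output. First,
because the synthetic environmental fields are smooth and noiseless, even
the "No HPV" control attains high absolute TSS (~0.85 rather than the
weak values typical of real control models): the fields act as implicit
spatial coordinates. The package therefore asserts *orderings* — distance
HPVs beat the control, more recent HPVs beat older ones, distance beats
presence — pooled as medians across ten replicate invasions, not absolute
TSS values, which are not transportable from simulation to field data.
Second, invasion sizes vary strongly across seeds (failed introductions
through pocket saturation); the replicate design absorbs this.

## Projection scenarios

`projectMap()` scores every cell of a predictor stack. Substituting HPV
layers gives the scenario maps:

* **Forecast** (`forecastStack()`): HPV layers recomputed from the
  *current* sites; the projection reads as the map at (present + minimal
  recentness). Iterating is possible via `thresholdToSites()` (cells above
  the ensemble's optimal threshold become pseudo-sites), with the caveat
  that the environmental predictors should be refreshed between steps if
  they change.
* **Potential** (`potentialStack()`): distance layers set to a constant
  (default 0, exposed as the fill), presence/count layers to a saturating
  1 — the probability of final space infilling.
* **Emergence / unsaturation** (`emergenceMap()`, `unsaturationMap()`):
  forecast − current and potential − current, highlighting where new sites
  should appear and which suitable areas remain unreached.

Identity substitution (current sites = HPV source sites) reproduces the
current map bit-exactly, a property the tests assert, and on synthetic
studies the five-year forecast scores AUC ≈ 0.99 against the simulator's
true year + 5 occupancy.

## Numerical and design choices

* Threshold grid step 0.001 with smallest-argmax tie-break: deterministic
  at desk-scale case counts.
* One pseudoabsence per cell, presence cells excluded, drawn uniformly
  from the mask (`samplePseudoabsences()`); excluding presence cells is a
  package decision (it avoids label noise and leaves the 1628-case
  contract intact). Multiple independent pseudoabsence sets are supported.
* nodata propagates: any missing predictor makes the projected cell NA;
  model-matrix rows with missing predictors are dropped with a logged
  count.
* Non-converging fits are flagged and excluded from ensembles rather than
  raising; an ensemble with no gate-passing member is an explicit error.
* One master seed spawns named per-stage seeds (`deriveSeed()`), so any
  stage can be re-run independently and identically.
* Problem sizes used by the test suite and the acceptance script — ten
  replicate 200 × 200 studies, three split repetitions, the reduced
  RF/GBM/SRE algorithm set for the factorial runs, 100 × 8-tree
  meta-model iterations — were chosen as the smallest sizes at which the
  pooled orderings are stable across seeds.

## Known limitations

* The package models cell-level occupancy at a fixed ~1 km grain; real
  population extents and sub-cell structure are out of scope.
* HPVs assume the historical record is complete enough that distance to
  the nearest *known* earlier site is meaningful; strongly biased
  historical records will bias the dispersal signal.
* The absolute quality scores reported on synthetic studies are not
  comparable to field studies (see the generator section); the package's
  claims are structural and ordinal.
* Reprojection, irregular grids and dispersal-constrained cellular
  automata are explicitly not provided.
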