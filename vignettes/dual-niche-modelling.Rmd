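---
title: "Dual climate–soil niche modelling with tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual climate-soil niche modelling with tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

`dualniche` models the joint habitat suitability of a desert host shrub and
an obligate parasitic plant from presence records and gridded environmental
layers. The ecological setting has three structural features that shape the
whole design:

1. **Two semi-independent environmental axes.** Climate varies smoothly and
   will shift under warming scenarios; soil properties (type, texture,
   water-holding capacity) vary patchily and are treated as temporally
   static. A single pooled model tends to let the smooth climate gradients
   swamp the patchy soil signal, so climate and soil suitability are fitted
   as *separate* models and combined afterwards.
2. **The "barrel effect".** A site is only as suitable as its least
   favourable requirement. The combined suitability of a cell is the
   per-cell *minimum* of its climate and soil suitabilities
   (`min_overlay()`), not their product or mean.
3. **Obligate parasitism.** The parasite cannot occur without its host, so
   its final suitability is the minimum of its own climate suitability, a
   soil suitability, and the host's combined suitability
   (`host_constrained_suitability()`). Nesting of the parasite's range
   inside the host's is then a mathematical guarantee, which the test suite
   verifies rather than assumes.

## The model

Each suitability model is a four-member ensemble: two random forests and two
gradient boosted tree classifiers, each at a "simple" and an "intermediate"
complexity setting (`default_ensemble_configs()`; defaults
RF 100×d6/l10 and 300×d∞/l2, GBDT 100×d2/η0.1 and 400×d4/η0.05). Tree
ensembles are used because the responses are non-linear and interactive, and
because integer-coded soil classes can be fed directly as split variables
without one-hot encoding. The ensemble prediction is the plain mean of the
four member probabilities; the final surface is additionally averaged over
the cross-validation iterations below. Averaging across members and
iterations is the main variance-control device — no stacking or weighting is
attempted.

### Training data

Presences are thinned to at most one record per grid cell
(`thin_occurrences()`, seeded uniform tie-break), mirroring the standard
1-km deduplication used to damp sampling bias. Because true absences do not
exist, pseudo-absences are sampled from a *dual-filtered* eligibility space:

* `environmental_profile_mask()` — a cell is withheld (ineligible) when its
  value lies inside the presence envelope (5%–95% quantiles by default) on
  *every* continuous layer; being an environmental outlier on at least one
  axis makes it eligible.
* `kmeans_eligibility()` — all valid cells are clustered (k = 8, 5 runs by
  default) in standardized environmental space; clusters in the lowest
  quartile of presence density are flagged, and a cell is eligible when
  flagged in a majority of the seeded runs. Majority voting is used because
  averaging raw cluster labels across runs is undefined under label
  switching; the vote preserves the intent (stability against K-means
  initialization) with a well-defined operator.

The final eligibility is the intersection of the two masks. Neither k, the
number of runs, nor the envelope quantiles have canonical values; they are
package defaults, exposed in the API. Each sub-model (climate, soil) applies
the protocol in its *own* predictor space — profiling the soil model against
climate layers would withhold soil-informative cells for climate reasons.

### Spatial block cross-validation

The landscape is tiled into contiguous square blocks (default: a fifth of
the short side, giving 25 blocks), and in each of 10 iterations 70% of the
blocks (round half up) train the ensemble while 30% validate it
(`make_blocks()`, `split_blocks()`). Pseudo-absences are redrawn *per
iteration*, matched to the per-block presence counts of each partition, so
every training and validation set is balanced and spatially separated from
its counterpart. When a presence-rich block has too few eligible cells, the
shortfall is redistributed within the same partition; when an entire
partition has none, that iteration is skipped with a warning rather than
silently unbalanced. Validation yields AUC (Mann–Whitney form), the optimal
threshold (maximum sensitivity + specificity over observed scores, ties to
the lower threshold), sensitivity/specificity/precision/TSS at that
threshold, and a continuous Boyce index.

### Boyce index: two deliberate choices

`boyce_index()` uses 10 overlapping windows of width 0.2, but on the
*quantile* (landscape-ECDF) axis of the suitability surface rather than the
raw HSI axis. This makes the index exactly invariant under rank-preserving
transforms of the surface — which a rank-correlation statistic ought to be —
and keeps the expected mass per window nearly equal, avoiding empty windows
on the strongly bimodal surfaces that contrastive training produces. Second,
the expected distribution E is restricted to the *validation blocks* (via
`region_mask`) when called from `run_iterations()`: presences can only be
observed there, so computing E from the whole landscape would compare P and
E across different domains and bias the index.

### Thresholds, integration, scenarios

Continuous surfaces are binarized at the *mean of the per-iteration optimal
thresholds* (≥ at the boundary, everywhere). The combined binary map is the
intersection of the per-model binary maps, each at its own threshold — the
"dual threshold" reading of co-suitability. A ±5% threshold sensitivity
table (`threshold_sensitivity()`) quantifies how fragile the mapped area is.
Scenario projection (`run_scenarios()`) shifts the standardized climate
layers additively, re-predicts with the already-fitted ensembles (training
data for a future period cannot exist, so no re-training), holds soil
static, and binarizes at the current-period thresholds. Suitable areas are
latitude-weighted spherical cell areas (R = 6371.0088 km) in 10³ km², and
per-scenario change is `(current − future)/current × 100`.

For the parasite, the Methods-style reading (its own soil model) and the
Discussion-style reading (the host's soil model) of the three-way minimum
are both supported via `parasite_soil_source = c("self", "host")`; the
default is `"self"`.

### Niche overlap

`schoeners_d()` computes `D = 1 − ½ Σ|pX,i − pY,i|` over cells valid in both
surfaces. By default both surfaces are normalized to unit sum first: with
raw `[0, 1]` HSI values the statistic can leave `[0, 1]`, contradicting its
defined range, and normalization is what makes D a comparison of
*distributions* rather than absolute calibrations. Raw mode is retained and
flagged in the report. Overlap bands are the conventional half-open 0.2-wide
intervals with the top band closed.

### Shapley attribution

`exact_shapley()` implements the Shapley value literally: full subset
enumeration (bounded at 15 features) with an interventional value function —
`v(S)` is the mean model output over a seeded background sample with the
features in S fixed to the explained point. This is chosen over polynomial
tree-path-conditional algorithms because it is the definition itself and can
be cross-checked against an independently coded permutation-form oracle,
which the test suite does on up to 5 features alongside the linear-model
closed form `φᵢ = bᵢ(xᵢ − m̄ᵢ)`. Efficiency (base + Σφ = prediction) holds to
floating-point accuracy by construction and is asserted at 1e-8. Member
matrices are averaged point-wise into an ensemble matrix
(`ensemble_shap()`); `global_importance()` ranks mean |φ|, and
`export_decision_and_dependence()` emits the cumulative decision paths
(ordered by ascending global importance, terminating exactly at each
prediction) and per-feature dependence pairs.

## The synthetic landscape

`generate_landscape()` supplies the study system with known truth. Climate
layers are seeded Gaussian white noise smoothed at a configurable
correlation length (default 6 cells on a 100×100 grid) and standardized;
soil classes are a Voronoi tessellation of seeded points (contiguous,
clumped units); AWC is a smoothed field mapped through the normal CDF. The
truth composes a logistic climate response with a soil response
(class-specific suitability × Gaussian AWC response centred at 0.55 ± 0.3)
by per-cell minima, host first, then parasite (its own shifted climate
coefficients, so the two niches overlap strongly but not perfectly).
Presences are drawn with probability proportional to truth suitability and
jittered within cells — 400 host and 200 parasite points in the benchmark
configuration, sizes chosen to be of the same order as typical curated
occurrence sets for arid-land species after deduplication.

What the generator deliberately does *not* emulate: observation/sampling
bias fields, spatially correlated label noise, real bioclim covariance
structure, coastlines and irregular nodata geometry, and GCM-specific
scenario patterns (futures are additive standardized shifts). Passing the
synthetic benchmark therefore demonstrates that the machinery is correct and
the workflow recovers known structure under clean conditions; it does not
certify performance on biased real-world occurrence data.

## Known limitations

The dual-filtered pseudo-absence design buys discrimination at the cost of
calibration. Because absences are drawn only from environments dissimilar to
presences, validation AUC/TSS are high, but the fitted probability surfaces
saturate and their *rank* fidelity against the known truth is limited: on
the benchmark landscape the Spearman correlation of the combined surface
with the final truth hovers around 0.6–0.75 depending on the seed. The
package's own known-truth experiments locate the cause in the sampling
design rather than the learners — a correctly specified parametric model
trained on the same filtered data recovers truth no better, while the same
model trained on uniform background absences recovers it almost perfectly.
This trade-off is inherent to profile-filtered pseudo-absence schemes and is
the main caveat when interpreting the continuous surfaces (the binary maps,
which only use ranks near the decision threshold, are much less affected).

Runtime-relevant sizes are package choices: the benchmark uses a 100×100
grid, 10 iterations and the four default members, which completes in well
under two minutes per species on a single core; all sizes scale through the
configuration objects.

## Interfaces

The package is function-first: `run_species()`, `constrain_to_host()` and
`run_scenarios()` are the orchestration layer, and every stage underneath is
exported and individually testable. Rasters interchange as plain-text ESRI
ASCII grids (`read_raster()`/`write_raster()`) — the long-standing text
raster format of the SDM toolchain — and occurrences as
`species_id,lon,lat,label` CSV. `scripts/acceptance.R` is the single
command-line entry point, reproducing the full benchmark from a seed.
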