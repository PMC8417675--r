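---
title: "Mining prenatal care pathways and their built-environment context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining prenatal care pathways and their built-environment context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carepathways)
```

## The analysis in one paragraph

`carepathways` studies how patterns of prenatal care relate to postpartum
depression (PPD) and to the walkability of a patient's neighbourhood. Each
patient's prenatal history is reduced to an ordered sequence of coded
clinical events (encounters, diagnoses, medication orders). Patients are
compared by a longest-common-subsequence (LCS) distance, grouped by
hierarchical clustering with the cluster count chosen by the silhouette
criterion, and each cluster's recurring care pathways are extracted with a
SPADE frequent-sequence miner. Around each patient's home, ten
built-environment indicators are measured in Euclidean buffers, and
census-tract attributes (air pollution, income inequality, education,
poverty) are joined. A recursive two-equation path model then links the
pieces: a multinomial logistic equation for cluster membership on
built-environment and demographic covariates, and a binary logistic
equation for PPD on the cluster indicators. Because the motivating EHR and
New York spatial data are protected, the package ships a seeded
synthetic-data generator that emulates the study's statistical structure
end to end; every algorithmic stage is validated against independent
oracles and planted ground truth.

## Patient sequences and the LCS distance

Events carry integer day stamps relative to delivery (day 0); the prenatal
window is `t <= 0`. `build_sequences()` restricts events to a configured
token allow-list, orders them by day with same-day ties broken
lexicographically by `(event_type, code)` — the tie rule is arbitrary but
fixed, because reproducible distances require a total order — and collapses
same-day duplicate tokens, so a pattern reflects *which* events occur and
in what order, not how often an order was re-entered that day.

For sequences $a$, $b$, $\mathrm{LCS}(a,b)$ is the length of their longest
common (not necessarily contiguous) subsequence. The package exposes three
normalised distances:

$$d_{\max} = 1 - \frac{\mathrm{LCS}(a,b)}{\max(|a|,|b|)}, \qquad
  d_{\mathrm{mean}} = 1 - \frac{2\,\mathrm{LCS}(a,b)}{|a|+|b|}, \qquad
  d_{\mathrm{sum}} = 1 - \frac{\mathrm{LCS}(a,b)}{|a|+|b|}.$$

All are symmetric, zero for identical sequences and 1 (for the first two)
when no token is shared. `lcs_distance()` defaults to $d_{\max}$, the
strictest length-mismatch penalty. The *pipeline* configuration, however,
defaults to $d_{\mathrm{mean}}$: a patient whose record holds only a
handful of events has $d_{\max}\approx 1$ against everyone, and one or two
such isolates per few thousand patients can form a runt cluster high in
the average-linkage hierarchy, flipping the silhouette choice of $k$ even
though the substantive clusters are recovered. Mean-length normalisation
keeps the same bounds while halving the penalty asymmetry, and proved
robust in our recovery experiments (k = 3 on every probe seed at
n = 2,000). Both choices remain one `normalization` switch apart.

The $O(|a||b|)$ dynamic program runs in compiled code over integer-encoded
tokens; all $n(n-1)/2$ pairs are computed exactly (about 14 s for
n = 2,000 on one core). There is no approximation or blocking artefact to
tune.

## Clustering and choosing k

`agglomerative_cluster()` delegates to `stats::hclust`. Average linkage is
the default because LCS dissimilarities carry no Euclidean geometry, which
Ward-type criteria assume. The hierarchy is built once and cut at every
candidate k (default 2–8); `silhouette_and_select_k()` scores each cut by
the mean silhouette width

$$s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))},$$

with $a(i)$ the mean within-cluster distance, $b(i)$ the smallest mean
distance to another cluster, and $s(i)=0$ for singleton clusters; ties in
the argmax go to the smaller k. The silhouette implementation is checked
in the test suite against both a direct per-point evaluation of the
formula and `cluster::silhouette`.

## SPADE pattern mining

The miner works on a vertical database: for every pattern, the list of
(patient, end-day) pairs at which an embedding ends. Patterns are ordered
lists of itemsets (the tokens recorded on one day); support counts
distinct patients once each. Depth-first search extends each frequent
pattern by single frequent items through two temporal joins: the S-step
appends the item as a new element at a strictly later day, and the I-step
adds it to the final itemset at the same day, restricted to items
lexicographically above the itemset's maximum so every pattern is
enumerated exactly once. Support pruning is exact by anti-monotonicity:
any pattern's prefix is at least as frequent.

Defaults: minimum support 0.10 of the cluster (the threshold is a config
parameter; there is no canonical value), maximum pattern length 5 items to
bound the lattice, and I-step enabled (set `use_istep = FALSE` to mine
pure event chains, which is also how reports render pathways). Outcome
splits — how many supporting patients developed PPD — are computed by an
independent containment scan rather than from the mining id-lists, which
doubles as an internal consistency check. The suite verifies exact
agreement of the pattern set and all supports with exhaustive enumeration
on hundreds of random databases.

## Built-environment indicators

All geometry is planar, in metres; real longitude/latitude layers must be
projected upstream (the synthetic region is generated in metric
coordinates). Membership tests use the closed disc. Per patient:

* counts of bus stops, subway stations and street intersections within
  500 m;
* bike-path length and light/heavy vehicle-kilometres travelled (link
  daily volume × clipped link kilometres) within 500 m, the segment–circle
  clipping solved exactly from the quadratic;
* green-space and sidewalk area within 500 m, and the land-use mix index
  $\mathrm{LUM} = -\sum_i p_i \ln p_i / \ln k$ over parcel-area shares
  $p_i$, where by default $k$ is the full 6-class taxonomy (residential,
  commercial, retail, industrial, recreation, other), so a buffer covering
  few classes scores low; zero parcel land makes LUM missing, flagged for
  imputation;
* the retail floor-area ratio in a 250 m buffer: full floor area of
  intersecting retail parcels (floor area is not spatially divisible)
  divided by clipped retail land area, 0 when no retail land intersects.

Polygon–disc intersections approximate the disc by an inscribed regular
128-gon clipped with Sutherland–Hodgman; the inscribed-area deficit is
$1 - \tfrac{128}{2\pi}\sin\tfrac{2\pi}{128} < 0.04\%$, inside the
documented 0.1 % bound and tested against Monte-Carlo oracles. Indicators
are translation-invariant and monotone in the radius by construction, and
the suite asserts both.

## The path model

The "structural equation model" here is a recursive generalized path
model with no latent variables: (1) multinomial logistic regression of
cluster membership (reference cluster absorbed) on built-environment and
adjustment covariates; (2) binary logistic regression of PPD on the
cluster indicators. For a fully observed recursive system the joint
likelihood factorises, so equation-by-equation maximum likelihood is the
joint MLE — the suite confirms this against a direct joint-likelihood
optimiser on a small instance. Odds ratios are `exp(coef)` with Wald tests
and 95 % intervals. Covariates pass an iterative variance-inflation
screen first (drop the largest VIF while any exceeds 10; exact collinear
ties drop the later-listed column). Missing cells (typically LUM in empty
buffers) are filled by chained-equation imputation — linear draws for
numeric columns, logistic draws for binary ones, m = 5 completed copies,
10 sweeps — and per-imputation fits are pooled by Rubin's rules. Group
contrasts across clusters use Pearson chi-square tests for categorical
variables and one-way ANOVA for continuous ones, skipping degenerate
(single-level or zero-variance) columns with a warning.

Separation in the outcome equation (a cluster with no cases) is detected
via exploding indicator standard errors and raised as an error naming the
term, rather than reported as a spurious huge odds ratio.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions; `simulate_study()` draws, from
one master seed, with an independent substream per table and layer (so
adding a layer never perturbs the others):

* latent care-pattern clusters with mixing proportions (0.22, 0.46, 0.32),
  echoing the reported 1,934/4,129/2,886 cluster sizes;
* per-cluster first-order Markov chains over a 25-token vocabulary of
  encounter/diagnosis/medication codes. Cluster 1 is high-complexity care
  (mental-health history, high-risk pregnancy, heavy prescribing),
  cluster 2 intermediate, cluster 3 routine. A `separation` weight
  (default 0.75) mixes each cluster's signature token distribution with a
  shared routine-care distribution; the default sits in a moderate regime
  chosen so that recovery is good but not trivial (adjusted Rand index
  ~1.0 rather than exactly forced, silhouette selecting k = 3). Event
  counts are a shifted Poisson (1 + Poisson(mean − 1), default mean 18) on
  distinct days in the pregnancy window, so timestamps strictly increase;
* a square planar region (default 12 km) with an east–west urbanicity
  gradient driving thinned-Poisson point layers (bus stops, subway,
  intersections), random polylines (bike paths; traffic links with
  lognormal light/heavy volumes), a 200 m land-use parcel grid whose
  commercial/retail share grows with the gradient, green and sidewalk
  polygons, and a tract grid carrying PM2.5, ozone, GINI, college percent,
  poverty, uninsured percent and a food-access flag that vary smoothly
  with the same gradient;
* cluster-specific home placement (Gaussians centred at 0.30/0.50/0.70 of
  the region side) — this is what plants the built-environment → cluster
  associations;
* PPD via logistic planting: probability
  $\mathrm{logit}^{-1}(\beta_0 + \ln(\mathrm{OR}_c))$ with baseline 0.0114
  in the reference cluster and default odds ratios 6.3 and 2.43 for
  clusters 1 and 2 — the effect sizes the downstream model should recover.
  PPD-positive patients receive a postpartum depression diagnosis event
  within a year of delivery, so outcome labelling can run from the event
  stream alone; emergency-department visits are injected with
  cluster-graded prenatal propensity.

What it does **not** emulate: real coding systems and their hierarchy,
within-patient care-schedule regularity (visit cadences), street-network
topology (intersections are a point process, not derived from the
network), spatial autocorrelation beyond the single gradient, informative
missingness, or confounding between the built environment and PPD that
does not pass through cluster membership. Passing recovery tests
therefore shows the *algorithms* are correct and the *pipeline* estimates
planted effects without bias at study scale — not that the substantive
findings generalise to any real cohort.

## Cohort rules and numerical conventions

* Inclusion: age 18–45 inclusive, at least one event in the encounter
  window, non-missing home location. The window is one year before a
  280-day pregnancy start through one year after delivery, i.e. days
  −645…+365; the anchoring (fixed 280-day pregnancy rather than the
  per-patient gestational length) is a documented choice, exposed as
  `window_days`.
* PPD: a qualifying diagnosis code strictly after delivery and no later
  than day 365 ("within one year" read inclusively; the boundary is
  tested on both sides).
* Trimesters: pregnancy start at delivery − 7·(gestational weeks); T1 the
  first 13 completed weeks, T2 weeks 14–27, T3 week 28 to delivery —
  standard obstetric cut-offs.
* The standard deviation of a singleton group is reported as 0, not NA.
* Silhouette of singletons is 0; argmax ties in k go to the smaller k;
  merge ties inside `hclust` follow its deterministic behaviour.
* Problem sizes used in validation were chosen to be desk-scale while
  leaving sampling noise well below the tolerances tested: n = 2,000 for
  clustering recovery, n = 50,000 × 50 replicates for odds-ratio recovery
  and coverage, 1,000 replicates for test calibration, 200 random
  databases for miner/oracle equivalence.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(sim = sim_config(n_patients = 2000, seed = 1))
run_pipeline(cfg, "run1")
report("run1")
```

The run directory then holds the synthetic bundle (`patients.csv`,
`events.csv`, `tracts.csv`, one GeoJSON per layer), the filtered cohort
and sequences, the distance matrix and labels, `patterns.tsv`,
`built_env.csv`, the model tables and a `manifest.json` with the config
hash and stage row counts. Re-running with the same configuration
reproduces every output byte for byte; `resume = TRUE` skips completed
stages.

## Known limitations

* The pairwise distance stage is exact and quadratic; n ≈ 10⁴ is
  comfortable, far beyond that is not the target scale.
* The miner returns all frequent patterns (no closed/maximal
  condensation) and supports no gap or window constraints.
* Euclidean buffers only; network-distance accessibility is out of scope.
* The imputation model is linear/logistic chained equations; it does not
  implement predictive mean matching or multilevel structure.
* Tract attributes are consumed as given — no land-use regression for
  pollutants and no travel-demand modelling for link volumes.
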