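# carepathways

Patterns of prenatal care, the built environment, and postpartum
depression (PPD): an R pipeline for clustering patients by the similarity
of their prenatal clinical event sequences, mining the care pathways that
characterise each cluster, measuring walkability and traffic exposure
around patients' homes, and fitting a path model that links neighbourhood
context to care-pattern cluster membership and cluster membership to PPD.
It is aimed at clinical informatics and epidemiology researchers working
with coded EHR event streams plus planar spatial layers — and, because such
data are protected, it ships a seeded synthetic-data generator that
reproduces the statistical structure of the design for validation,
teaching and method development.

## The method

1. **Sequences.** Each patient's prenatal events (encounters, diagnoses,
   medication orders, day-stamped relative to delivery) become an ordered
   token sequence: filtered to an allow-list, sorted by day with a fixed
   lexicographic tie-break, same-day duplicates collapsed.
2. **LCS distance.** Patients are compared by the longest common
   subsequence: `d_max = 1 − LCS(a,b)/max(|a|,|b|)` (mean- and sum-length
   normalisations are available; the pipeline defaults to mean-length,
   see the vignette). Computed exactly for all pairs in compiled code.
3. **Clustering.** Average-linkage hierarchical clustering on the
   distance matrix; the number of clusters k maximises the mean
   silhouette width `s(i) = (b(i) − a(i))/max(a(i), b(i))`.
4. **Pattern mining.** A from-scratch SPADE miner (vertical id-lists,
   S-step/I-step temporal joins, depth-first equivalence classes,
   anti-monotone pruning) enumerates every frequent sequential pattern in
   each cluster, with per-pattern PPD/no-PPD supporter splits.
5. **Built environment.** Per patient, in Euclidean buffers: bus stops,
   subway stations, intersections (500 m counts); bike-path length,
   green area, sidewalk area; light/heavy vehicle-kilometres travelled
   (volume × clipped link length); the entropy land-use mix index
   `LUM = −Σ pᵢ ln pᵢ / ln k`; the 250 m retail floor-area ratio; plus
   census-tract joins (PM2.5, O₃, GINI, college %, poverty, uninsured %,
   food access).
6. **Models.** VIF screening (>10 drops), chained-equation imputation with
   Rubin pooling, chi-square/ANOVA cluster contrasts, and the recursive
   two-equation path model — multinomial logistic for cluster membership,
   binary logistic for PPD on cluster indicators — reported as odds
   ratios with Wald intervals.

## A worked example

```r
library(carepathways)
cfg <- run_config(sim = sim_config(n_patients = 600, seed = 1), seed = 1)
run_pipeline(cfg, "run1")   # simulate -> cohort -> cluster -> mine -> features -> model
report("run1", top_n = 3)
```

```
== Run report: run1 ==
Cohort summary (n = 587)
  continuous, mean (SD):
    age                33.89 (4.63)
    bmi                23.83 (4.10)
    gestational_week   38.73 (2.08)
  ...
Clusters:
  cluster 1: n = 274, PPD 2.55%
  cluster 2: n = 181, PPD 0.55%
  cluster 3: n = 132, PPD 8.33%
  PPD x cluster chi-square = 15.52 (df 2), p = 0.000427

Top patterns per cluster (support, PPD split):
  [1] RX:ANTIHISTAMINE   238 (87%)  PPD 7 / 231
  ...
  [3] ENC:ED             110 (83%)  PPD 10 / 100
  [3] DX:ANXIETY         107 (81%)  PPD 7 / 100
  [3] DX:DEPRESSION_HX   106 (80%)  PPD 9 / 97
```

587 of 600 simulated patients survive the inclusion rules (age 18–45, an
event in the encounter window, a known home location). The three clusters
recover the planted care profiles — cluster 3 here is the high-complexity
group (emergency visits, anxiety, depression history) and carries the
highest PPD rate (8.33 %); hierarchical-clustering label numbers are
arbitrary. The chi-square line reproduces the PPD-by-cluster contrast, and
`patterns.tsv`, `built_env.csv` and `path_model.tsv` in the run directory
hold the full mined-pathway, exposure and odds-ratio tables. Re-running
with the same configuration reproduces every output byte for byte.

A thin command-line wrapper with `simulate` / `run` / `report` subcommands
is installed at `inst/scripts/pipeline.R`.

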