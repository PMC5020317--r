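# volcontrib

Analytics for patterns of volunteer contribution in citizen-science
biological recording.

Opportunistic occurrence datasets are shaped by the people who collect
them: most volunteers contribute a few records on one or two days, a small
cadre contributes most of the data, effort concentrates on favourite
sites, and easy or abundant species dominate the record stream. For
scheme organisers and biodiversity informaticians those biases are both a
nuisance and a signal. `volcontrib` implements the standard analyses of
that signal as a tested pipeline:

* **Ingestion** — Darwin-Core-flavoured CSV tables; OSGB grid references
  parsed at mixed precision (100-km letters through 1-m references,
  DINTY tetrads); exact-day and ≤1-km precision filters with a fully
  reconciling audit; recorder-identity normalisation with group/anonymous
  flagging and optional surname+initial synonym collapsing.
* **Engagement metrics** — per volunteer: observation count, activity
  ratio `AR = active days / linked days`, relative activity duration
  `RAD = active days / study window`, and variation in periodicity
  `VP = (own mean gap between active days) / (cohort mean gap)`.
* **Profiling** — min-max normalisation, Ward WSS diagnostic, k-means
  (Lloyd, k-means++, 25 restarts) with k chosen by maximum average
  silhouette width and accepted at ASW ≥ 0.51; profiles named
  dabbler / steady / enthusiast by ascending mean observation count.
* **Spatial** — aggregation to 1-km cells (records, volunteers, informal
  groups, productivity = records/volunteers), deterministic hotspot
  rankings, Spearman correlations across datasets and metrics with an
  auditable cell-pairing policy, GeoJSON export.
* **Taxa** — informal/higher group composition percentages and per-group
  recording statistics with British-checklist coverage.
* **Traits** — per-species record counts screened against traits with
  quasipoisson GLMs (Pearson dispersion, F-tests) and Bonferroni-adjusted
  alpha reporting.
* **Synthetic data** — a seeded generator planting engagement archetypes,
  effort hotspots and trait-linked recording rates, so the whole pipeline
  is testable without any proprietary dataset.

## Worked example

```r
library(volcontrib)

sim <- simulate_dataset(n_volunteers = 300, seed = 42, coarse_fraction = 0.05)
cleaned <- clean_records(sim$raw)
cleaned$audit
#> Record filter audit
#>   input:               12838
#>   rejected (date):     0
#>   rejected (precision):656
#>   rejected (anonymous):0
#>   rejected (group):    0
#>   output:              12182
```

5% of the simulated records were georeferenced at 10 km, and exactly those
656 rows fall to the precision filter; the audit always reconciles to the
input row count.

```r
eng <- engagement_table(engagement_records(cleaned$records), sim$window)
model <- fit_profiles(eng, seed = 42)
model
#> Volunteer engagement profile model
#>   k = 3 (accepted), average silhouette width = 0.785
#>   dabbler      n =  197  mean obs =     31.4  AR = 0.58  RAD = 0.029  VP = 0.93
#>   steady       n =  102  mean obs =     45.1  AR = 0.48  RAD = 0.048  VP = 1.12
#>   enthusiast   n =    1  mean obs =   1402.0  AR = 0.22  RAD = 0.218  VP = 2.45
```

Three profiles are selected (silhouette 0.785, above the 0.51 acceptance
mark). The recovered centroids show the expected gradient: dabblers are
numerous with few observations, short spells and high day-to-day
regularity relative to the cohort; the lone enthusiast contributes 1402
observations across a fifth of the study window.

```r
labelled <- assign_groups(cleaned$records, pool_mapping(sim$species_pool))
cells <- aggregate_cells(labelled)
hotspots(cells, "n_records", 5)
#> # A tibble: 5 × 3
#>    rank monad  n_records
#>   <int> <chr>      <int>
#> 1     1 TQ2535       126
#> 2     2 TQ0542       121
#> 3     3 TQ3318       119
#> 4     4 TQ1012       109
#> 5     5 TQ2207       105
```

The five planted hotspot cells head the ranking. `composition(labelled,
"higher")` and `group_stats(labelled, read.csv(volcontrib_extdata("british_list")))`
summarise what was recorded; `trait_screen()` models why some species are
recorded more than others. `run_pipeline(run_config(...))` chains every
stage and writes CSV/GeoJSON/JSON outputs to a directory.

See the vignette in `vignettes/volunteer-contribution-analytics.Rmd` for
the models, the generator's design and its limitations.

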