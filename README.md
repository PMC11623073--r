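# locustlens

Desert locust (*Schistocerca gregaria*) swarms destroy crops across dozens
of countries, and outbreaks are driven by climate: rainfall, soil moisture
and temperature set the conditions under which solitary locusts turn
gregarious and swarm. `locustlens` is an R package for predicting the
monthly presence or absence of locust swarms at region level from three
gridded climate covariates — precipitation, maximum temperature and soil
moisture — using a **country-partitioned K-nearest-neighbour classifier**.

The package covers the whole workflow:

1. **Data fusion.** Point sighting records (latitude, longitude, start
   year/month) are reverse-geocoded offline against a rectangular
   country/region atlas and joined to monthly netCDF climate by nearest grid
   cell and exact year-month, producing one positive (`"yes"`) row per
   resolvable sighting; unresolvable rows are dropped and counted.
2. **Pseudo-absence generation.** Sighting feeds only report presences.
   For every known region of each affected country, every study-span month
   with no recorded attack becomes one negative (`"no"`) row, with climate
   attached at the region centroid — so per region, negatives + attacked
   months always equal the span length in months.
3. **Classification.** A from-scratch K-NN (lazy learner, no training
   phase). Distances use the feature-weighted Manhattan (L1) metric on
   z-scored features,

   d(x, z) = Σ_r w_r · |x_r − z_r|,   (w_r = 1 by default)

   and the prediction is the majority class among the k = 7 nearest
   neighbours,

   C(x) = argmax_C Σ_{i=1..k} 𝟙(y_i = C),

   with deterministic tie handling (neighbour ties to the smaller training
   index, class ties to the nearest neighbour's class). The *partitioned*
   model fits one K-NN per country — each test sample is scored only by
   training samples from its own country — which lets countries with
   opposite climate–attack relationships coexist; `scope = "global"` gives
   the conventional single-fit baseline on the identical interface.
4. **Evaluation.** Stratified k-fold cross-validation, confusion matrix,
   accuracy/precision/recall/F1, exact Mann–Whitney AUC from the positive
   vote fraction, and a per-country breakdown.
5. **Carbon ledger.** Operational emissions of the compute phases:
   emissions (gCO₂eq) = energy (kWh) × regional carbon intensity
   (gCO₂eq/kWh), with a constant power model (42.5 W CPU, 12.678 GB RAM at
   3 W per 8 GB).

A seeded synthetic-data generator (`sim_config()`, `simulate_glad()`)
emulates all three inputs — atlas, seasonal climate grid within observed
variable ranges, and events whose region-month occurrence follows
country-specific logistic coefficients — so the full pipeline is testable
without any downloads.

## Worked example

Two synthetic countries with opposite-sign planted climate response, four
years, 5-fold stratified CV:

```r
library(locustlens)
cfg <- sim_config(seed = 42, n_countries = 2, year_span = c(1990, 1993))
sim <- simulate_glad(cfg)
pos  <- build_positive_rows(sim$events, sim$climate, sim$atlas)
neg  <- generate_negatives(attack_calendar(pos), sim$atlas, sim$climate,
                           span = cfg$year_span)
glad <- assemble_dataset(pos, neg)
#> assembled dataset: 93 positive / 99 negative rows across 2 countries

fit <- locustlens(glad)   # k = 7, uniform weights, Manhattan distance
fit
#> LocustLens country-partitioned K-NN classifier
#>   192 training rows, 2 countries
#>   k = 7, weights = uniform, metric = manhattan

rec <- locustlens_cv(glad, seed = 42)
evaluate_predictions(rec)
#> Evaluation of 192 predictions ( micro averaging )
#>
#>          truth
#> predicted yes no
#>       yes  83 10
#>       no    8 91
#>
#>  accuracy precision    recall        f1       auc
#>    0.9062    0.9121    0.8925    0.9022    0.9600
#> ...
#> Per country:
#>   country  n accuracy precision recall     f1    auc
#> 1     C01 96   0.8750    0.9070 0.8298 0.8667 0.9433
#> 2     C02 96   0.9375    0.9167 0.9565 0.9362 0.9759
```

The classifier recovers the planted structure: under the same folds the
single-fit global baseline reaches accuracy 0.828 on this dataset, the
country-partitioned model 0.906. `run_pipeline(out_dir, cfg)` chains the
same stages and writes every intermediate artifact (CSV/netCDF/JSON) with
metadata sidecars; data artifacts are byte-reproducible from the seed.

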