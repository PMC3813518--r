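# mmtrends

Robust abundance trend assessment for marine mammal populations.

Population-level abundance time series for marine mammals (and similar
long-lived wildlife) are short, irregularly surveyed, and carry
heterogeneous, often unreported observation error. `mmtrends` implements
a complete assessment pipeline for such data, from raw survey tables to
recovery statistics:

- **Assessment windows.** Each population's trend is assessed over its
  three most recent generations, anchored at the last survey
  (`[t_last − 3G, t_last]`). Series spanning less than three generations
  fall back to their full span, with a minimum of ten years; anything
  shorter, or with fewer than three estimates, is classified Unknown.
- **Confidence-weighted robust trend regression.** For each eligible
  population the pipeline fits, by an MM-type high-breakdown robust
  regression (bisquare ρ; S-step with tuning constant 1.548 for a 50%
  breakdown point, M-step at 4.685 for 95% Gaussian efficiency), both

  - linear: `z(N_t) = α + β·t + ε_t`, and
  - log-linear: `z(log N_t) = α + β·t + ε_t`,

  where `z(·)` standardizes to mean 0, SD 1 so slopes are comparable
  across populations of very different size. Each estimate's 1–6
  confidence rank (ACID: 1 = lowest, 6 = highest) enters as a case
  weight `rank/6` multiplying its ρ contribution. The model with the
  larger robust R² is selected (ties within 0.01 go to the log-linear
  form). For the log-linear fit, `slope × SD(log N)` recovers the
  instantaneous growth rate `r` in 1/yr.
- **Four-way classification.** Significantly Increasing / Significantly
  Decreasing (slope sign with a 95% CI excluding zero), Non-Significant
  Change (CI covers zero), or Unknown (insufficient data).
- **Non-nested aggregation.** Survey areas are often nested; to avoid
  double-counting animals, summaries are computed over the largest (or
  smallest) non-nested population set derived from the containment
  relation in the metadata.
- **Species-level comparison.** Population classifications are rolled up
  to species (majority-of-abundance holder, else the modal category,
  else Unknown) and cross-tabulated against an external reference trend
  table such as Red List listings.
- **Decline and recovery.** For populations with historical abundance
  estimates H, a minimum `N_min` and a recent estimate `N_recent > N_min`:
  decline `= 100·(H − N_min)/H` and recovery `= 100·N_recent/H`
  (possibly above 100%), averaged over multiple H and summarized by
  taxon/habitat group.
- **Synthetic data with ground truth.** `simulate_nested_dataset()`
  generates exponential or depletion–recovery trajectories, irregular
  survey years, rank-dependent lognormal observation error, and nested
  sub-populations, so every stage can be validated against planted
  truth.

## Worked example

```r
library(mmtrends)

cfg <- sim_config(n_populations = 4, seed = 42,
                  growth_rate = c(0.06, -0.05, 0.04, 0.0))
sim <- simulate_nested_dataset(cfg)
res <- run_pipeline(pipeline_config(sim$abundance, sim$populations, seed = 42))
print(res)
res$results[, c("population_id", "model_form", "slope",
                "ci_lo", "ci_hi", "classification")]
```

```
Trend-assessment pipeline result
  stages: input_series=8, deduplicated=8, eligible=8, classified=8
  SIG_INCREASING 50%, SIG_DECREASING 25%, NON_SIGNIFICANT 25%, UNKNOWN 0% over 4 non-nested populations
  population_id model_form    slope   ci_lo   ci_hi  classification
1        pop_01  loglinear  0.08263  0.0711  0.0942  SIG_INCREASING
2        pop_02  loglinear -0.09836 -0.1015 -0.0952  SIG_DECREASING
3       pop_02a  loglinear -0.10164 -0.1161 -0.0872  SIG_DECREASING
...
```

Four parent populations (two of them split into nested sub-populations
`a`/`b`, which are excluded from the headline percentages as nested
areas): the planted growth (+0.06), decline (−0.05), growth (+0.04) and
flat (0.0) trends come back as Significantly Increasing / Decreasing /
Increasing / Non-Significant. Slopes are in standardized response units
per year; back-transforming the log-linear slope for `pop_01`
(`growth_rate(res$fits[["pop_01"]]$loglinear)`) gives an estimated
growth rate of 0.0573/yr against a planted 0.06/yr, from 17 noisy
surveys over three generations.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/mmtrends.R`:

```sh
Rscript inst/scripts/mmtrends.R simulate --out-dir data/ --seed 5
Rscript inst/scripts/mmtrends.R run --abundance data/abundance.csv \
  --populations data/populations.csv --out-dir out/ --seed 5
```

## Input formats

`abundance.csv`: `population_id, year_start, year_end, abundance,
error_kind (none|cv|se|ci95), error_lo, error_hi, is_pup_count,
acid_rank`. Year ranges are collapsed to their mid-point; duplicate
regular/pup-count series are collapsed, keeping the regular series
unless the pup series has strictly more in-window points.

`populations.csv`: `population_id, species_name, species_type, sub_type,
dolphin_or_porpoise, habitat, generation_time, area_label, contains
(semicolon-joined ids), historical_estimates (semicolon-joined numbers)`.

See the methods vignette (`vignettes/trend-assessment-methods.Rmd`) for
the statistical details and design choices.
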