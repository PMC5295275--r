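# ejadd

Linking Environmental Justice indicators to Average Daily Dose estimates.

Screening tools used in environmental-justice (EJ) work rank communities by
demographic burden but stop short of estimating exposure dose, while
conventional risk-assessment dose models ignore demographics. `ejadd`
connects the two for analysts working at the census-tract or community
scale. It implements:

- the **Average Daily Dose** model,
  `ADD = C × IR × EF × conv / BW` (mg per kg body weight per day), where
  `C` is the contaminant concentration, `IR` the daily intake rate of the
  medium (air inhaled or soil/dust ingested), `EF` the fraction of time in
  contact, `BW` body weight, and `conv` a unit conversion on the `C × IR`
  product;
- **EJ indicator scoring**: a tract's fraction of non-white residents, or
  of residents whose income-to-poverty ratio is below 1.5, is binned evenly
  over [0, 1] into integer scores 1–10;
- **chemical mixtures** via Relative Potency Factors
  (`RPF_i = unit risk_i / unit risk_index`) summed into an Index Chemical
  Equivalent Dose, `ICED = Σ RPF_i × ADD_i`, assuming dose additivity;
- a **tract pipeline** that joins concentrations and demographics, derives
  an age-appropriate body weight and intake rate from an Exposure Factors
  Handbook-style lookup table, stratifies per-tract doses by EJ score,
  normalizes stratum means to percent-of-maximum, excludes sparse strata,
  and builds 10 × 10 poverty-score × race-score dose surfaces with stacked
  mixture layers;
- a **local-scale scenario engine** for named community scenarios (the
  packaged fixture is a four-community lead soil-ingestion spectrum from
  wealthiest to EJ community);
- a seeded **synthetic tract generator** emulating joint demographic and
  multi-pollutant concentration structure, so the whole pipeline runs and
  is tested without any external data download.

## Worked example: community scenarios

```r
library(ejadd)
report <- run_scenarios(read_scenarios())
report
#> Community dose scenarios (ADD, mg/kg-day)
#>
#>             Community    C IR    EF   BW      ADD
#>  Wealthiest Community    5 50 0.125 80.0 0.000391
#>    Middle Community 1   50 60 0.250 82.4 0.009100
#>    Middle Community 2  500 75 0.500 83.2 0.230000
#>          EJ Community 5000 85 1.000 84.0 5.060000
#>
#> Largest dose ratio: EJ Community / Wealthiest Community = 12,941
#> (from displayed doses; 12,952 at full precision)
```

The four lead soil-ingestion doses span four orders of magnitude: the
wealthiest community (low soil lead, 3 contact hours/day, lower ingestion
rate) receives 3.91 × 10⁻⁴ mg/kg-day, the EJ community (mining-impacted
soil, constant exposure, elevated ingestion) 5.06 mg/kg-day — roughly
12,941 times more when the ratio is quoted from the displayed doses.
`tidy(report)` returns the per-scenario tibble, `glance(report)` a one-row
summary.

## Worked example: tract-level dose trends

```r
tracts <- simulate_tracts(n_tracts = 2000, seed = 42)
doses  <- per_tract_add(tracts)        # EF = 1, pooled national age
trend  <- doses |>
  group_mean_by_score(tracts, by = "race") |>
  apply_exclusion() |>
  normalize_to_percent()
subset(trend, chemical == "diesel_pm")
#>   indicator score chemical  n_tracts mean_add percent
#> 1 race          1 diesel_pm      135 0.000282    26.3
#> 2 race          2 diesel_pm      321 0.000325    30.3
#> 3 race          3 diesel_pm      368 0.000377    35.1
#> 4 race          4 diesel_pm      398 0.000454    42.3
#> 5 race          5 diesel_pm      298 0.000545    50.7
#> 6 race          6 diesel_pm      239 0.000639    59.5
#> 7 race          7 diesel_pm      138 0.000762    71.0
```

Mean diesel-PM dose rises steadily with race score (percent is the stratum
mean as a share of that chemical's maximum across scores). Surfaces over
both indicators come from `build_surface()`:

```r
pairs <- group_mean_by_score(doses, tracts, by = "both")
surf  <- build_surface(pairs, "benzene")
surf
#> <score_surface> benzene: 56 of 100 cells populated, 2000 tracts
autoplot(surf)                         # heat map; write_surface_json(surf, ...)
```

`mixture_layers()` stacks benzene, benzene + RPF-adjusted 1,3-butadiene,
and + RPF-adjusted acetaldehyde into cumulative layers for the same
surfaces. A command-line wrapper with `simulate`, `run`, `scenarios` and
`validate` subcommands ships at `system.file("cli", "ejadd.R", package =
"ejadd")`.

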