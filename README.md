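# diarrscan

Retrospective space-time cluster detection for district-level disease
surveillance panels — monthly case counts reported by administrative units,
with a population at risk projected by compound growth. The package was
built around the analysis of under-five diarrhea morbidity in Sidama Zone,
Southern Ethiopia (19 districts, July 2011 – June 2017, HMIS monthly
reports), but every component is generic: any (unit × month) count panel
with point locations and base populations will do.

It is aimed at epidemiologists and public-health analysts who want the
standard SaTScan-style retrospective analysis — excess-risk mapping plus
purely spatial, purely temporal and space-time cluster detection — as
scriptable, testable R functions rather than a GUI workflow.

## The method

**Null model.** Conditional on the panel total *C*, cases fall on cells in
proportion to person-time: the expected count of any set of cells is
*E*[*c*] = *p·C*/*P*, with *p* the person-time in the set and *P* the panel
total. Person-time comes from base populations compounded monthly,
*pop(u, m)* = *pop₀(u)*·(1 + *r*)^(m/12).

**Scan statistic.** Candidate windows are circles over nearest-neighbour
unit sets (spatial), month intervals (temporal), and circle × interval
cylinders (space-time), capped at 50% of the population at risk and 50% of
the study period. Each window is scored by the discrete-Poisson
log-likelihood ratio

LLR = *c* log(*c*/*E*) + (*C* − *c*) log((*C* − *c*)/(*C* − *E*)),  applied when *c* > *E* (high rates),

and the window relative risk is RR = (*c*/*E*) / ((*C* − *c*)/(*C* − *E*)).
Significance is by Monte Carlo: the observed LLRs are ranked among the
maximum LLRs of replicate datasets drawn multinomially under the null,
*p* = (1 + #{replicate max ≥ LLR}) / (1 + R). Reporting is greedy and
non-overlapping: the maximal-LLR window is the primary cluster, secondary
clusters follow in LLR order if disjoint from everything already reported.

**Seasonality.** Zone-wide monthly rates are decomposed multiplicatively by
ratio-to-moving-average: a 12-month centered moving average, calendar-month
ratio indices renormalized to mean 1, and an OLS linear trend on the
deseasonalized series.

A synthetic panel generator (`generate_panel()`, `reference_scenario()`)
produces Poisson panels with known seasonality, trend and planted clusters
of specified relative risk, so every claim above is testable against ground
truth.

## Worked example

Simulate a panel shaped like the Sidama study at 1/10 population scale
(planted clusters: spatial RR 1.82 on Boricha, temporal RR 1.37 over months
29–46, a Malga space-time cylinder RR 2.03 over months 17–46), then run the
spatial scan:

```r
library(diarrscan)
cfg <- reference_scenario(scale = 0.1, seed = 1)
sim <- generate_panel(cfg)
sc  <- scan_config(n_replicates = 199, seed = 2)
ws  <- enumerate_spatial_windows(sim$locations, sim$population, sc)
clusters <- report_clusters(scan(sim$cases, sim$population, ws, sc))
print(clusters)
#>   rank    kind unit_label center_unit radius month_start month_end n_cells
#> 1    1 spatial    Boricha     Boricha      0           0        71      72
#> 2    2 spatial      Malga       Malga      0           0        71      72
#>   observed expected obs_over_exp relative_risk    llr p_value
#> 1     3057  1845.50         1.66          1.77 372.64   0.005
#> 2     1127   809.64         1.39          1.42  58.01   0.005
```

The planted Boricha excess is recovered as the primary cluster at the
smallest attainable p (0.005 with 199 replicates); its realized
observed/expected (1.66) sits below the planted 1.82 because conditioning
on the realized total shifts every expectation upward. Malga surfaces as a
disjoint secondary cluster, driven by its planted cylinder. The seasonal
fit on the same panel recovers the built-in February–May peak and the mild
trend:

```r
fit <- seasonal_decompose(incidence_rate(colSums(sim$cases), colSums(sim$population)),
                          start_month = 7)
print(fit)
#> Multiplicative seasonal fit
#>   trend: y = 0.0126 * t + 4.31  (t = month, 1-based)
#>   seasonal indices (mean 1):
#>   Jan   Feb   Mar   Apr   May   Jun   Jul   Aug   Sep   Oct   Nov   Dec
#> 1.171 1.341 1.357 1.380 1.248 0.927 0.714 0.746 0.701 0.668 0.809 0.938
```

`sidama_tables()` exposes the published result tables (yearly rates,
excess risk, spatial and space-time clusters) as in-memory fixtures;
`run_all(pipeline_config(...))` drives the full pipeline from two CSVs to a
report bundle (rate tables, seasonal fit JSON, cluster CSVs and GeoJSON,
run manifest).

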