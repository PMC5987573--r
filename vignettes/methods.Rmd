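---
title: "Methods: discrete-Poisson scan statistics for district-month surveillance panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-Poisson scan statistics for district-month surveillance panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diarrscan)
```

diarrscan analyses a complete rectangular panel of monthly case counts over
administrative units — the setting of routine facility-based surveillance,
where each district reports one count per month and the population at risk
is only known from a census projection. This vignette documents the model,
the choices that were genuinely open when the package was designed, and
what the validation experiments do and do not establish.

## Data model and demography

A panel is a (unit × month) matrix; months are indexed 0-based from panel
start, with the calendar month of index 0 carried as metadata (the Sidama
panel starts in July, so fiscal years are July–June). Readers refuse
incomplete panels rather than imputing: a missing (unit, month) cell is an
error naming the cell, because silent zero-filling would bias every rate
and every scan window downward.

Person-time comes from compound growth. With base population $p_0(u)$ at
month 0 and annual growth rate $r$ (default 0.029, the regional rate used
for the Sidama projection),

$$\mathrm{pop}(u, m) = p_0(u)\,(1+r)^{m/12}.$$

The exponent $m/12$ interpolates the annual projection formula
$P = P_0(1+r)^t$ smoothly across months, so month 12 equals exactly one
annual compounding step. The under-five share (default 0.156) is a separate
scalar applied when starting from total census populations. Units are
persons (person-months when summed over cells).

## The null model and excess risk

All inference conditions on the observed total $C$. Under the null, cases
fall on cells proportionally to person-time: $E[c] = p\,C/P$ for any cell
set with person-time $p$, panel person-time $P$. Expected counts therefore
sum to $C$ exactly and are invariant to rescaling all person-time — both
are tested properties. Per-unit observed/expected is the excess risk (the
surveillance literature's SMR, kept under both names), and the per-unit
relative risk uses the outside-unit baseline
$(c/E)\,/\,((C-c)/(C-E))$.

The RR formula deserves a note: the source analysis prints RR columns
without defining them. $(c/E)/((C-c)/(C-E))$ is the SaTScan convention and
is the unique simple candidate consistent with every printed
(observed, expected, RR) triple across the published tables; the test suite
asserts that consistency. One printed RR (Malga's 1.65 in the spatial
cluster table) disagrees with its own printed counts, which give 1.63 — the
value printed in the district table; the fixtures keep both as printed and
the tests assert the recomputed value.

## Windows

*Spatial.* For every unit as centre, circles absorb nearest neighbours one
distance block at a time (ties enter together and are never split), until
adding the next block would push the member person-time above the cap
(default 50% of total person-time). Duplicate member sets from different
centres are kept once. With equal populations this admits member sets up to
$\lfloor 0.5\,n \rfloor$ units — 9 of 19 districts.

*Temporal.* Every month interval no longer than
$\lfloor 0.5\,M \rfloor$ (36 of 72 months), spanning all units.

*Space-time.* Every circle × interval cylinder whose interval respects the
temporal cap and whose person-time stays within the spatial cap's share of
total person-time over the same interval.

Distance is Euclidean on raw latitude/longitude degrees by default — the
standard Cartesian treatment of point coordinates at zonal scale, matching
the source analysis; a haversine great-circle metric is available via
`scan_config(distance_metric = "great_circle")`. At 19 points either metric
induces the same neighbour orderings unless geometry is adversarial.

## The scan statistic and Monte Carlo inference

Each window scores
$\mathrm{LLR} = c\log(c/E) + (C-c)\log\!\big((C-c)/(C-E)\big)$ when
$c > E$, else 0 (high-rate scan; a two-sided option exists behind
`high_rates_only = FALSE`). The null distribution of the maximum is
estimated by redistributing the $C$ cases multinomially over cells with
probabilities $E(\text{cell})/C$ — the standard conditional-Poisson
sampler; the source analysis names Monte Carlo testing but not the
sampler — and scanning each replicate over the same windows. Then
$p = (1 + \#\{\text{replicate max} \ge \mathrm{LLR}\})/(1 + R)$, so with
$R = 999$ the smallest attainable p is 0.001. Reported p-values are exact
Monte Carlo ranks, never interpolated.

Reporting is greedy by descending LLR: a window is reported only if
significant and disjoint from every already-reported cluster — no shared
unit for spatial/space-time, no shared month for temporal. Ties in LLR
break toward fewer cells, then lexicographic member label and start month,
making output order fully deterministic.

Two engineering choices matter for scale. Windows live in a compact
container (distinct member sets plus an interval table) rather than one
object per window: the full 19 × 72 cylinder enumeration is ~280,000
windows, and per-window objects would dominate the Monte Carlo loop. And
spatial/space-time scans return the best window per member set — any other
interval on the same base can never be reported ahead of it under the
unit-overlap rule, so the collapse is exact, not an approximation; temporal
scans return every interval because month-overlap reporting needs them.

## Seasonal decomposition

Zone-wide monthly rates (per 1000) are decomposed multiplicatively —
"deseasonalized" in the classical ratio-to-moving-average sense; the
additive variant would be wrong for rates whose seasonal swing scales with
level. The 12-month centered moving average (weights 1/24, 1/12 × 11,
1/24) is exact for affine trends and annihilates any exact 12-month
periodic component; both are tested properties. The first and last six
months have no smoothed value and are excluded from index estimation rather
than padded. Indices are calendar-month means of series/CMA renormalized to
mean 1; the trend is OLS of the deseasonalized series on the 1-based month
index, so the intercept refers to a month-0 extrapolation — the published
trend equation is stored as a fixture with that caveat, since the
underlying monthly series was never deposited and its time origin is not
stated.

## The synthetic generator

`generate_panel()` draws independent Poisson counts with intensity

$$\lambda(u, m) = \mathrm{pop}(u, m)\cdot \beta \cdot s(\mathrm{month}(m))
\cdot (1+\gamma)^m \cdot \prod_{\text{planted} \ni (u,m)} \mathrm{RR},$$

with base rate $\beta$, seasonal indices $s$ (mean 1), monthly trend
$\gamma$, and planted clusters acting multiplicatively — exactly the scan
statistic's alternative hypothesis, and composing when planted windows
overlap. Independence given intensity matches the scan model's Poisson
assumption; a negative-binomial `dispersion` option exists for robustness
experiments but is off by default, so passing tests say nothing about
overdispersed data.

`reference_scenario()` fixes the study conditions: 19 districts over 72
months; published coordinates and populations for the 10 districts that
have them, synthetic coordinates (flagged as such) and a common base
population for the other 9, chosen so the zone-wide annual incidence is
about 5822 per 100,000; seasonal indices peaking February–May
(`default_seasonal_indices()`, amplitude ≈ 0.75–1.35); trend 0.003/month,
the published slope of 0.015 rate-units per month relative to the ~4.8
rate level; and three planted clusters echoing the published ones —
Boricha spatial RR 1.82, an 18-month all-district temporal cluster RR 1.37
(months 29–46), and a Malga cylinder RR 2.03 (months 17–46). The base rate
is solved in closed form so the expected panel total equals 202,406 at
scale 1; the `scale` argument multiplies populations for cheaper runs.

What the generator does **not** emulate: reporting artifacts (new
facilities coming online — the likely driver of part of the real trend),
spatial correlation beyond the planted windows, overdispersion, and
population mis-projection. Recovery results on synthetic panels therefore
validate the machinery, not the epidemiology.

## Validation experiments and their sizes

These are run by the test suite; the sizes were chosen as the smallest
panels at which each property is informative.

* **Oracle equivalence.** On 100 random 5-unit × 12-month panels, the scan
  engine's maximizing window and LLR equal an independent brute-force
  enumerator that loops over every admissible window and evaluates the
  likelihood from its definition, for all three modes.
* **Planted-cluster recovery.** 20 seeds of `reference_scenario()` at 1/10
  scale, 199 replicates: the Boricha window must be the spatial rank-1 with
  p ≤ 0.05 in ≥ 90% of seeds, and the reported space-time cluster
  containing Malga must have ≥ 80% of its interval inside the true planted
  interval in ≥ 80% of seeds. The interval criterion is precision-shaped
  (share of the reported interval that is truly elevated) because the
  planted all-district temporal cluster overlaps the cylinder months and
  legitimately pulls reported cylinders toward the jointly elevated
  sub-interval.
* **Type-I error.** 100 null panels (19 units × 36 months, flat
  seasonality, no trend, nothing planted — intensity exactly proportional
  to person-time), 199 replicates: the primary spatial p-value is ≤ 0.05 in
  at most 10% of seeds. Seasonality is removed here because a spatially
  uniform seasonal pattern is part of the temporal scan's alternative, not
  its null.
* **Seasonality recovery.** A noise-free 144-month series with the default
  Feb–May indices and slope 0.015/month: indices recovered within 5%,
  slope within 10% (the residual error is the curvature bias of
  ratio-to-CMA under a multiplicative trend–season interaction).

## Degenerate inputs and numerical notes

Single-unit panels: spatial and space-time scans and the excess-risk table
(whose RR is undefined when one unit holds all expectation) are skipped by
the pipeline with explicit notices; seasonality and temporal scans still
run. A window containing all cases gets RR = ∞ rather than an error inside
`scan()`. Zero counts use the $0\log 0 = 0$ convention. Cap comparisons use
a $1 + 10^{-9}$ relative tolerance so exact-fraction ties (e.g. two equal
units under a 0.5 cap) are included deterministically. All LLR arithmetic
is in log space; no factorials are ever formed.

## Known limitations

Circular windows only (no elliptic bases); purely retrospective analysis
(no prospective surveillance adjustment); no covariate adjustment in the
expected counts; no small-area smoothing of the excess-risk surface; and
the published monthly series being unavailable, the package's agreement
with the source analysis is established at the level of its printed window
statistics and of ground-truth recovery on emulated panels, not by
re-running the original data.
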