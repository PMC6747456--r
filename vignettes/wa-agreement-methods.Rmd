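---
title: "Well-activity exposure metrics and their agreement with air monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Well-activity exposure metrics and their agreement with air monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waagree)
```

## The exposure model

"Well activity" (WA) metrics summarize the intensity of unconventional oil
and gas development around a geocoded receptor (a residence, or a monitor
standing in for one) as phase-specific inverse-distance-squared sums over
every well active in that phase on that day, statewide, with no buffer
radius. For receptor $j$ on day $d$, with $d_{ij}$ the distance in meters to
well $i$:

$$\mathrm{WA}^{pad}_{jd} = \sum_i \frac{1}{d_{ij}^2}, \quad
  \mathrm{WA}^{drill}_{jd} = \sum_i \frac{1}{d_{ij}^2}, \quad
  \mathrm{WA}^{frac}_{jd} = \sum_i \frac{t_i}{d_{ij}^2}, \quad
  \mathrm{WA}^{prod}_{jd} = \sum_i \frac{v_i}{d_{ij}^2},$$

each sum running over the wells in the corresponding development phase that
day; $t_i$ is total well depth (m) and $v_i$ average daily gas production
volume (m³/day). The model assumes that every active well emits, that
emissions are homogeneous within a phase, and that a well's contribution
falls with squared distance regardless of wind, terrain or other sources.
Those assumptions are exactly what the agreement analysis interrogates: if
they held even approximately, quartile categories of WA and of measured
concentrations at the same points should agree far better than chance.

### Daily phase assignment

Each well's phase windows are closed date intervals at calendar-day
resolution:

* **pad preparation** — the 30 days `[first_spud − 30, first_spud − 1]`
  before the spud of the *first* well on the pad, attributed to that well
  only (ties broken by lowest well id) so each pad contributes one term to
  the pad-preparation sum;
* **drilling** — begins on the spud date and lasts
  $\mathrm{clamp}(\mathrm{round}(1 + 29p),\,1,\,30)$ days, where $p$ is the
  well's midrank depth percentile within the analyzed fleet. The source
  methodology states only that the duration is 1–30 days "based on
  percentiles of total well depth"; the linear map with half-up rounding is
  this package's choice — it is deterministic, monotone in depth, and spans
  the stated range. A step map (depth quartiles to fixed durations) would
  also satisfy the constraint; since drilling is a transient phase whose WA
  quartiles are dominated by which wells are active at all, the difference
  is immaterial to the agreement statistics.
* **fracturing** — exactly 7 days from the stimulation date;
* **production** — first production date through the last production date,
  or through the end of the study when the last date is missing or later.
  Monthly production-report gaps are not modeled: production is treated as
  continuous.

Where windows overlap on a day the later phase wins (production >
fracturing > drilling > pad preparation): the well's actual state is the
most advanced one it has reached. Inactive days are represented by absence
from the calendar. Wells missing every chronology date, wells with
order-violating dates, and wells with no active day inside the study period
are excluded (reasons `missing_dates`, `illogical_chronology`,
`inactive_in_period`); a well with a spud date but no stimulation date is
kept, since it still contributes pad-preparation, drilling and production
days.

### Distances

Distances are haversine great-circle distances on a sphere of radius
6,371,008.8 m (via `geosphere`). An ellipsoidal geodesic differs by under
0.5% at these scales, which cannot change a quartile rank. A receptor
exactly coincident with a well is a hard error rather than an infinite WA —
real monitor–well distances start at hundreds of meters — with an optional
`min_distance_m` floor for simulation safety.

## Concentration summaries

Raw observations are reduced to one value per receptor-day: hourly CO, NO₂,
SO₂ and PM₂.₅ to the daily mean and maximum of available 1-h values; hourly
ozone to the MDA8 (the maximum 8-h running mean over windows starting each
hour of the day, a window counting when at least 6 of its 8 hours are
present — the regulatory 75% completeness convention; windows may run into
the next day); 24-h benzene samples pass through. Days with partial hourly
coverage use all available hours. The daily *mean* is the classified
quantity; the maximum is carried for reporting only.

Rolling sensitivity analyses replace the daily series with trailing
calendar-window means over 90 or 180 days, emitted only when at least 5
daily values fall in the window. The threshold of 5 is this package's
choice: 1-in-6-day benzene sampling puts ~15 values in a full 90-day window,
so 5 keeps sparse series usable while discarding windows that would average
a handful of samples. Windows are past-looking, matching how exposure
windows precede outcomes in the epidemiology designs this methodology feeds.

## Agreement analysis

WA values and concentrations are pooled across all receptors and days of
the analyzed subset and cut at their empirical 25th/50th/75th percentiles
(linear interpolation between order statistics, `quantile` type 7) into
very-low/low/medium/high categories; boundary values go to the lower
category (any consistent rule preserves quartile mass up to ties). Quartile
schemes are recomputed after every filter — buffer restriction or rolling
replacement — because the categories are defined by the quartiles of
whatever subset is analyzed. WA series with mass points (many zero-WA days
for transient phases) can yield non-increasing cut-points; this is flagged
with a warning rather than an error, because it is a real feature of these
metrics, and the resulting collapsed categories are part of what an analyst
should see.

Agreement between the two 4-level classifications is summarized by the 4×4
table (rows: concentration; columns: WA), the identical-category
proportion, the mirror-opposite proportion (categories summing to 5 under
1–4 coding, i.e. very-low↔high *and* low↔medium; an extremes-only
very-low↔high variant is available via `opposite = "extremes"`), the
row-conditional WA distribution within each concentration category, and the
weighted kappa

$$\kappa_w = \frac{p_o - p_e}{1 - p_e}, \qquad
  p_o = \sum_{ij} w_{ij} p_{ij}, \qquad p_e = \sum_{ij} w_{ij} p_{i\cdot} p_{\cdot j},$$

with linear (Cicchetti–Allison) weights $w_{ij} = 1 - |i-j|/3$ by default
(quadratic available). The standard error is the Fleiss–Cohen–Everitt
large-sample form, not assuming the null, and the 95% CI is
$\kappa_w \pm 1.96\,\mathrm{se}$. Receptor-days are treated as independent
in the variance; temporal autocorrelation within monitors would widen the
true intervals, a caveat shared with the analysis convention this package
follows.

## The synthetic-data generator

The generator exists so every stage is testable with known structure; its
defaults describe a Marcellus-like configuration and are fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_pads`, `wells_per_pad` | 100, 3 | multi-well pads, wells jittered ≤ 200 m around the pad center |
| `bbox` | 39.8–42.0° N, −80.5–−75.0° E | a Pennsylvania-scale box |
| `study_start`, `study_end` | 2011-01-01 – 2015-12-31 | five-year study window |
| `n_receptors` | 76 | monitor count at the scale of a statewide network |
| `depth_mean_m`, `depth_sd_m` | 2000, 400 | normal depth, truncated below at 500 m (inverse-CDF, no mass point) |
| `volume_log_mean`, `volume_log_sd` | log(5·10⁴), 0.8 | lognormal gas volumes, m³/day |
| `gap_days_max` | 90 | inter-phase inactive gaps, uniform on [0, max] — phases are sequential but can idle between |
| `conc_log_mean`, `noise_sd` | log(0.16), 0.5 | log-scale location/spread of concentrations (benzene-like ppbv scale) |

Chronologies are built forward (spud → stimulation → first production →
last production with non-negative gaps), so simulated fleets pass the
feasibility screen with zero exclusions by construction — that is asserted,
not assumed. Concentrations come in two regimes: **independent**
($c = e^{\mu + \sigma\varepsilon}$, unrelated to wells) and **coupled**
($c = e^{\mu + \gamma z + \sigma\varepsilon}$, where $z$ is the
rank-standardized total WA — the normal score of the rank of the sum of the
four metrics). Rank-standardizing before coupling keeps $\gamma$'s meaning
stable across configurations whose raw WA scales differ by orders of
magnitude, and makes the zero-noise coupled series a strictly increasing
function of total WA, so pooled quartile categories of concentration and
total WA coincide exactly — the property behind the perfect-recovery tests.

Each generator draws from its own RNG stream (`seed` plus a fixed
per-operation offset), so wells, receptors and concentrations are
independently reproducible; separate pollutant series use an additional
`stream` offset.

What the generator does *not* emulate: atmospheric dispersion, wind,
terrain, seasonal and diurnal cycles, inter-pollutant correlation,
deliberate monitor siting, or re-fracturing. Passing tests therefore show
the pipeline's statistics behave correctly under known coupling and under
the null — they do not show that real concentrations follow total WA, which
is precisely the empirical question the method is applied to.

## Calibration properties the tests pin down

* Two independent uniform 4-category classifications give an expected 25%
  identical-category proportion and 25% mirror-opposite proportion (four
  cells each of sixteen equiprobable ones) and $\kappa_w \to 0$; asserted at
  $n = 10^5$ within three Monte-Carlo standard errors (±0.4 percentage
  points).
* Coupled simulation at zero noise with a single active phase (a
  production-only fleet, so total WA equals the production metric) yields
  $\kappa_w = 1$ and 100% agreement for that metric; the transient-phase
  metrics are all-zero and degenerate there, which is asserted as such.
* $\kappa_w$ is non-decreasing in coupling strength over a fixed-seed
  three-point grid, and independent-mode kappas stay inside ±0.1.
* The vectorized WA evaluation equals a scalar triple-loop oracle to
  relative 10⁻¹²; weighted kappa matches an independently coded literal
  evaluation of its definition and externally computed frozen values;
  quartile cut-points match a first-principles sorted-order interpolation
  oracle.

Problem sizes in the test suite (fleets of tens of pads, 6–12 receptors,
6–24-month windows, $10^5$ null pairs) were chosen so the full suite
exercises every stage at meaningful scale while remaining quick to run
routinely; the statistics above are scale-free, so nothing depends on the
larger fleet sizes a real deployment would use.

## Degenerate inputs and numerical choices, collected

* Quantiles: type-7 linear interpolation; at least 4 values required.
* Boundary values classify downward (`value ≤ cut` → lower category).
* Kappa is undefined when $p_e = 1$ (all mass in one row *and* one column);
  that is an error, not a zero.
* $d = 0$ receptor–well pairs: hard error; optional positive floor.
* Drilling-duration rounding: half-up (so percentile 0.5 → 16 days), not
  banker's rounding.
* Same-day phase transitions are legal (non-strict chronology
  inequalities).
* Missing last production date means "still producing at study end".
* MDA8 windows: start each hour of the day, ≥ 6 of 8 hours present, means
  over available hours.

## Limitations

The package validates *classification agreement*, not health-effect
estimation: it says nothing about bias in any particular epidemiologic
effect estimate beyond the general warning that misclassification across
non-adjacent ordinal categories is not guaranteed to bias toward the null.
Kappa confidence intervals ignore within-monitor autocorrelation. The
synthetic concentration model is a lognormal stand-in chosen for positivity
and skewness, not an inference about real pollutant distributions. Vendor
data reconciliation, real AQS/DEP file dialects, map rendering and
health-outcome modeling are out of scope.
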