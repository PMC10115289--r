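---
title: "Break-even appraisal of cycling infrastructure: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Break-even appraisal of cycling infrastructure: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclebreakeven)
```

## The decision problem

A local authority plans a cycleway and wants to know, *before* building
it, how much behaviour change the investment needs to pay for itself:
how many residents must become regular cyclists (cycling daily or almost
daily) for the discounted health-related and environmental benefits to
offset the construction cost — a benefit-cost ratio (BCR) of 1:1. This
package implements that break-even analysis as a transparent,
reproducible comparative risk assessment in the style of the WHO Health
Economic Assessment Tool (HEAT) for cycling, together with the one-way
sensitivity analysis an appraisal of this kind ordinarily reports.

The bundled base case, `coventry_fixture()`, is a 6-km separated
cycleway in Coventry (UK): a catchment population of 173,169 adults, a
construction cost of $12,800,491 (international dollars; £8,594,000
converted with a purchasing-power-parity coefficient of 0.667865), a
10-year appraisal horizon, a 5% annual discount rate and a value of a
statistical life (VSL) of $4,260,000.

## Model structure

The population is distributed over five cycling-frequency levels, from
level 1 ("daily or almost daily") to level 5 ("never"). A scenario moves
a share $s$ of the total population from one source level into level 1;
everything else is held fixed ("steady state vs steady state": no
individual-level simulation, no recurrent events). Survey categories are
ranges, so each level is mapped to representative cycling days per year;
the defaults are category midpoints — 312, 104, 24, 6, 0 — and are
configurable via `frequency_levels()`. All downstream head-count
arithmetic is independent of this mapping.

A person at level $i$ cycles
$v_i = d_i \times \text{trips/day} \times \text{km/trip}$
kilometres per year. Only the product of trips and trip length matters
anywhere in the model, a property the test suite checks exactly.

Four domains are valued:

**Physical activity.** All-cause mortality responds linearly to cycling
volume up to a cap:
$RR(v) = 1 - (1 - RR_{\text{ref}}) \cdot \min(v / v_{\text{ref}},\; r_{\max}).$
Deaths per year in a state with level shares $p_i$ are
$N \cdot m \cdot \sum_i p_i \, RR(v_i)$, with $N$ the population size
and $m$ the annual all-cause mortality rate; the domain impact is the
post-minus-baseline difference (negative = deaths averted).

**Air pollution.** Cycling raises the inhaled particulate dose. The
extra person-kilometres are converted to hours at the configured cycling
speed, and the excess exposure is expressed as an annual-equivalent
PM2.5 increment: ambient concentration × (ventilation ratio − 1) ×
fraction of cycling done in traffic. Extra deaths are person-years of
that increment × exposure-response slope × baseline mortality. This is a
deliberately simple dose-proportional form — sign and proportionality
are the contract, not a full mode-specific exposure ledger.

**Crash risk.** Extra deaths = extra km × fatality rate per
100 million km.

**Carbon.** New cycling kilometres displace other modes according to
the modal-shift shares (default 50% public transport, 30% car, 20%
walking); each displaced motorised kilometre saves its emission factor.
Walking contributes nothing.

Mortality impacts are monetised at the VSL; carbon at the damage cost
per tonne of CO2. Each domain's steady-state annual value is discounted
over the horizon with a demand take-up ramp:
$PV = \sum_{t=1}^{H} \min(t / \tau, 1) \cdot a \cdot (1 + r)^{-t},$
where $\tau$ is the take-up time and $a$ the annual value. Deaths are
*reported* as annual steady-state counts alongside the discounted
values, not as discounted death counts.

## Numerical choices

- **Discount timing.** End-of-year discounting is the default. The
  convention used by the original tool is not recoverable from its
  printed outputs (back-solving its scenario values yields a combined
  discount-and-ramp factor ≈ 0.739 that matches no simple convention),
  so the choice is explicit and configurable
  (`discount_convention = "end"` or `"mid"`).
- **Take-up ramp.** Linear, `min(t / takeup, 1)` — the simplest monotone
  ramp; it reproduces the reported direction of the take-up sensitivity
  (BCR falls as take-up lengthens).
- **Root finding.** The total benefit is monotone increasing in the
  shifted share (asserted at every bisection step), so
  `solve_breakeven()` uses plain bisection on
  $[0, \text{baseline source share}]$ with a default tolerance of
  $10^{-6}$ on $|BCR - 1|$; an initial probe at the share that lifts
  regular cycling to 5% of the population narrows the bracket when it
  already overshoots. Results are bracket-independent.
- **Rounding.** All solving is done in continuous shares; head counts
  are rounded half-up only at reporting time (`count_from_share()`).
- **Degenerate inputs.** Constructors enforce shape only; all scientific
  invariants are checked by `validate_config()`, which reports every
  violation at once, so deliberately broken configurations (from
  `inject_violation()`) can exercise each rule in isolation.

## Sensitivity analysis semantics

`default_variations()` builds the standard 20-variation one-way grid:
age cohorts, VSL ±20%, discount rate ±1.5 percentage points, 5- and
15-year horizons, ±20% trip length and trips per day, take-up 2/3/5
years, and cycling fully in traffic. Two semantic decisions deserve
note:

- **Age-cohort variations** swap only the cohort's annual mortality
  rate; nothing else about the population changes.
- **"Baseline" vs "post" volume variations.** Varying
  `trip_length_km`/`trips_per_day` rescales travel behaviour in *both*
  states (the whole dose-response shifts, so the BCR scales by
  approximately the same factor). Varying `post_trip_length_km`/
  `post_trips_per_day` rescales the post-intervention state only.

A post-state volume *increase* raises every existing cyclist's volume
and can clear the intervention cost before anyone changes frequency
level. The break-even contract here only searches nonnegative shifts
into level 1, so such variations are reported as `feasible = FALSE`
with their (greater-than-1) BCR at the base shift — the honest reading
of "no additional regular cyclist is needed". An appraisal that instead
searched negative shifts (moving people out of level 1 until benefits
fall to the cost) would report a below-baseline share for these rows;
that convention is intentionally not implemented.

For each row the package reports the BCR with the *base-case* break-even
shift held fixed, the new break-even share (always re-solved from level
2), the absolute number of regular cyclists at break-even (pre-existing
plus new) and its difference from the base case.

## Default risk parameters

The case study's own report prints the economic and behavioural inputs
but not the background risk parameters of the underlying tool. The
fixture therefore ships documented order-of-magnitude defaults from the
public HEAT methodology; results computed with them are order-of-
magnitude estimates, and the package does **not** claim to reproduce the
original tool's dollar magnitudes (its proprietary background data are
not available). The reported scenario tables are instead bundled as
reference data (`coventry_breakeven_scenarios()`,
`coventry_sensitivity_results()`) and all head-count and summary
arithmetic is cross-checked against them.

| parameter | default | rationale |
|---|---|---|
| `rr_reference` | 0.90 | ~10% all-cause mortality reduction for regular commuter cycling |
| `reference_volume_km_per_year` | 1,200 km | ≈100 min/week at 14 km/h |
| `max_volume_ratio` | 4.5 | caps the risk reduction at 45% |
| `annual_mortality_rate` | 0.004 | crude all-cause rate, England-scale, ages 20–74 |
| `crash_fatalities_per_100M_km` | 2.0 | national cyclist fatality rate per distance cycled |
| `pm25_ugm3` | 10 | UK urban ambient PM2.5 |
| `ventilation_ratio` | 2 | inhaled dose cycling vs rest |
| `er_slope_per_ugm3` | 0.008 | ~8% mortality per 10 µg/m³ PM2.5 |
| `in_traffic_fraction` | 0.5 | half of cycling in traffic |
| `cycling_speed_kmh` | 14 | average urban cycling speed |
| `emission_factor_g_per_km` | 90 / 171 / 0 | bus (per passenger) / car / walking |
| `carbon_damage_cost` | $130/t | social damage cost of CO2 |

## What the synthetic generator emulates — and what it does not

`sample_configs()` draws randomised configurations with the statistical
structure the appraisal assumes: cycling shares from a Dirichlet
distribution with concentration $(1, 2, 3, 5, 9)$ (most people rarely or
never cycle), VSL log-uniform on $[10^6, 10^7]$, discount rate uniform
on $[0, 0.1]$, horizons of 5–20 years, take-up of 1–5 years, and the
remaining behavioural, risk and intervention parameters uniform on
realistic ranges. Every draw is valid by construction and the sequence
is deterministic under its seed (the caller's RNG state is left
untouched).

The generator emulates *configurations*, not travel behaviour: it does
not simulate individual travel diaries, seasonal or weather effects,
correlations between parameters (e.g. wealthier areas having both
higher VSL and lower mortality), or measurement error in cycling-level
surveys. Passing property tests therefore demonstrate the internal
consistency of the model — monotonicity, linearity, sign structure,
solver correctness — on valid inputs, not the external accuracy of any
particular parameterisation on real data.

## Verification strategy and problem sizes

The test suite checks, among others: the discounting function against a
term-by-term summation oracle (1,000 random parameter draws, $10^{-10}$
tolerance); the bisection solver against an exhaustive $10^{-5}$-step
grid scan of the BCR curve on 50 random feasible configurations (the
pool is filtered to break-even shares below 1% of the population to
keep the exhaustive scan exhaustive *and* finite); exact invariance of
all outputs under trips-vs-length rescalings; VSL linearity of the three
mortality domains with carbon invariance; BCR monotone in horizon and
VSL (increasing) and in discount rate and take-up time (decreasing); the
(+, −, −, +) domain sign pattern for every shift toward regular
cycling; and exact share-mass conservation of `apply_shift()`.

## A worked base case

```{r, eval = FALSE}
cfg <- coventry_fixture()
results <- lapply(2:5, function(l) solve_breakeven(cfg, l))
summarize_breakeven(results, cfg$intervention, cfg$economics)
#> Across 4 scenarios: mean 556 new regular cyclists (0.321% of population)
#>   93 cyclists per km; $2302 (local 1538) generated per cyclist per year over 10 years
```

Under the package's default risk parameters the fixture breaks even at a
mean of 556 new regular cyclists (93 per km) — the same order of
magnitude as, but not equal to, the 1,604 (267 per km) of the original
appraisal, whose background data differ. The required shift shrinks as
the source level moves from 2 to 5: a person who never cycled gains the
full level-1 volume, so fewer converts are needed — the same ordering
the reference tables show (2,151 from level 2 down to 1,373 from level
5).

## Known limitations

- Mortality only: no morbidity, QALYs/DALYs, travel-time savings,
  congestion or equity effects.
- The air-pollution domain is a proportional approximation, not a full
  exposure model; its contribution is small under the defaults.
- Mixed-source uptake (people arriving at level 1 from several levels
  at once) is not modelled; real uptake will be a blend of the four
  single-source scenarios.
- No probabilistic sensitivity analysis; the one-way grid bounds each
  assumption separately but not their joint uncertainty.
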