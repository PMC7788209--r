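---
title: "Simulating ward nurse staffing establishments and flexible staffing"
author: "wardsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ward nurse staffing establishments and flexible staffing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardsim)
```

## The problem

Hospital wards plan a *staffing establishment*: the permanent nursing hours
allocated per day, usually derived from an acuity/dependency tool that
classifies each patient into one of five levels (0, 1a, 1b, 2, 3), each
carrying an hours-per-patient-day multiplier. Most guidance sets the
establishment at the **average** measured demand. But demand varies from
shift to shift — patient numbers change, the acuity mix changes, some
patients need continuous one-to-one observation ("specialing") — and supply
varies too: staff go off sick at short notice, and cover from internal
bank or external agency pools is only sometimes available. `wardsim` is a
Monte Carlo, agent-based simulation of this system: wards are agents that
move between *understaffed*, *adequate* and *overstaffed* states each
6-hour shift, and the package compares establishment rules and
flexible-staffing policies on understaffed/overstaffed patient-shift rates
and staffing cost per patient-day.

## The model

A simulated day has four 6-hour periods (morning, afternoon, evening,
night); day 0 is a Monday. For each ward and shift, in order:

1. **Census.** The number of patients at the shift start is drawn from the
   ward's day-of-week census distribution; a five-level acuity mix is drawn
   from a ward Dirichlet (resampled once per shift) and converted to whole
   patients by largest-remainder rounding (ties to the lowest level index).
   A Poisson specialing count is truncated at the census.
2. **Demand estimate.** Daily care hours are `sum(counts * multipliers)`;
   the shift receives the period's diurnal share. Each specialed patient
   adds one whole person-shift (6 h). Hours split between registered nurses
   (RN) and assistants (HCA) by the ward skill mix; specialing hours go to
   the configured group (default HCA).
3. **Absence.** Each planned person-block (4 h or 6 h, recorded when the
   establishment was rounded) is lost independently with probability 3%
   (RN) or 4% (HCA) — short-notice sickness removes whole people.
4. **Balance and redeployment.** Face-value shortfall and surplus
   (estimate vs available, no productivity discount) are computed per
   group. Within each division, whole people move greedily from the
   largest surplus to the largest shortfall (6 h, or 3 h half-shifts;
   deterministic tie-break by ward id); RNs substitute only for RNs, HCAs
   only for HCAs, and a donor never drops below its own estimate.
5. **Temporary staff.** Remaining gaps are requested *up to the adequacy
   boundary*: blocks are derived from
   `max(0, (1 - tau) * estimate - staffing_after_redeployment)` per group.
   Each block is first a bank request, escalating to agency on failure,
   succeeding with the policy's availability probability for the staff
   group, period and channel. Unfilled blocks stay unfilled. Because
   requests stop at adequacy, hires cannot create overstaffing beyond
   block granularity — which is why simulated overstaffing is essentially
   invariant across availability assumptions.
6. **Actual requirement and classification.** What patients truly needed
   is the estimate with independent mean-one lognormal noise per acuity
   level (coefficient of variation `noise_cv`); specialing hours are not
   noised. Achieved *effective* hours discount redeployed and bank staff
   to 90% and agency staff to 75% productivity (requests, in contrast, are
   made at face value). A shift is understaffed/overstaffed when achieved
   effective hours fall more than `tau` (default 15%, as in the RAFAELA
   tool tradition) below/above the actual requirement; the boundary itself
   counts as adequate.

Outcomes are **patient-shift weighted**: every patient present at the
start of an understaffed ward-shift counts. A patient-day is four patient
shifts. Replications are independent years; summaries report means with
95% t-intervals.

## Establishment scenarios and policies

The planning window simulates `observation_days` (default 20) days of
classified demand with noise off, using a dedicated RNG (`base_seed - 1`)
so the window is independent of any simulated year. Baselines:

| scenario | statistic |
|---|---|
| `low` | 0.8 × mean daily demand |
| `standard` | mean daily demand |
| `high` | empirical 90th percentile (type-7 interpolation) |

Daily hours are spread over the four periods by the ward's diurnal
profile, split by skill mix, and each (period, group) value is rounded to
the nearest sum of 4 h/6 h blocks (`{0, 4, 6, 8, ...}`, ties round up).

Policies: `none` (no redeployment, no hires), `empirical` (availability
5%–45%, higher for assistants and daytime, agency 10 points below bank),
`higher` (all 0.75), `unlimited` (all 1).

## Parameters that matter

* **Care multipliers** (h/patient-day per level), default
  `(4.2, 5.8, 7.2, 8.4, 24.0)`. These are synthetic placeholders — the
  real instrument's multipliers are licensed — but they are *scaled* so a
  typical mix yields ≈6–6.5 nursing hours per patient-day, the
  establishment scale reported for English acute wards (≈42–576 h/day per
  ward). The scale is not cosmetic: with multipliers half this size, a
  6 h block is up to half of a night-period establishment, block rounding
  swamps the 15% band, and both outcome tails inflate for reasons that
  have nothing to do with staffing policy.
* **`noise_cv`** (default 0.1): shift-level unpredictability of true need
  per acuity level. At 0 the actual requirement equals the estimate.
* **Absence** (0.03 RN / 0.04 HCA): approximates reported national
  nursing sickness differentials.
* **`tau`** (0.15): half-width of the adequate band.
* **Productivity** (0.9 redeployed/bank, 0.75 agency): applied to
  achieved hours only, never to requests.
* **Rates**: configurable base rates per band, 30% employer on-cost
  (bank staff attract on-costs on only half their hours, so bank <
  permanent in the same band), all-inclusive agency caps, and a 30%
  unsocial-hours uplift (night period and weekends) for permanent and
  bank staff.

## What the synthetic generator emulates — and what it does not

`generate_hospital()` reproduces the *statistical structure* the engine
needs: per-ward day-of-week census distributions (discretized truncated
normals with a weekday/weekend occupancy contrast, mean occupancy ≈0.90
weekday/0.85 weekend, CV 0.08), Dirichlet acuity-mix dispersion
(concentration 50), Poisson specialing (0.2/shift), skill mixes in
0.45–0.70, beds 10–36, and contiguous division blocks. It makes **no**
claim to match any real hospital's histograms: real census distributions
are often skewed and autocorrelated, real acuity mixes differ by
specialty, and real divisions are clinical, not contiguous. A green test
therefore establishes that the *mechanism* behaves as specified under a
plausible stated world — not that the package reproduces any published
rate. The source study's printed percentages and costs derive from
confidential ward-level data and are used here only as qualitative
ordering checks (understaffing falls and overstaffing rises with higher
baselines; understaffing falls with availability; overstaffing is nearly
invariant to availability; cost rises with both).

## Numerical choices

* **Percentile convention**: type-7 (linear interpolation at
  `(i - 1)/(n - 1)` plotting positions) for the `high` baseline.
* **Rounding**: per (period × group), nearest achievable block sum, ties
  up. Establishment blocks prefer 6 h, covering remainders with 4 h
  blocks.
* **Shortfall decomposition**: fewest blocks, then least excess —
  `floor(s/6)` whole blocks plus one final 3 h half-block when the
  remainder is ≤ 3 h, else one more whole block. Temporary hires may take
  the final half-block: without that, a ≤3 h residual can never be
  covered and the unlimited-availability limit (0% understaffed with
  productivity 1 and no noise) would fail on small night shifts.
* **Classification boundary**: strict inequalities with a
  `1e-9`-relative epsilon so exact ±15% cases are adequate despite binary
  rounding.
* **RNG**: one seed per replication, split into named substreams
  (census, acuity, specialing, absence, noise, availability), each a
  saved R RNG state. Changing the policy — which changes how many
  availability draws occur — leaves the other streams untouched, so
  policy comparisons are coupled on the same demand/absence history.
* **Degenerate inputs**: an infinite Dirichlet concentration gives a
  fixed mix (and consumes no draws); zero-demand wards give all-zero
  plans; a zero-requirement, zero-achieved shift is adequate; a Poisson
  specialing draw is truncated at the census.

## Design choices where the design was open

* **Requests target adequacy, not the full estimate.** Temporary staff
  are requested only to lift face-value staffing to `(1 - tau)` of the
  estimate. This follows the source study's stated mechanism (temporary
  staff were requested only to reach "adequate" and so did not contribute
  to overstaffing); filling to the full estimate makes overstaffing climb
  steeply with availability, which contradicts the reported structure.
* **Exact constancy of overstaffing across availability rows is not
  attainable**, because classification is made against the *noisy*
  requirement: a fill can cross the +15% boundary when the noise draw
  puts the actual requirement just below achieved/1.15. The acceptance
  suite asserts the structural hire cap exactly, and constancy to well
  under one percentage point.
* **Bank before agency**, both in 6 h blocks (final 3 h half permitted);
  redeployment is greedy rather than an optimal matching — a rule-based
  response, with an exhaustive-search oracle bounding the gap (zero on
  all enumerable block instances).
* **Permanent staff are salaried**: costed on the planned establishment
  whether present or not; redeployed hours are cost-neutral.
* **Division assignment** is contiguous blocks of `wards_per_division`
  (last block possibly smaller) — the source does not describe division
  construction.
* **Specialing** consumes exactly one person-shift per specialed patient
  and defaults to assistant hours; the window includes specialing demand.

## Known limitations

* No within-shift dynamics, no admission/discharge process, no
  autocorrelation between shifts or interaction between wards.
* No cross-division redeployment, overtime, or multi-skill substitution.
* Cost tables are stand-ins, not national pay scales or agency caps;
  annualized establishment arithmetic (holiday/uplift factors) is out of
  scope.
* Absolute outcome rates depend strongly on the synthetic demand
  variability and the multiplier scale; only orderings and structural
  invariants are claims of this package.

## A worked run

```{r example, eval = FALSE}
hospital <- reference_hospital(4)
res <- run_replications(hospital, scenario = "standard",
                        policy = "empirical", n_replications = 10,
                        base_seed = 1)
res$summary
```

See the README for output from an actual run, and
`tests/testthat/test-acceptance.R` for the property suite (fixed-point and
unlimited-flex limits, hire cap, monotone orderings, fill-rate closed
forms, redeployment optimality, absence calibration, determinism, cost
identities).
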