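---
title: "Entropy-weighted nearest-neighbour air quality evaluation: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted nearest-neighbour air quality evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqeval)
```

## The evaluation model

The package grades daily ambient air quality against a regulatory
standard by treating the standard's per-level threshold vectors as known
clustering centers and assigning each day the level of its nearest
center. Two ingredients make that meaningful:

**Commensuration.** Pollutant concentrations live on wildly different
scales (PM10 in hundreds of µg/m³, CO in single mg/m³), so raw Euclidean
distance is dominated by whichever indicator happens to have big numbers.
Every indicator is therefore min–max normalized. All five pollutants
handled here are *cost* indicators — lower is better — so
`r = (max - x) / (max - min)`, placing the cleanest value at 1 and the
dirtiest at 0; the benefit form `(x - min)/(max - min)` is implemented and
tested but unused by the case study. The same affine map is applied to the
centers, so that "Level I" sits near the clean end of every axis.

**Indicator weights.** The entropy weighting method scores each
indicator by how unevenly its values are spread over the days evaluated:
with frequencies `f_ij = r_ij / sum_j r_ij`, the entropy is
`e_i = -k * sum_j f_ij log f_ij` (with `0 log 0 := 0`) and the weight is
`lambda_i = (1 - e_i) / sum_i (1 - e_i)`, which always sums to one. A
nearly uniform indicator carries little evaluative information and gets
little weight. The weighted Euclidean distance
`sqrt(sum lambda_i (a_i - b_i)^2)` is available, but the library default
is unweighted — the distance definition itself carries no weights, and on
the bundled month the weights are nearly equal (~0.2 each), so ranks are
robust either way.

### Assumptions

* Days are graded independently; there is no temporal smoothing.
* Thresholds and observations must share units per indicator; the
  package checks and refuses rather than converting (CO stays in mg/m³
  on both sides, so normalization cancels units).
* Center thresholds are non-decreasing with level for cost indicators —
  validated when a standard is loaded.
* An indicator whose thresholds are *identical across all levels* of the
  standard in use cannot discriminate between levels and is dropped
  before evaluation. Under the two-level GB 3095-2012 this removes CO and
  NO2 (their Level I and II thresholds coincide); under the three-level
  GB 3095-1996 their Level III thresholds differ, so everything is kept.
  One uniform rule reproduces both situations.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `averaging_time` | `"24h"` | which threshold row of the standard to use; the bundled data are 24-hour means |
| `pool` | `"joint"` | min–max extremes from observations ∪ centers; `"observations"` uses the data extremes and clips centers into \[0, 1\] |
| `weighting` | `"none"` | unweighted vs entropy-weighted distance |
| `k_convention` | `"objects"` | entropy constant: `1/ln n` (objects), `1/ln m` (indicators), `1/ln 10` (common log), or custom |
| `tie` | `"worst"` | equidistant centers resolve to the more polluted level — the health-protective choice |

The joint pool is the default because a standard's upper thresholds can
exceed everything observed in a clean-ish month; pooling keeps center
coordinates inside \[0, 1\] and distances comparable. With
`pool = "observations"`, a column that is constant across the
observations (e.g. a single-day input) falls back to the pooled extremes
rather than failing.

## Calibrating against the published reference results

The bundled Beijing February 2014 record ships with the results its
original published analysis reported: five indicator entropies and
weights, and per-day level assignments under both standards
(`aqeval_reference()`). That analysis left two things unstated, and the
package resolves both *empirically*, by enumeration and comparison,
rather than by guessing.

### The entropy constant

The textbook constant `k = 1/ln n` bounds entropies by 1, yet the
reference entropies are all near 1.39. `calibrate_entropy()` enumerates
frequency source (normalized `r` vs raw `x`) crossed with
`k ∈ {1/ln n, 1/ln m, 1/ln 10}` and scores each candidate's maximum
absolute residual against the reference row:

```{r}
cal <- calibrate_entropy(beijing_feb2014())
cal
```

Exactly one candidate matches to the printed precision: **common-log
frequencies of the normalized values** (`k = 1/ln 10`, residual
≈ 3.5e-5). Every residual is recorded either way. The library default
remains `k = 1/ln n`; `k_convention = "common_log"` is what the
case-study weights use. Note a side effect of `e > 1`: every `1 - e_i`
is negative, so the usual "low entropy → high weight" reading inverts;
`entropy_weights()` records a diagnostic note when this happens, and the
package reproduces the numbers without endorsing the interpretation.

Two of the five reference weights (PM10 and NO2) disagree with the
weights recomputed from the reference *entropies* by half a unit in the
fourth decimal (e.g. `(1 - 1.3595)/1.9427 = 0.18505`, printed `0.1850`):
the original weights were evidently rounded from unrounded entropies.
The tests assert exact four-decimal agreement where it is attainable and
`< 6e-5` where it is not.

### The classification configuration

Nothing in the reference states how centers were made commensurate with
the data, whether the distance was weighted, or which indicators entered
it. `calibrate_classification()` enumerates a grid — indicator set
(rule-retained vs particulate-only) × pool (joint vs observations) ×
distance (unweighted vs entropy-weighted) — and scores each candidate by
per-day rank agreement:

```{r}
calibrate_classification(beijing_feb2014(), "GB3095-2012")
calibrate_classification(beijing_feb2014(), "GB3095-1996")
```

The particulate-only candidate is in the grid because haze-fog is a
particulate-pollution phenomenon and because SO2's Level II threshold
(150 µg/m³) exceeds every observation of the month — an indicator whose
worse-level thresholds are never approached cannot vote for the worse
level and only inflates its distance.

Selection is by maximum agreement, with two documented refinements:
candidates within **one day** of the maximum are treated as equivalent
(one day in 28 is below the resolution of the reference's own rounding —
its closest day's two distances differ by 0.0075), and equivalents are
broken toward more indicators, then unweighted distance, then the joint
pool. The pinned outcome (`case_study_config()`):

* **GB 3095-2012**: particulate indicators (PM2.5 + PM10), joint pool,
  unweighted — reproduces **28/28** reference ranks, including the two
  severe-pollution runs (11–16 and 20–26 February).
* **GB 3095-1996**: all four available indicators, observation pool,
  unweighted — **19/28**, with the nine residual disagreements reported
  per day.

Full agreement for the 1996 experiment is provably unattainable, not
merely unachieved: for the I-versus-II decision only indicators whose
Level I and II thresholds differ can matter (PM10 and SO2), and on
17 February both sit below their I/II threshold midpoints, forcing
Level I under *any* positive per-indicator scaling — yet the reference
assigns Level II. The remaining disagreements cluster on days where the
gaseous Level III thresholds (CO 6 mg/m³, SO2 250 µg/m³), far above
anything observed, inflate the distance to Level III. Reproduction of the
reference's printed *distance values* is correspondingly out of reach at
any configuration in the grid; rank-level agreement plus this calibration
report is the package's reproduction claim.

## Numerical choices

* **Constant columns** (max = min) are an error under plain
  normalization — the formula divides by zero and the column carries no
  information — except under the observation pool, where the pooled
  extremes break the tie (see above).
* **Exact distance ties** go to the worst tied level; `tie = "best"` is
  available.
* Zero frequencies use the `0 log 0 := 0` convention; an all-zero
  normalized column (entropy undefined) is an error.
* Weights are computed exactly as the formula prescribes even when some
  `1 - e_i` change sign (weights outside \[0, 1\] are possible then); a
  note is recorded instead of silently renormalizing.
* Distances are printed to four decimals in result files; internal
  computation is double precision throughout.

## The synthetic generator

`aq_scenario()` / `aq_simulate()` produce a synthetic month:
log-normal baselines per pollutant, a shared latent "haze factor" giving
positive cross-pollutant correlation (stagnant weather loads all
pollutants together, matching the strongly co-moving columns of the real
month), and episode windows whose concentrations are multiplied by an
amplitude. Defaults mirror the bundled record's structure: 28 days, two
episodes (days 11–16 and 20–26) of amplitude 4, baseline medians near the
calm-day levels of that month (PM2.5 45, PM10 65, CO 1.1, NO2 40, SO2 30),
log-scale dispersion 0.5, haze-factor variance share 0.7. Values are
truncated at zero (vacuous for log-normals, kept for safety under future
noise models).

The generator emulates level and co-movement structure only: no
meteorology, no chemistry, no weekly cycles, no measurement error model,
and episode onsets are step functions rather than ramps. Tests passing on
synthetic data therefore certify the pipeline's statistical behaviour
(episode days get graded worse; null episodes don't), not fidelity to any
real airshed.

## Problem sizes and test design

The test suite works at the scale the method is meant for: the 28 × 5
bundled month for all case-study checks, 100–120 random instances
(5–15 days × 2–6 indicators) for the property checks (weight simplex,
normalization range, metric axioms, permutation/scale invariance) against
independently written naive oracles, and 200 seeded 28-day replicates for
the synthetic episode-recovery check (amplitude 3, the weakest "strong"
episode; pooled across replicates a clear majority of episode days must
reach the worst level). The whole suite runs in well under a minute.

## Known limitations

* The method grades relative to a standard's thresholds; it is not an
  AQI/IAQI calculator and does no breakpoint interpolation.
* Min–max normalization makes results depend on the evaluated batch:
  adding a day can change other days' normalized coordinates (and, with
  the observation pool, their grades). `predict()` on a fitted
  evaluation deliberately freezes the fitted extremes for new days.
* Entropy weights need at least two days and are unstable for very short
  records.
* The calibrated case-study configuration is pinned to one month of one
  city; for other data the library defaults (rule-retained indicators,
  joint pool, unweighted) are the recommended starting point, with
  `calibrate_classification()` available when reference gradings exist.
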