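---
title: "Methods: the phenology model and its three calibrators"
author: "soycal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the phenology model and its three calibrators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soycal)
```

## The problem

Soybean is a short-day crop: its progress toward flowering and maturity is
driven jointly by temperature and by daylength. Process models describe a
cultivar by a small set of cultivar-specific parameters (CSPs) that are not
directly measurable in the field and must be estimated from observed
phenology. `soycal` implements a compact photothermal phenology model with
the seven classical CSPs, and three estimation algorithms for them — a
modified NSGA-II, GLUE, and Differential Evolution — together with the
evaluation metrics and a repeat-calibration protocol, so the three
algorithms can be compared end-to-end on fully synthetic multi-site,
multi-cultivar experiments.

The four predicted events are first flowering (FS), first pod (PS), first
grain (GS) and first maturity (MS).

## The forward model

Daily development rate is the product of two dimensionless factors:

* a **thermal factor** `TF`, a trapezoid on the daily mean temperature
  `(Tmax + Tmin)/2` with cardinal temperatures `t_base < t_opt_lo <=
  t_opt_hi < t_ceil` (defaults 6, 26, 30, 45 degC — configuration values
  for a warm-season legume, exposed in `cardinal_temps()`);
* a **photoperiod factor** `PF = clamp(1 - PPSEN * (DL - CSDL), 0, 1)` for
  daylength `DL` (hours): development is unconstrained at or below the
  critical short day `CSDL` and declines at `PPSEN` per hour beyond it.

One day at `TF = PF = 1` contributes one *photothermal day*. A phase
completes on the first calendar day its accumulated rate reaches the phase
duration; accumulation for each phase starts the day after the event that
opens it. The phase durations are the CSPs `EM-FL` (emergence to first
flower), `FL-SH` (first flower to first pod), `FL-SD` (first flower to
first grain, sharing the post-flowering accumulator with `FL-SH`), and
`SD-PM` (first grain to maturity). Because `FL-SH <= 10 < 12 <= FL-SD`
within the calibration box, PS always precedes GS.

Three further choices complete the model:

* **Emergence** is thermal-only: accumulation of `TF` from the day after
  sowing up to a threshold `e_base + e_slope * depth` (defaults 3.0
  photothermal days + 0.1 per cm; both configurable). Sowing depth
  therefore delays emergence slightly, which is all the information the
  experiment metadata carries about it.
* **Post-anthesis photoperiod sensitivity**: from the day after FS the
  effective critical short day tightens to `CSDL - R1PPO`, i.e. `R1PPO`
  (hours) is the increase in daylength sensitivity after anthesis. The
  photoperiod factor applies from emergence onward (a reproductive-only
  variant can be had by setting `R1PPO` small and `CSDL` large, but is not
  a switch; this is a deliberate simplification).
* **Daylength** uses the standard hour-angle formula with solar declination
  `23.45 sin(2 pi (284 + doy)/365)` degrees and a twilight elevation angle
  of -6 degrees by default (civil twilight, the convention of daily crop
  models; `twilight_angle = 0` gives geometric sunrise/sunset). The
  hour-angle cosine is clamped to [-1, 1] so polar day and night are
  defined.

Stage dates are integer calendar days (the first day the accumulator meets
the threshold), matching the whole-day resolution of field scoring. Day of
year is counted past 366 when a season crosses the year boundary so stage
arithmetic stays monotone within a season.

This forward model is deliberately small. The full soybean growth model
family that motivates the parameter set also tracks carbon, water and
nitrogen balances; none of that is represented here, and no claim is made
that this model reproduces any particular published simulator's internals.
What it preserves is the *role* of each of the seven CSPs, which is what
makes calibrating them meaningful:

| CSP | units | range |
|-----|-------|-------|
| CSDL | h | 11.78–14.6 |
| PPSEN | 1/h | 0.129–0.385 |
| R1PPO | h | 0.189–0.549 |
| EM-FL | photothermal d | 15.5–28.9 |
| FL-SH | photothermal d | 5.5–10.0 |
| FL-SD | photothermal d | 12.0–16.0 |
| SD-PM | photothermal d | 12.0–16.0 |

## The three calibrators

All three search the same box (`csp_bounds()`), start from uniform draws,
and score candidates by simulating the four stages against one cultivar's
observed dates. A candidate whose simulation fails to reach a stage within
the horizon (default 200 days after sowing) is *penalised*, never dropped:
per-stage objectives are set to the horizon length, the DE fitness to its
square, and the GLUE likelihood to the corresponding near-zero value. This
keeps population sizes fixed and runs abortion-free.

### Modified NSGA-II (`run_mnsga2`)

The objectives are the four per-stage absolute errors in days. Relative
errors were rejected because the final single-solution selection already
uses the weighted relative total error, and duplicating it would make the
multi-objective stage vacuous. The loop is the standard elitist NSGA-II:
fast non-dominated sorting, crowding distance, binary tournament on
(rank, crowding), simulated binary crossover (`eta_c = 20`, `pc = 0.8`),
polynomial mutation (`eta_m = 20`, `pm = 1/7` per coordinate), merge of
parents and children, and environmental selection (fill by front, truncate
the splitting front by descending crowding). Children are clipped to the
box after variation.

The *modification* is the final step: among the rank-1 individuals of the
last generation, the returned solution minimises

```
Err_tol = sum_i w_i * |(O_i - S_i) / O_i|,   i in {FS, PS, GS, MS}, w_i = 1
```

with ties broken by the weighted least-squares objective
`phi = (c - Xb)' M (c - Xb)` (`M = diag(w^2)`; `pest_phi()`), then by
first-seen order. `Err_tol` is the operative criterion; `phi` is the
diagnostic and tie-breaker.

The per-generation diagnostic trace records the *best-so-far* `Err_tol`
over rank-1 candidates (a cumulative minimum). With four objectives the
rank-1 front can exceed the population size, and crowding truncation may
then discard the front member that happens to minimise `Err_tol`, so the
raw per-generation value is not guaranteed monotone; the best-so-far trace
is, and it is the quantity a user should read as convergence. The final
selection still uses only the final front, which is the documented
procedure.

### GLUE (`run_glue`)

A single batch of `n_samples` uniform prior draws (default 20000) is
scored with a Gaussian likelihood

```
L = exp(-SSE / (2 * sigma2 * 4)),  SSE = sum_i (O_i - S_i)^2
```

normalised by the batch maximum; samples with normalised likelihood `>=
0.90` form the behavioral set (size `N_fi`; the best sample always
survives). The point estimate is the likelihood-weighted mean, with
weighted 2.5/97.5 percentile intervals per coordinate.

`sigma2` is the expected *observation error variance* of a stage date and
defaults to 4 days^2 (a 2-day scoring granularity). An earlier candidate
default — the variance of the observed stage dates themselves — was
measured and rejected: that quantity (hundreds of days^2, since it spans
flowering to maturity) describes season length, not measurement
uncertainty, and it flattens the likelihood so much that the behavioral
set at the 0.90 threshold admits candidates up to ~10 days RMSE away and
the weighted mean drifts. With `sigma2 = 4` the 0.90 threshold keeps
candidates within about 1.3 days^2 of the best SSE per stage, which is the
intended "behavioral" notion for data scored on whole days. The value is a
configuration field, not a constant.

The threshold is applied to the max-normalised likelihood so that 0.90
means the same thing regardless of `sigma2`.

### Differential Evolution (`run_de`)

DE/rand/1/bin: donor `x_r1 + F (x_r2 - x_r3)` with three distinct
companions, binomial crossover at `CR = 0.5` with one forced donor
coordinate, greedy replacement (ties go to the trial), bounds by clipping.
The fitness is the mean squared stage error in days^2. Defaults are
population 500 and 40 generations.

The two control constants deserve a note: the study conditions label them
"crossover probability 0.5" and "mutation 2.38/sqrt(2 N_op)" with `N_op =
7`. The second expression evaluates to about 0.636, which is a standard
recommendation for the differential *weight* F and would be an atypical
per-gene mutation probability; it is therefore mapped to `F`, and 0.5 to
`CR`. Both are ordinary config fields (`de_config()`) if a user disagrees.

## Evaluation and the protocol

`rmse()`, `mae()` and `r2()` are the three goodness-of-fit measures; `r2`
is computed about the 1:1 line (`1 - RSS/TSS` with residuals taken against
the simulation, TSS about the observed mean), which can be negative and
errors out for constant observations. Pooled metrics concatenate all
cultivar-by-stage pairs first.

`run_calibration_protocol()` repeats a calibration (default three times)
with distinct sub-seeds drawn deterministically from the top-level seed,
compares the repeated parameter vectors pairwise with a paired one-tailed
t-test across the seven parameters, and returns the coordinate-wise mean
as the final estimate. Degenerate t-test inputs are defined explicitly:
zero-variance differences are declared not significant when their mean is
zero (p = 1) and significant otherwise (p = 0). Aggregation never blocks
on significance; the flags are reported.

`run_cross_evaluation()` implements the cross-experiment design: cultivars
C1–C3 calibrated on experiment 1 are evaluated on experiment 2, C4–C6 from
experiment 2 on experiment 3, and C7–C9 from experiment 3 on experiment 1,
with per-pairing and pooled metrics plus a full observed-vs-simulated pair
dump from which every reported number can be recomputed.

## The synthetic suite

`build_experiment_suite()` generates the whole test bed from one seed:

* **Weather**: a sinusoidal annual temperature cycle (annual mean 16 degC,
  amplitude 11 degC, diurnal range 8 degC, daily Gaussian noise sd 1.5
  degC) peaking in mid-July for northern sites — a lower-Yangtze summer in
  caricature. Two calendar years per series cover seasons that cross the
  year boundary.
* **Sites and sowing**: site A at 31.571 N sown 5 July (year 1) and 24 June
  (year 2); site B at 32.059 N sown 21 June (year 2); depth 3 cm.
* **Cultivars**: nine parameter vectors drawn uniformly from the box,
  *rejection-sampled* so that every cultivar reaches maturity within the
  200-day horizon in all three experiments. The rejection step matters:
  a late-June sowing at ~32 N with a low CSDL and high PPSEN can stall
  development into autumn and never mature; such draws describe cultivars
  a breeder would not sow there, and they would leave the suite without
  observations. Sampling remains deterministic under the seed.
* **Observations**: forward predictions plus integer-rounded Gaussian
  noise (default sd 2 days, the granularity of field scoring), re-drawn
  until the stage ordering `fs <= ps <= gs < ms` holds. At `noise_days =
  0` the observations equal the model exactly.

What the suite does **not** emulate: structural error (the model that
generated the data is the model being calibrated), weather measurement
error, within-plot replicate variation, and any stress response. Passing
parameter-recovery tests on this suite therefore demonstrates that the
calibrators work as optimisers and that the pipeline is correct — not that
the forward model would fit real field observations, where evaluation
errors are dominated by the structural mismatch that is absent here. That
is also why independent-evaluation errors on the synthetic suite (roughly
2–6 days pooled RMSE at 2-day noise, across suite replicates) sit at, and
sometimes below, the lower end of what comparable field studies report:
with no structural error the calibration can approach the noise floor.

Equifinality is endemic by construction — seven parameters are fit to four
observations — so recovered *parameters* are not expected to match the
generating truth; recovered *stage dates* are, and all recovery contracts
in the tests are stated in phenology space.

## Numerical choices and degenerate inputs

* Threshold crossing uses plain `>=` on sequentially accumulated sums; the
  test oracle (a literal day-by-day loop) accumulates in the same order,
  so implementation and oracle agree exactly, not approximately.
* Crowding distance: boundary individuals get `Inf`; zero-range objectives
  contribute 0 (duplicated objective vectors never divide by zero).
* Tournament full ties (equal rank and crowding) are decided by a fair
  coin from the run's seeded stream.
* `select_optimal` ties: smaller `phi`, then first-seen order.
* Weighted quantiles invert the weighted empirical CDF (no interpolation),
  so a single behavioral sample yields a degenerate interval.
* All run functions take a single seed and use one R RNG stream;
  `run_calibration_protocol` derives sub-seeds by sampling integers from
  the seeded stream, so any repeat is reproducible bit-for-bit.

## Problem sizes

The package defaults are the full study conditions (MNSGA-II 1000 x 20,
GLUE 20000, DE 500 x 40). The test suite and the acceptance script use
reduced budgets — MNSGA-II 200 x 20, GLUE 5000, DE 100 x 40, nine
cultivars, three repeats — which the recovery tests show are already
sufficient to reproduce noise-free stage dates within a day or two; the
comparison of algorithms is about estimation behaviour, not about raw
budget.

## Known limitations

* The forward model is a minimal photothermal accumulator; no vernalation,
  hourly temperature response, CO2 or stress effects, and no growth
  variables (biomass, LAI, yield).
* GLUE here is the pragmatic behavioral-set procedure, not a formal
  Bayesian posterior; interval coverage is not calibrated.
* The DE variant is plain rand/1/bin; self-adaptive variants are out of
  scope.
* Observed dates must be strictly positive in the `Err_tol` denominator,
  which day-of-year values always satisfy.
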