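---
title: "Ecological windows for dredging near seagrass meadows: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological windows for dredging near seagrass meadows: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecowindows)
```

## The problem

Dredging plumes reduce the light reaching benthic habitats. For seagrass
meadows, whose growth and mortality are dominated by light availability,
the impact of a dredging campaign depends strongly on *when* it happens and
*how long* it lasts, because the meadow's capacity to resist and to regrow
varies through the year and across genera with different life histories.
An *ecological window* is a period in which a given stressor can be
scheduled with minimal impact. `ecowindows` estimates such windows by
simulating a probabilistic whole-of-system model of meadow state under
dredging scenarios and scoring the simulated response against three
resilience criteria.

## The dynamic Bayesian network

Meadow state is described by a set of discrete nodes. The shipped
reference topology has 17 nodes: an environment driver (`light`, states
below/above saturation), four site descriptors (climate, tidal regime,
meadow type, life history), process nodes (physiological status, growth,
seed density, recruitment from seeds, ability to resist, ability to
recover, loss, recovery, net change) and population nodes (baseline
population, realised shoot density, realised biomass). Each non-root node
carries a dense conditional probability table (CPT) over the full grid of
its parents' states; sparse or default-row table dialects are rejected at
validation so configurations stay unambiguous.

Time advances in calendar-month slices. Four nodes carry their own state
across slices (physiological status, seed density, baseline population,
realised shoot density); this *interface* set is what makes the model
dynamic. The model is *non-homogeneous*: regime selectors switch a node's
CPT with the calendar month, which encodes the growing/senescent season,
the seed-set window and the germination window, oriented by the site's
hemisphere (southern-hemisphere growing season October–March). The light
driver enters as soft evidence: in month `m` the node `light` is assigned
the distribution `(1 - p_m, p_m)` where `p_m` is the site's monthly
probability of an above-saturation light day.

### Exact inference, its oracle, and the compiled fast path

Filtering is exact. At each slice the joint distribution over the
interface nodes is propagated by sum-product variable elimination over the
intra-slice factors, conditioning on the previous interface joint; node
marginals are read off during the same pass (valid because all downstream
factors are proper conditionals in pure forward filtering, summing to 1).
No sampling and no projection are involved. The reference topology keeps
the interface at 4 nodes (144 joint states) precisely so exact filtering is
cheap; a hard cap (default `1e5` joint states) raises an explicit resource
error rather than silently approximating.

Two independent checks guard the implementation. First,
`brute_force_trajectory_joint()` re-derives the same trajectories by direct
enumeration: the complete joint over *all* nodes of a slice is computed by
multiplying table entries over every (previous interface state, current
full state) pair. It shares no factor algebra with `forward_infer()` and
agrees with it to below `1e-10` on randomized networks. Second, because
soft evidence on a root enters the slice update linearly, the whole update
collapses to `new = sum_e P(env = e) * T[month, e] %*% prev` with
transition matrices precomputed once per calendar month and environment
state (`dbn_compile()`). The compiled path is exact — it is checked against
the generic path to `1e-10` — and is what the scenario engine uses.

After each slice the interface joint is renormalized; a renormalization
factor beyond `1e-6` triggers a warning (in practice drift stays at the
`1e-15` level).

## Discretization and the weighted mean

Population factors are discretized as percentages of a reference value:
zero = 0, low = (0, 20], moderate = (20, 80], high = (80, 100]. Loss and
recovery factors use zero = 0, low = (0, 10], moderate = (10, 30],
high = (30, 100]. Intervals are half-open on the continuous percent scale,
so every value classifies uniquely; printed integer thresholds such as
"21–80" are read as the integer-labelled endpoints of these intervals.

Each non-zero state carries a five-point value grid under a uniform
distribution on its integer interval `lo..hi`:
`lo + ceiling(w * k / 4)` for `k = 0..4`, `w = hi - lo`. The ceiling-rounded
quartile is the unique simple rule reproducing the printed grid
{81, 86, 91, 96, 100} for the high state; the state value is the median
(third) point, which equals the mean for a uniform distribution.

```{r}
state_value_grid(discretization_scheme("population"))
```

State-probability trajectories are aggregated with the weighted mean
`mu'(t) = sum_j p_j(t) xbar_j`, and

```
mu(t) = p0(t)               if mu'(t) <  alpha
      = (1 - p0(t)) mu'(t)  if mu'(t) >= alpha
```

Note the deliberate scale mix of this published form: when the meadow is
near extinction (`mu' < alpha`) the trajectory reports the zero-state
*probability*, a number in [0, 1], rather than a percent-scale mean. With
`alpha = 1` — the lower edge of the low interval, the package default —
near-extinct trajectories therefore sit near 0–1 on the percent scale,
which is the intended behaviour. This is documented here prominently
because it surprises first-time users.

## Scenarios

A dredging design dredges 1, 2, 3, 6, 9 or 12 continuous months, or 6
months in alternating blocks: `6-3` = 3 on / 3 rest / 3 on (9-month span)
and `6-2` = 2 on / 2 rest, ending on a dredging block (10-month span).
The designs with a control, each applied at all 12 start months, form the
108-scenario grid per site; 28 synthetic sites give the 3024-run study
scale. During dredging months the light probability becomes
`min(baseline, level)` with level 0 (complete deprivation, the
conservative default), 0.25, 0.5 or 0.75; rest blocks and everything
outside the stress period stay at baseline.

Each run is initialisation (default 24 months, two full seasonal cycles),
stress, and response (default 60 months). Settling into the baseline
pattern is checked with a limit-cycle detector (month-matched
total-variation distance below `1e-3` across consecutive periods) and
logged, not enforced — transitory (annual) meadows cycle through zero by
design. The control trajectory of the same site, started from the same
initial beliefs and horizon, is the baseline for all comparisons; it is
*month-matched*, because an annual meadow's baseline may itself be zero in
some months, making any scalar baseline meaningless.

The response clock starts at the first slice after the last dredging month.
Resistance is evaluated at that slice; recovery time is the smallest
`m >= 0` with the response within 20 % of baseline at `stress end + m`
(`m = 0` meaning already inside the band when the stress ends), censored as
"permanent" beyond 60 months; persistence compares mean zero-state
probabilities over the 60-month response window (ratio below 1.025). When
the baseline weighted mean is exactly zero, relative change is defined as
0 — a response above an absent baseline is not a loss. The published
account does not state whether the extinction-risk ratio aggregates by
instantaneous value, mean or maximum; the package defaults to the mean
over the response window (the most stable choice) and offers the maximum
behind `resilience_criteria_config(persistence_aggregate = "max")`.

Scores: 4 = all three criteria, 3 = resistance + recovery, 2 = recovery +
persistence, 1 = recovery only, 0 = recovery failed. Resistance as defined
implies the recovery criterion (it is the same band test at `m = 1`), so
resistance without recovery is rejected as inconsistent input. A cell with
score ≥ 1 is an ecological window; `min_light_for_window()` walks the
light levels upward and returns the first that opens one.

## The synthetic archetypes

The original model's 34-node structure and its expert-elicited tables are
not published, so this package ships a smaller reference topology that
retains every factor named in the main analysis, together with a
*synthetic* CPT generator. The generator's goal is qualitative fidelity to
the three seagrass life histories, not numerical reproduction of any
elicited probability:

* **colonising** (e.g. *Halophila*): heavy seed investment, rapid growth
  and turnover, low physiological resistance — crashes under deprivation
  but recovers quickly;
* **opportunistic** (e.g. *Zostera*): intermediate on every axis;
* **persistent** (e.g. *Amphibolis*): high physiological resistance, slow
  growth and sparse seed production — resists short stress, recovers
  slowly once damaged.

Archetype behaviour is expressed as linguistic labels (certainty,
extremely likely, very likely, likely, 50/50, unlikely, very unlikely,
extremely unlikely, impossible) mapped to probabilities
{1.0, 0.95, 0.85, 0.70, 0.50, 0.30, 0.15, 0.05, 0.0} — the label set is
standard; the numbers are this package's defaults (symmetric around 0.5 by
construction) and are overridable. Tables are built from ordered logistic
kernels: each row's location is a function of the parents' ordinal scores
with coefficients set by the labels, plus a small seeded jitter (±0.05,
well below every parent effect) emulating elicitation variability. Ordered
logistic rows are automatically first-order stochastically monotone in the
location, so the generator can guarantee — and verifies table-by-table —
the dominance properties the analysis relies on: better light gives
stochastically higher growth and physiological status, stronger resistance
and better physiology give lower loss, higher recovery gives higher net
change, and so on.

Several kernel choices matter for the life-history contrast and were made
deliberately:

* physiological status has a piecewise carry-over — robust while good,
  collapsing once degraded at a rate scaled by the archetype's mortality
  under low light. This is what lets a persistent meadow shrug off one
  month of deprivation yet be deeply damaged by three.
* loss is gated by *critical* physiology (as well as by light and the
  resist ability), so deprivation damage accrues with its duration rather
  than linearly.
* realised shoot density is a sticky ordinal chain whose step sizes are
  archetype-dependent: the regrowth step scales with the genus's growth
  rate and the decline step is damped by its resistance. Without this
  asymmetry every archetype relaxes back to baseline at the same mixing
  rate and recovery time carries no life-history signal.
* recovery is routed through growth and seed recruitment (the ability to
  recover), never through a direct pull toward the baseline node, so a
  slow-growing genus genuinely cannot rebound quickly.

The three shipped example sites (`example_sites()`) share a weakly
seasonal climatology (annual mean 0.72, amplitude 0.04) and differ only in
life history. This choice is deliberate: with a strongly seasonal
baseline, the month-matched 20 % recovery band is crossed whenever the
baseline itself dips seasonally, so recovery time measures the season, not
the organism. A near-limit-point baseline makes recovery time reflect the
archetype machinery. The study-scale fixture (`make_study_fixture()`)
still spans strongly seasonal, high-latitude, transitory and tropical
sites in both hemispheres.

What the synthetic data does *not* emulate: real elicited probabilities
(unavailable), burial and sediment-quality hazards, connectivity between
meadows, temperature-dependent saturation thresholds (folded into the
monthly light probability input), and observation error in site
characteristics. Passing the archetype tests therefore shows that the
*analysis machinery* reproduces the qualitative life-history contrasts
when the inputs encode them — it is not evidence about any real meadow.

## Calibration and validation utilities

Monthly light-saturation probabilities are estimated from daily series by
a conjugate beta-binomial update pooled per calendar month across years
(posterior mean and equal-tailed 95 % interval; months without data are
flagged, never interpolated). Replicated field measurements are converted
to observed state probabilities by classifying each replicate through the
discretization scheme and taking the Dirichlet(1, …, 1)-multinomial
posterior mean. Both replace MCMC-based hierarchical models with
closed-form conjugate estimators: same likelihoods, reproducible without a
sampler. Validation MSE is the mean squared difference between predicted
and observed state probabilities over aligned (time point × state) cells,
with a zero-state-only variant because avoiding local extinction is the
key management objective. The visual calibration step of matching
observations to predictions is replaced by a deterministic grid search
over a reference-value scaling minimizing the all-states MSE
(`calibrate_reference_value()`).

Sensitivity analysis fits one gradient-boosted regression tree ensemble
(via `xgboost`, single-threaded for determinism) per response variable —
the four states of shoot density, and equivalently biomass — on
logit-transformed posterior probabilities at `t` and `t − 1` (probabilities
clipped at `1e-6` before the logit, since near-deterministic regimes reach
0/1). Contemporaneous states of the response's *own* node are excluded
from the predictor set: they are deterministic complements of the response
and would absorb all influence tautologically; the node's lagged states,
including the lagged response itself, remain predictors. Relative
influence is the normalized total gain; the most influential set is
defined as weights within two orders of magnitude of the maximum.

## Numerical choices and degenerate inputs

* Probabilities are renormalized each slice; drift beyond `1e-6` warns.
* CPT rows must sum to 1 within `1e-9`; the YAML writer emits 15
  significant digits so serialized schemas re-validate.
* The interface-joint cap (`1e5` states) and the brute-force enumeration
  cap (`1e7`) raise explicit resource errors.
* Zero-baseline months: relative change defined as 0 (logged via the
  criterion attributes); persistence ratio 0/0 is 1.
* `mu' = alpha` ties break to the percent-scale branch (the indicator is
  `mu' >= alpha`).
* Environment drivers must be supplied for every environment node at every
  slice; missing drivers are an error, not an implicit uniform.

## Problem sizes used by the shipped tests

The test suite verifies the oracle equivalence on 50 randomized networks
of up to 4 nodes × 3 states × 24 slices; behavioural-signature and
monotonicity checks run the three example sites over 1/3/6-month designs
at all (or four representative) start months with the full 24 + 60-month
windows; the study-scale smoke test runs 3 sites × the full 108-scenario
grid with reduced 12 + 24-month windows. These sizes were chosen to
exercise every code path at full fidelity where it matters (the signature
checks) while keeping the default suite comfortably interactive.

## Known limitations

* The reference network is a reduced topology; burial, sediment quality
  and connectivity are declared extension points of the schema format, not
  modelled.
* No structure or parameter learning: tables come from configuration or
  the synthetic generator. No smoothing/backward pass: the use case is
  filtering.
* The compiled fast path requires month-only regime selectors and
  root-environment nodes; anything else falls back to the generic path.
* Recovery time is an integer month count; sub-monthly timing is outside
  the model's resolution.
* Scores depend on the 20 % / 6-month / 1.025 thresholds; all are
  configurable, and conclusions should be checked for sensitivity to them.
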