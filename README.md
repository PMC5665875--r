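# ecowindows

Ecological windows are pre-planned periods in which an anthropogenic
stressor — here, dredging near a seagrass meadow — can be scheduled with
minimal impact on the ecosystem. `ecowindows` implements a whole-of-system
analysis for finding them: a discrete, monthly-slice, **non-homogeneous
dynamic Bayesian network (DBN)** of seagrass meadow state driven by the
monthly probability of above-saturation benthic light, a **dredging scenario
engine**, and a **resilience scoring system** built on three criteria —
resistance, recovery and persistence. It is written for quantitative
ecologists and environmental managers who need to compare stressor
schedules under uncertainty.

## The model

Meadow state is a set of discrete nodes (population, process, site and
environment factors) with expert-style conditional probability tables.
Time slices are calendar months; transition tables switch with season
(non-homogeneous dynamics), and the light driver enters as soft evidence:
the probability `p_m` that a day in month `m` has above-saturation benthic
light. Filtering is **exact**: the joint distribution over the small
interface set (nodes with cross-slice children) is propagated by
sum-product elimination, with a brute-force full-joint oracle for
verification and a compiled fast path (per-month, per-light-state
transition matrices) for scenario studies.

Population nodes are discretized as a percentage of a reference value
(zero = 0, low = 1–20, moderate = 21–80, high = 81–100; loss/recovery nodes
use 0 / 1–10 / 11–30 / ≥31). State-probability trajectories are aggregated
by the weighted mean

    mu(t) = p0(t) * 1[mu'(t) < alpha] + (1 - p0(t)) * mu'(t) * 1[mu'(t) >= alpha],
    mu'(t) = sum_j p_j(t) * xbar_j,

where `xbar_j` is the median of the five-point uniform quantile grid of
state `j` (for high, {81, 86, 91, 96, 100}, median 91), `p0` the zero-state
probability, and `alpha` (default 1) a near-extinction threshold.

A dredging scenario is a design (1, 2, 3, 6, 9, 12 continuous months, or
6–3 / 6–2 alternating), a start month, and a permitted light level during
dredging (0, 0.25, 0.50 or 0.75; the realized probability is the minimum of
this and the baseline). Eight designs plus a control across 12 start months
give the standard 108-scenario grid per site. Each run has an
initialisation period (default 24 months), the stress period, and a
response period (default 60 months — a loss is treated as permanent if not
recovered within 5 years). Against the month-matched control trajectory,
three criteria are assessed:

* **resistance** — < 20 % change in `mu` immediately after the stress;
* **recovery** — back within 20 % of baseline within 6 months of stress
  removal (recovery time is censored at 60 months);
* **persistence** — mean zero-state probability over the 5-year response
  window below 1.025 × the baseline's.

They combine into a 0–4 score; a (design × start month) cell with score ≥ 1
is an ecological window, and `min_light_for_window()` finds the smallest
permitted light level that opens one.

Because the original expert-elicited tables are not published, the package
ships a synthetic generator: monotone CPT bundles for the three seagrass
life-history archetypes (colonising *Halophila*-like, opportunistic
*Zostera*-like, persistent *Amphibolis*-like) built from ordered logistic
kernels and a nine-label linguistic probability scale, plus seasonal light
climatologies and a 28-site study fixture. Calibration utilities estimate
monthly light probabilities from daily series (beta-binomial), convert
replicated field measurements to state probabilities
(Dirichlet-multinomial), compute validation MSE, and rank variable
influence with boosted regression trees.

## Worked example

```r
library(ecowindows)

site <- example_sites()$persistent
site
#> Site 'amphibolis-reef-synthetic' (30.0 deg S)
#>   temperate subtidal enduring meadow, persistent life history (Amphibolis)
#>   monthly P(above-saturation light):
#>     0.76 0.75 0.74 0.72 0.70 0.69 0.68 0.69 0.70 0.72 0.74 0.75

bundle <- synth_site_archetype_cpts(archetype_params("persistent"), seed = 1)
net <- build_reference_network(site, bundle)
net
#> Dynamic Bayesian network schema
#>   nodes: 17 (light, climate, tidal, meadow_type, life_history, ...)
#>   interface (cross-slice): physiological_status, seed_density,
#>     baseline_population, realised_shoot_density
#>   tables: 20

scn <- scenario(site, dredge_design(3), start_month = 4, light_level = 0)
res <- run_scenario(scn, net)
assess_scenario(res)
#> amphibolis-reef-synthetic_3-0_m04_l0: score 1 (R=FALSE C=TRUE P=FALSE),
#>   recovery time 6, extinction ratio 1.043
```

Three months of complete light deprivation starting in April costs this
persistent meadow its resistance (the weighted mean drops more than 20 %
relative to the control) and raises its 5-year extinction risk by 4.3 %,
but the meadow returns to within 20 % of baseline in 6 months, so the cell
still counts as a (marginal) ecological window with score 1. A whole
window table comes from running the full grid:

```r
results <- lapply(enumerate_scenarios(site), run_scenario, schema = net)
wt <- build_window_table(results)
summary(wt)
```

## Layout

* `R/` — DBN core and compiled propagation, seagrass reference network,
  scenario engine, resilience metrics, synthetic site/CPT generators,
  calibration and validation.
* `inst/extdata/sites/` — three synthetic example sites (one per life
  history).
* `inst/schema/network-schema.json` — the schema wire format.
* `inst/cli/ecowindows.R` — command-line front end
  (`synth-sites`, `run`, `run-study`, `windows`).
* `vignettes/ecological-windows.Rmd` — the methods vignette.
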