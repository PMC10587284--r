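---
title: "Benchmarking fishing-fleet productivity: DEA scores, Malmquist decomposition and second-stage regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking fishing-fleet productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleetdea)
library(dplyr)
```

## The problem

Industrial purse-seine fleets targeting tropical tuna have grown steadily
more effective at catching fish without any corresponding growth in nominal
effort: better fish-aggregating devices, satellite buoys with echo-sounders,
bird radar, more skilled skippers. For stock assessment and capacity
management this *effort creep* matters enormously — if a day of fishing in
2019 is worth three days of 1992 fishing, effort-based controls silently
erode. `fleetdea` implements a production-economics toolkit for measuring
this from a vessel-year panel: catches per species (normalised by spawning
stock biomass into exploitation rates), days fished, number of sets, and a
capital input such as vessel length.

Each vessel in each year, under each fishing strategy — sets on floating
objects (FOB) or on free-swimming schools (FSC) — is a decision-making unit
(DMU) compared against the other vessels active that year under the same
strategy.

## Efficiency and capacity scores

Scores come from output-oriented data envelopment analysis (DEA) under
variable returns to scale (VRS). For a vessel with inputs $x_n$ and outputs
$y_m$, the technical-efficiency program finds the largest uniform output
expansion $\theta_1$ feasible inside the convex hull of the reference
group's observed bundles:

$$
\max \theta_1 \quad \text{s.t.} \quad
\theta_1 y_m \le \textstyle\sum_j z_j y_{j,m} \;\forall m, \quad
\textstyle\sum_j z_j x_{j,n} \le x_n \;\forall n, \quad
\textstyle\sum_j z_j = 1, \quad z \ge 0 .
$$

Technical efficiency is $\mathrm{TE} = 1/\theta_1 \in (0, 1]$. The capacity
program is identical except that the constraints on the *variable* inputs
(days fished, sets) are relaxed — formally their utilisation multipliers are
free above zero, so those constraints can never bind and are simply omitted;
only the fixed capital input constrains the expansion. Its optimum
$\theta_2 \ge \theta_1$ yields capacity utilisation
$\mathrm{CU} = 1/\theta_2$. Because CU confounds genuine underutilisation
with technical inefficiency, the unbiased capacity utilisation is the ratio

$$\mathrm{UCU} = \mathrm{CU} / \mathrm{TE},$$

which isolates underutilisation net of inefficiency. A fleet-mean UCU of
0.80 reads: the fleet could have caught $1/0.80 - 1 = 25\%$ more fish with
its existing capacity, or taken the same catch with $20\%$ fewer vessels
(`capacity_implications()`).

The VRS assumption (the $\sum z_j = 1$ convexity row) is deliberate:
fishing vessels do not operate at a common optimal scale, and the
constant-returns envelope would conflate scale effects with inefficiency.

## Productivity change and its decomposition

Between adjacent years the Malmquist index multiplies out as
$\mathrm{PC} = \mathrm{EC} \times \mathrm{TC}$, computed from four Shephard
output distances $d^a(x^b, y^b)$ (the observation of period $b$ scored
against the frontier of period $a$; $d = 1/\theta$):

$$
\mathrm{EC} = \frac{d^{t+1}(x^{t+1}, y^{t+1})}{d^{t}(x^{t}, y^{t})},
\qquad
\mathrm{TC} = \sqrt{
  \frac{d^{t}(x^{t}, y^{t})}{d^{t+1}(x^{t}, y^{t})} \cdot
  \frac{d^{t}(x^{t+1}, y^{t+1})}{d^{t+1}(x^{t+1}, y^{t+1})}} .
$$

EC is catch-up toward the frontier (skill, better use of inputs); TC is the
shift of the frontier itself (technology). Per-pair indices are aggregated
as geometric means over vessels — computed in log space for numerical
stability — and chained into cumulative series anchored at the base year
= 1 (`cumulate_malmquist()`). The annualised TC rate over any sub-period,
$(\mathrm{cumTC})^{1/(Y-1)} - 1$, is the effort-creep estimate
(`annualised_rate()`).

Two structural decisions here were genuinely open:

* **Pairing.** The index needs each vessel in both years of a pair. We use
  per-pair balanced subsets — exactly the vessels present in both years —
  so entry and exit reduce a pair's sample rather than truncating the
  panel.
* **Cross-period infeasibility.** Under VRS the cross-period program has no
  feasible point when a vessel's inputs fall outside the other year's
  input hull; this is a well-known pathology of output-oriented VRS
  Malmquist indices, not a solver failure. Infeasible vessel-pairs are
  flagged, dropped from that pair's geometric mean, and counted in the
  series (`n_infeasible`) and the run manifest, so no number is fabricated
  and no record disappears silently.

## The second stage

To explain UCU, every subset of the candidate covariates (prices, fuel
cost, piracy events, dipole index, engine power, set counts, buoy
deployments, the TAC dummy) is fitted by OLS and ranked by AIC
(`enumerate_ucu_models()`; ties prefer fewer parameters). The best model is
refitted and bootstrapped by case resampling (`bootstrap_ucu()`, default
B = 1000): per covariate we report the bootstrap bias
$\overline{b^*} - b$, the corrected estimate $2b - \overline{b^*}$, the
bootstrap standard error, and a significance code from the smallest
two-sided percentile interval excluding zero. Case resampling is robust to
the heteroskedasticity that score regressions typically show
(`ucu_diagnostics()` runs Breusch–Pagan and Durbin–Watson checks at 5%);
cluster resampling by vessel is available via `resample = "vessel"` for
within-vessel dependence.

The elasticity of UCU to covariate $x$ is $E = b \,(\Delta x / \Delta y)$:
the expected percent change in UCU per 1% change in $x$. $\Delta x$ and
$\Delta y$ are, by default, means of first differences of the annual
fleet-mean series over the analysis period; an endpoint-difference variant
is available (`mode = "endpoint"`). The formula's prose reading is
ambiguous in parts of the applied literature (one also sees "a 1% change
in $x$ gives $b/E$% change in $y$"); we follow the interpretation used in
reported results — $E$ itself is the % response — and keep both $\Delta$
conventions explicit in the output so the arithmetic is auditable.

OLS on a (0, 1]-bounded score is a deliberate, standard choice for
second-stage DEA regressions; a bounded-response model is out of scope
here.

## The synthetic fleet

`simulate_fleet()` generates panels with *known* ground truth so that every
stage can be validated against what it should recover:

* **Frontier.** Potential output per species is
  $q_s \cdot L^{0.30} D^{0.25} S^{0.25}$ (length, days, sets); the
  exponents sum to 0.8 < 1, giving the concave, VRS-consistent frontier
  the scores assume, with interior room for inefficiency.
* **Drift.** The frontier is multiplied by $(1 + g)^{t - t_0}$; the default
  $g = 0.036$ (3.6%/yr) is a realistic effort-creep rate for a tropical
  tuna purse-seine fleet. The generator's `true_tc` is exactly $1 + g$.
* **Inefficiency.** True TE is drawn i.i.d. Beta(6, 2) (mean 0.75, mass
  near 1), stationary over time; observed outputs are
  `true_te` × frontier, so no vessel ever exceeds its year's frontier and
  the per-pair geometric-mean TC is an (asymptotically) unbiased estimate
  of $1+g$: the finite-sample gap between the DEA hull and the true
  frontier is the same in distribution in adjacent years and cancels in
  the ratio.
* **Exploitation rates.** Outputs are constructed as rates and converted
  to catches via constant per-species spawning-stock-biomass levels
  (defaults 1.0 and 2.0 Mt, the right order of magnitude for Indian-Ocean
  yellowfin and skipjack), exercising the same catch/SSB join as real
  data.
* **Covariate link.** True UCU is a linear function of generated
  covariates plus Gaussian noise (optionally heteroskedastic via
  `het_covariate`), clipped into (0, 1]. This link is defined at the
  *score* level: it validates the second-stage machinery (selection,
  bootstrap, elasticities) against known coefficients, but it is a testing
  device — the generator does not model how covariates would act through
  catches on the DEA scores themselves, and the noise model is not a claim
  about any real fishery. Coefficient-recovery settings keep the mean
  score well inside (0, 1) so clipping is negligible.
* **Entry/exit.** Independent per-vessel-year Bernoulli absence, to
  exercise the per-pair balanced pairing.

What passing tests therefore show: the linear programs, the decomposition
identities, the chaining arithmetic and the bootstrap machinery are
correct, and the pipeline recovers known drift and known coefficients under
the generator's assumptions. What they cannot show: that any real fleet
satisfies those assumptions (smooth Cobb–Douglas frontier, i.i.d.
inefficiency, constant drift, linear covariate effects).

## Numerical choices

* The linear programs are solved by a dense two-phase primal simplex with
  Bland's anti-cycling rule, written for this package: DEA programs are
  tiny (here ≤ 6 rows and ~30 columns) but highly degenerate (zero
  right-hand sides), so robustness under degeneracy matters more than
  pivoting heuristics. Batched solves score a whole reference set in one
  call.
* Feasibility/optimality tolerance is 1e-7; an expansion factor within
  1e-6 of 1 is snapped to exactly 1 to stabilise the frontier set
  (`te = 1` should be a clean label, not 0.9999997).
* Score invariants (`cu ≤ te ≤ 1`, θ₂ ≥ θ₁) are enforced after solving:
  violations beyond 1e-4 abort the run (they would indicate a
  mis-specified program), smaller ones are clipped.
* Geometric means in log space; cumulative identities hold to 1e-6.
* In tests, LP optima are verified against an independent brute force:
  enumeration of the intensity-weight simplex on a grid, with a two-sided
  bracket (strict-feasibility grid maximum ≤ θ* ≤ slack-feasibility grid
  maximum + rounding bound) so the comparison is rigorous at any grid
  step. Grid steps per group size are chosen to keep enumeration in
  memory (e.g. 1/400 at J = 2 down to 1/40 at J = 5).
* Degenerate groups: a single-vessel reference set scores te = cu = 1 and
  its annual standard error is reported as 0 with `se_defined = FALSE`.

## Problem sizes

The validation suite runs the full stack at the reference conditions —
30 vessels over 28 years (840 vessel-years per draw), 200 independent
seeds for the drift-recovery check and 200 replications × B = 200 for
bootstrap coverage — which keeps the whole suite under two minutes on one
CPU while leaving the statistical checks well-powered. Routine analyses
use B = 1000 bootstrap replicates.

## A short tour

```{r}
cfg <- fleet_config(n_vessels = 12, years = 2000:2007, seed = 42)
sim <- simulate_fleet(cfg)
panel <- join_ssb(sim$panel, sim$ssb)

scores <- dea_scores(panel)
annual <- annual_means(scores)
head(annual)

series <- cumulate_malmquist(malmquist(panel))
annualised_rate(series, "tc")
```

```{r, fig.width = 7, fig.height = 4.5}
autoplot(series)
```

```{r}
reg <- scores |>
  filter(lp_status == "optimal") |>
  inner_join(panel, by = c("vessel_id", "year", "strategy"))
ranking <- enumerate_ucu_models(reg, c("fuel", "events", "dmi", "n_sets"))
fit <- fit_ucu_ols(reg, attr(ranking, "best"))
boot <- bootstrap_ucu(fit, B = 200, seed = 1)
tidy(boot)
ucu_elasticities(boot)
```

## Known limitations

* Output-oriented VRS only; no input orientation, slack-based or
  super-efficiency scores, and no CRS Malmquist or scale-efficiency-change
  decomposition.
* DEA is deterministic: all deviation from the frontier is read as
  inefficiency, and measurement error in catches maps directly into
  scores.
* Cross-period infeasibilities reduce the per-pair sample; with very small
  groups a pair can lose most vessels (the series reports how many).
* The second stage ignores the generated regressor problem (UCU is itself
  an estimate); the bootstrap addresses heteroskedasticity, not that.
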