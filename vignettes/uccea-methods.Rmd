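---
title: "Methods: a partitioned-survival cost-effectiveness model for first-line therapy in advanced urothelial carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned-survival cost-effectiveness model for first-line therapy in advanced urothelial carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uccea)
```

## The decision problem

Two first-line regimens for locally advanced or metastatic urothelial
carcinoma (la/mUC) are compared from the healthcare payer perspectives of
the United States and China:

* **EV+P** — enfortumab vedotin 1.25 mg/kg on days 1 and 8 plus
  pembrolizumab 200 mg on day 1 of each 21-day cycle (pembrolizumab for at
  most 35 cycles, enfortumab vedotin without a preset cap), as studied in
  EV-302;
* **N+GC** — nivolumab 360 mg plus gemcitabine 1000 mg/m² (days 1 and 8)
  and cisplatin 70 mg/m² every 21 days for six cycles, then maintenance
  nivolumab 480 mg every 4 weeks for up to 24 months, as studied in
  CheckMate-901.

Neither trial has released individual patient data, so the efficacy
inputs are parametric survival distributions fitted to pseudo individual
patient data reconstructed from published Kaplan-Meier curves. The
package reimplements the full analysis pipeline of the original
evaluation — reconstruction, fitting, cohort simulation, costing,
incremental analysis and sensitivity analyses — as tested, reusable
functions, and ships a synthetic-data generator so every stage can be
verified against known ground truth without any external download.

## Cohort model

### Partitioned-survival accounting

The model has three health states: progression-free (PFS), progressed
disease (PD) and death. State membership at time $t$ is read directly
off the two survival curves:

$$\text{PFS}(t) = S_{\text{PFS}}(t), \qquad
  \text{Dead}(t) = 1 - S_{\text{OS}}(t), \qquad
  \text{PD}(t) = \max\{0,\; S_{\text{OS}}(t) - S_{\text{PFS}}(t)\}.$$

This partitioned-survival construction is the unique one consistent with
the cumulative death fraction at any time being $1 - S_{\text{OS}}(t)$;
an explicit transition-probability formulation is derivable from the
trace but is not used as the engine. Because the two curves are
extrapolated from *independently* fitted families, they can cross in the
far tail; where $S_{\text{PFS}} > S_{\text{OS}}$ the PD membership is
clamped at zero (and PFS capped at $S_{\text{OS}}$ so memberships still
sum to one). The clamp count is recorded on the trace and a warning is
raised when more than 5% of cycle boundaries are affected — which does
happen for the N+GC arm, whose generalized-gamma PFS tail is heavier
than its log-normal OS tail. All membership identities are enforced to
$10^{-12}$ in the test suite.

### Time grid, horizon, discounting

* Cycle length: 21 days, matching the dosing schedule. Time is measured
  in **months** of 365.25/12 days, so one cycle is 0.6899 months.
* Horizon: 50 years, i.e. $N = \lceil 600 / 0.6899 \rceil = 870$ cycles;
  the final boundary slightly exceeds 600 months (effect below
  $10^{-4}$ on any output).
* Discounting: annual compounding with fractional exponents,
  $(1+r)^{-t/12}$, at 3% per year (US) or 5% (China). Recurring accruals
  are discounted at cycle midpoints, one-off costs (terminal care) at
  cycle boundaries. These conventions are isolated in
  `discount_factor()` and `trace_accrual()`.
* Half-cycle correction: per-cycle accrual uses the average of the two
  boundary memberships (on by default). The corrected value is bracketed
  by the left- and right-endpoint sums, and halving the cycle length
  moves discounted QALYs by less than 0.5%.

The month as time unit deserves a note: with the fitted overall-survival
parameters interpreted in months, the 50-year trace reproduces the
published cumulative death fractions (97.9% EV+P, 99.6% N+GC) exactly to
the printed precision, and the log-logistic scale parameter (32.1)
sits next to the trial's median overall survival in months. No other
unit is consistent with those figures.

### Survival inputs

The base case uses the four selected distributions (time in months):

| Arm  | Curve | Family            | Parameters |
|------|-------|-------------------|------------|
| EV+P | PFS   | log-normal        | meanlog 2.6709, sdlog 1.4649 |
| N+GC | PFS   | generalized gamma | mu 1.9794, sigma 1.1635, Q −0.6043 |
| EV+P | OS    | log-logistic      | shape 1.3124, scale 32.1285 |
| N+GC | OS    | log-normal        | meanlog 3.1474, sdlog 1.2350 |

The generalized gamma uses the Prentice $(\mu, \sigma, Q)$
parameterization — the standard one in survival extrapolation practice,
nesting the Weibull, gamma and log-normal ($Q = 0$) families — so the
published parameter vector drops in verbatim. Distribution evaluation
is delegated to `flexsurv`, with closed forms cross-checked in the test
suite.

A known internal-validation wrinkle: direct evaluation of these PFS
distributions gives 1-year progression-free survival of 55.1% (EV+P) and
41.7% (N+GC), whereas the original model's simulated traces report 50.8%
and 34.1%. The construction behind those lower simulated values was
never published; this package deliberately evaluates the printed
distributions as stated. The consequence is a slightly larger
progression-free share, which in turn puts the EV+P US QALY total about
3% above the original (3.44 vs 3.34) — the `internal_validation()`
helper reports such landmark comparisons without asserting them.

## Utilities and adverse events

Health-state utilities are 0.772 (PFS) and 0.698 (PD). The five most
frequent grade ≥ 3 adverse events per arm enter twice:

* an expected management cost $\sum_i p_i c_i$ applied once at model
  entry, and
* an expected utility decrement $\sum_i p_i d_i$ applied for exactly one
  cycle, i.e. a QALY loss of $\sum_i p_i d_i \cdot \Delta/12$ with
  $\Delta$ the cycle length in months.

Incidence over time is not published, so events are placed at entry,
where the discount factor is 1.

## Costing

Per-administration drug acquisition rounds partial vials **up** in the
base case; `vials_needed(dose, vial, sharing = TRUE)` switches to exact
fractional costing to explore the vial-sharing policy lever. Dosing uses
a representative patient of 70 kg / 1.86 m² (US) or 65 kg / 1.72 m²
(China). Component schedules enforce the caps above; maintenance
nivolumab, a 4-weekly schedule on a 21-day grid, is costed as a
per-cycle rate scaled by 21/28.

Recurring costs are assigned to states as follows (a modeling choice the
original analysis does not publish, exposed through the configuration):

* **PFS (on treatment)** — drugs, intravenous administration (while any
  component is active), tumor imaging, laboratory/radiological
  monitoring, hospitalization and daily care;
* **PD, first `second_line_cycles` cycles after progression** —
  second-line therapy (gemcitabine-cisplatin) plus imaging and routine
  follow-up, driven by a per-entrant schedule in which the progression
  inflow at each cycle is the decline of the PFS curve (partitioned
  accounting cannot split PFS exits into progression versus death; the
  inflow is treated as progression, an upper bound, and the second-line
  occupancy is capped by actual PD membership);
* **PD afterwards** — best supportive care plus routine follow-up;
* **Death** — a one-off terminal-care cost per incident death.

`second_line_cycles` defaults to 6 — one full gemcitabine-cisplatin
course — and appears in the one-way sensitivity analysis. Because this
state-cost mapping and the second-line duration are not published,
absolute cost totals are reproducible only approximately: this package's
EV+P totals land within about 2% of the original (US \$1.89M vs \$1.86M),
while its N+GC arm is cheaper than the original's (US \$458k vs \$882k) —
a difference no published input explains, and the main reason the
incremental results differ in level while every qualitative conclusion
(EV+P not cost-effective anywhere, zero acceptability at both
thresholds) is unchanged. One knock-on effect is worth flagging: in this
implementation the China model with the enfortumab vedotin price set to
\$0 falls *below* the Chinese willingness-to-pay threshold, whereas the
original reports it stays above; the claim depends entirely on the
unpublished cost accounting of the comparator arm.

## Incremental analysis

$\mathrm{ICER} = \Delta\mathrm{Cost} / \Delta\mathrm{QALY}$, with
standard dominance labelling for sensitivity draws where signs vary
(cheaper-and-at-least-as-effective → *dominant*;
costlier-and-less-effective → *dominated*). Net monetary benefit
$\mathrm{NMB} = \lambda \cdot \mathrm{QALY} - \mathrm{Cost}$ at
willingness-to-pay $\lambda$ underlies the acceptability curve;
thresholds are \$150,000/QALY (US) and \$40,451.64/QALY (China, three
times 2024 GDP per capita).

## Sensitivity analyses

* **One-way (tornado)**: every unit cost, drug price, utility,
  adverse-event risk/disutility/cost is varied ±20% (the ranges printed
  with the inputs; the discount rate uses the guideline ranges 0–5% US
  and 0–8% China). The AE-risk ranges follow the printed ±20% input
  table; a ±10% convention is sometimes quoted for them, and the
  configuration accepts any explicit range. Each bound re-runs the full
  two-arm model; rows are ranked by ICER span.
* **Probabilistic**: 10,000 Monte-Carlo draws; gamma for costs, beta for
  utilities and probabilities, uniform for weight, body surface area and
  discount rate. Gamma/beta are moment-matched with mean = base and
  sd = (high − low)/3.92, reading the range as a 95% interval — the
  common convention where none is stated; infeasible beta moments fall
  back to uniform with a warning. Draws are independent (no published
  correlation structure) and the survival-curve parameters are held
  fixed, since no ranges or distributions are published for them — a
  limitation, as parameter uncertainty in the extrapolation is thereby
  understated. Survival fixedness has a useful computational corollary:
  the cohort traces are invariant across draws and are built once.
* **Price thresholds**: the deterministic ICER is monotone in any price
  multiplier, so the multiplier at which it crosses the threshold is
  found by bisection on [0, 1] to a tolerance of $10^{-4}$. The two-way
  analysis scans independent multipliers for enfortumab vedotin and
  pembrolizumab and reports the joint (diagonal) threshold, interpreting
  an "X% of baseline" scenario as the same multiplier applied to both
  drugs.

## Synthetic data and reconstruction

`simulate_ipd()` emulates a single-arm trial read-out: event times drawn
by inverse-CDF sampling from any of the six families, uniform staggered
entry over an accrual window, and administrative censoring at a fixed
calendar time. It does **not** emulate loss to follow-up, covariates or
competing risks, so passing reconstruction/fitting tests demonstrate
correctness of the algorithms under administrative censoring only — not
robustness to informative dropout in real digitized curves.

`make_digitized_fixture()` samples the Kaplan-Meier step curve on a
regular grid with numbers-at-risk at a chosen interval — both exposed as
parameters since real digitizations vary — and can add bounded uniform
jitter to emulate plot-reading error (clamped to keep the curve a valid
survival function, with the clamp count recorded).

`guyot_reconstruct()` inverts the product-limit estimator from the
coordinates and at-risk table: censoring within each risk interval is
assumed uniform (the standard assumption), interval censor counts are
found by a monotone search that makes the implied at-risk numbers match
the published ones exactly, integer rounding conflicts are resolved by
explicit end-of-interval censoring or event removal (counted as clamps),
and a reported total event count, when available, constrains the final
interval. On noiseless fixtures the round-trip error (max |ΔS| between
input coordinates and the re-estimated curve) is held under 0.01; the
default tolerance for declaring a reconstruction successful is 0.02,
configurable in `reconstruction_report()` consumers. Refining the
coordinate grid improves fidelity overall, though integer count recovery
keeps the improvement from being strictly monotone step-to-step.

## Fitting and model selection

`fit_mle()` maximizes the right-censored log-likelihood
$\sum_i \delta_i \log f(t_i) + (1-\delta_i) \log S(t_i)$ on an
unconstrained transformed scale via `flexsurvreg`, with two perturbed
restarts from moment-based initial values if the first attempt fails or
does not converge (generalized-gamma likelihoods are ridge-prone).
`model_select()` ranks families by AIC ($2k - 2\ell$), reporting BIC
($k\ln n - 2\ell$), with ties broken by parameter count then family
name. The third selection criterion used in practice — visual congruence
with the Kaplan-Meier estimate — is a judgment step: `km_overlay()`
exports the plot-ready table rather than automating a score. At
n = 5,000 with moderate censoring, all six families recover their
generating parameters within 5%.

## Problem sizes and reproducibility

The test suite exercises the generator at up to n = 200,000 (closed-form
survival checks), reconstruction at n = 300–500 (typical trial-arm
sizes), fitting at n = 5,000, and the probabilistic analysis at its full
10,000 draws; these sizes were chosen so each suite completes in minutes
on a single core while leaving Monte-Carlo error well inside the
asserted tolerances. All randomness flows through explicit integer
seeds: identical seeds give bit-identical simulated samples, parameter
draws and acceptability curves.

## Known limitations

* Efficacy inputs come from an unanchored indirect comparison of two
  trials; the package inherits that bias structure.
* Partitioned-survival accounting cannot identify the PFS→death flow, so
  the progression inflow that drives second-line costing is an
  approximation (upper bound).
* The state-to-cost mapping and second-line duration of the original
  analysis are unpublished; absolute cost totals (and anything downstream
  of them, such as the zero-EV-price scenario) are reproducible only up
  to those choices, all of which are exposed in the configuration.
* Survival-parameter uncertainty is excluded from the probabilistic
  analysis (no published ranges).
* No expected-value-of-perfect-information analysis is provided.
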