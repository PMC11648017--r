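---
title: "A Markov cohort model for ctDNA-guided treatment switching in mCRPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for ctDNA-guided treatment switching in mCRPC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaCEA)
```

## The decision problem

First-line treatment of metastatic castration-resistant prostate cancer
(mCRPC) with an androgen receptor pathway inhibitor (ARPI, abiraterone
acetate or enzalutamide) fails early in a substantial minority of patients,
but conventional response assessment only identifies non-responders after
3–6 months. Circulating tumor DNA (ctDNA) measured at baseline and after 4
weeks of therapy can flag patients headed for a non-durable response much
earlier. The question this package addresses is economic: if flagged
patients switch to docetaxel after the first 4-week cycle instead of waiting
for conventional progression, do the extra assay costs and earlier
chemotherapy pay for themselves in quality-adjusted life-years (QALYs)?

`ctdnaCEA` implements a time-dependent Markov cohort model comparing the two
policies from a healthcare-payer perspective, with probabilistic, one-way,
and scenario sensitivity analysis.

## Model structure

Seven health states — first-line ARPI, second-line docetaxel, third-line
cabazitaxel, no-progression-after-docetaxel, no-progression-after-
cabazitaxel, best supportive care (BSC), and death — are expanded to 25
states: each taxane line is represented by ten 3-week tunnel sub-states
(the usual 10-cycle course) so that time on chemotherapy is encoded in the
state itself. Patients completing 10 cycles without an event wait in the
corresponding no-progression state. Every alive state can transition to BSC
(a configurable background rate, since the schematic shows the edges but no
rates are published) and to death; death is absorbing.

The cohort starts fully in the ARPI state and is evolved over a 5-year
horizon on an irregular cycle grid: one 28-day cycle (the ctDNA evaluation
window) followed by 21-day cycles — 86 cycles covering 1813 of 1826.25
days. The trailing partial cycle is dropped so that every cycle is
full-length; the truncation is under 1% of the horizon. Costs are
discounted at 4% per year and effects at 1.5% (the Dutch convention),
evaluated at cycle start; occupancy is likewise valued at cycle start with
no half-cycle correction. This is the simplest defensible reading of a
spreadsheet cohort model; the effect of the convention is bounded by half a
cycle (1.5–2 weeks) of rewards.

### Strategy arms

Both arms mix abiraterone and enzalutamide sub-cohorts 50/50 by default.

* **Standard of care** holds progression out of the ARPI state until the
  first cycle boundary at or after 182.625 days (day 196 on the default
  grid), reflecting a second-line switch "after 6 months at the earliest";
  the probability mass stays in ARPI and continues to face the ARPI death
  hazard.
* **ctDNA-guided**: every patient is tested (3 samples × €350, charged once
  to survivors of cycle 1). At the end of cycle 1, a fraction
  `ctdna_flag_fraction` (default 0.4 — the proportion with detectable ctDNA
  at baseline and week 4 is not published and must be overridable) moves to
  the first docetaxel tunnel state. Of the switchers, `ctdna_ppv = 0.85`
  are true non-durable responders; false positives receive identical
  docetaxel outcomes, and the split is retained for reporting only. The
  remaining, predicted-durable patients follow durable-responder PFS/OS
  curves and, by default, are not subject to the 6-month hold — whether
  non-flagged patients can progress before 6 months is not specified, so
  the choice is exposed as the `durable_hold` switch.

### Survival inputs and transition probabilities

How the original spreadsheet converted trial survival into transition
probabilities is not described, so the package adopts an explicit,
reproducible reconstruction: each line's PFS and OS enter as exponential
distributions identified by their medians (the only summaries universally
printed by the cited trials), converted to daily hazards as
$\lambda = \ln 2 / (\text{median} \times 30.44)$. Piecewise-constant
hazards are supported for users who digitize full curves; each cycle then
receives the duration-weighted mean hazard, and a spec ending before the
horizon has its last piece extended with a warning.

Within a cycle, progression and death compete as constant cause-specific
hazards: the death hazard comes from OS, the progression hazard is the PFS
event hazard minus the death hazard (an error if negative), and the total
event probability $1 - e^{-\lambda t}$ is apportioned in proportion to the
hazards. This standard multistate conversion cannot produce negative
probabilities, unlike subtracting probabilities directly.

Tunnel states use clock-reset semantics: post-switch docetaxel and
cabazitaxel hazards depend only on time in state, never on calendar time.
The no-progression states inherit the hazard of the last tunnel interval
(exact for exponential inputs, a constant-extension approximation for
piecewise inputs), and the BSC death hazard is treated as
time-homogeneous at its initial value.

### Costs, utilities and one-off charges

Drug and administration costs accrue per cycle of state occupancy (taxane
drug costs only during the 10 tunnel cycles), visit costs in every alive
state, and a BSC per-cycle cost in the BSC state. Expected adverse-event
management costs ($\sum p_i c_i$ over the line's grade ≥ 3 events) plus a
diagnostic work-up are charged once to the flow entering each treatment
line: severe events cluster early in a line, and per-cycle charging would
require duration data the sources do not provide. Whether AE probabilities
were sampled in the original probabilistic analysis is not stated; here
they are sampled (beta), consistent with the distribution families used
for probabilities. Utilities weight occupancy time by line; death has
utility zero.

## Uncertainty

Every uncertain scalar is a `dist_spec(kind, mean, se)`: beta for
probabilities and utilities, gamma for costs and survival medians, fitted
by method of moments — the published analysis names the families but not
their parameterization, and moment matching from (mean, se) degenerates
gracefully to fixed values. Where a source provides no uncertainty, the
default standard error is 10% of the mean.

The probabilistic analysis (`run_psa()`, default 5000 iterations) draws one
parameter set per iteration and runs both arms on it (common random
parameters, which removes between-arm parameter noise from the
incrementals). The mean ICER is the ratio of mean incremental costs to mean
incremental effects — mean ratios are unstable whenever a draw's
incremental effect approaches zero — and 95% intervals are 2.5th/97.5th
percentile order statistics (`quantile(type = 1)`), with no normal
approximation. Iteration seeds follow the counter scheme
$(\text{seed} + i) \bmod (2^{31}-1)$ so any subset of iterations is
reproducible. The durable-median-above-pooled ordering is validated on
point estimates but deliberately not re-imposed on draws; clamping would
bias the null construction used in validation.

One-way sensitivity (`run_owsa()`) sets one parameter to its low and high
value with everything else at base case; endpoints are full PSA means by
default (a deterministic mode exists) because the tornado is reported
without intervals. Shifting the mean of a distributed parameter preserves
its coefficient of variation. The four scenario analyses are pure overlays
(`scenario_spec()`) on the base configuration: trial curves for the
durable sub-cohort (s1), second-line-setting cabazitaxel data for
switchers (s2), mean ARPI utility for switchers on docetaxel (s3), and
real-world docetaxel data in both arms (s4).

## The synthetic parameter sets

The published analysis draws its inputs from a supplemental parameter
listing; only a handful of anchors appear in print. The generator
(`generate_parameter_set()`) therefore fixes the printed anchors — assay
€350 × 3 samples, predictive value 0.85, ARPI split 0.5, WTP €80,000,
discounting 4%/1.5%, 5-year horizon, 28/21-day cycles, 10-cycle taxane
courses — and fills everything else with documented synthetic magnitudes:

* Trial survival medians follow the cited registration trials
  (abiraterone 16.5/34.7 months PFS/OS, enzalutamide 17/35, docetaxel
  8.3/24.3, cabazitaxel 5.5/13.6, BSC OS 7).
* Durable-responder medians are the pooled ARPI medians plus fixed margins
  of +20 (PFS) and +40 (OS) months. The source cohort for durable
  responders is small and its survival lies well above the pooled trial
  medians, which average durable and non-durable responders; the margins
  are chosen so that persistently ctDNA-negative patients have the
  markedly better prognosis that motivates the policy, and so that the
  synthetic base case reproduces the published qualitative ordering
  (guided arm more effective, positive incremental net benefit at €80,000,
  with the abiraterone-only mixture the least favourable but still
  positive tornado endpoint).
* Drug prices are Dutch-plausible 2022 values: enzalutamide (patented)
  €2450 per 21-day cycle, abiraterone (early generic) €700, docetaxel €120
  plus €350 administration, cabazitaxel €3900 plus €350.
* Costs and utilities carry 10% (utilities: 0.05 absolute) standard
  errors; the background BSC-entry rate is 2 × 10⁻⁵ per day.

With a seed, trial medians are instead drawn uniformly from documented
plausible ranges (ARPI PFS 5–17, OS 18–35 months; taxane and BSC medians on
the cited trials' order of magnitude), preserving the durable margins.

Three further profiles support validation. `null_effect` makes the two
arms structurally identical (flag fraction 0, assay cost 0, durable curves
equal to pooled curves, hold applied to both), so the true incremental
cost and effect are exactly zero while symmetric survival noise remains —
its PSA probability of cost-effectiveness must be ½ up to binomial error.
`strong_effect` widens the durable margins; `stress` shortens all
survival, raises the flag fraction and widens uncertainty to exercise
conservation and validation at the extremes.

What the fixture is not: a transcription of the published inputs. The
package deliberately does not search parameter space to reproduce the
published table — that would fabricate agreement — so numerical agreement
with the published base case is not expected, and the acceptance suite
documents the deviation rather than hiding it.

## Validation

* An individual-level microsimulation (`microsim_oracle()`) pushes
  simulated patients through exactly the per-cycle transition matrices and
  reward rules of the cohort engine; the engine computes this simulation's
  expectation, and the two are compared at 2 × 10⁵ patients (agreement
  within 3 Monte Carlo standard errors on costs, QALYs and life-years).
* Closed-form oracles cover the single-risk chain (geometric-series
  life-years), the competing-risk split (a 10⁶-draw two-risk simulation),
  and piecewise hazard averaging (numerical quadrature).
* Structural properties are asserted over the full grid: row-stochastic
  matrices (10⁻¹²), occupancy conservation, monotone death occupancy,
  tunnel timing, the exact linearity of the incremental net benefit in the
  assay price, and affinity of all results in the ARPI mixture share.

Problem sizes in the shipped tests — 5000-iteration PSA for the base case,
1000 per scenario, 2 × 10⁵ microsimulated patients — match the analysis
defaults while keeping the suite comfortably fast on a single CPU.

## Known limitations

* Per-line death hazards are derived from each line's trial OS median, so
  a state behaves like "remaining survival from line start". Full trial OS
  curves include survival under subsequent therapies, which a multistate
  model re-adds after progression; the per-state hazards are therefore
  pessimistic, most strongly for lines with long post-progression
  survival, and the model consequently penalizes early switching more than
  a patient-level survival model would. Users with access to
  line-conditional survival should supply piecewise hazards instead.
* Exponential survival is an approximation; medians are the only
  universally printed summaries, but real PFS curves have non-constant
  hazards.
* Perfect adherence, no re-challenge, no treatment intensification, and no
  post-cabazitaxel active line (PARP inhibitors and radioligand therapy
  are out of scope, as in the source analysis).
* The false-positive switchers receive standard docetaxel outcomes; no
  separate curves exist for them, and the assumption is surfaced in the
  arm definition rather than buried.

## A worked example

```{r example, eval = FALSE}
ps <- load_parameters(system.file("extdata", "base_like.yaml",
                                  package = "ctdnaCEA"))
run_cea(ps)                      # deterministic incrementals
psa <- run_psa(ps, n = 5000, seed = 1)
psa                              # mean ICER, iNMB, P(cost-effective)
plot_ce_plane(psa); plot_ceac(psa)
tor <- run_owsa(ps, default_owsa_specs(ps), n_psa = 1000, seed = 1)
plot_tornado(tor)
```
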