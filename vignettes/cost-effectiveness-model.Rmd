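---
title: "A Markov cohort model for adjuvant therapy in resected EGFR-mutant NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for adjuvant therapy in resected EGFR-mutant NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjuvantCEA)
```

## The decision problem

Patients with completely resected stage II--IIIA non-small-cell lung
cancer carrying an activating EGFR mutation can receive adjuvant
gefitinib (250 mg daily for 24 months, oral) or standard
vinorelbine--cisplatin chemotherapy (every 3 weeks for four cycles,
intravenous). A randomized trial in this population reported longer
median disease-free survival under gefitinib (30.8 vs 19.8 months),
similar overall survival (medians 75.5 vs 62.8 months, not
significantly different), and far fewer grade 3--4 adverse events (12%
vs 48%). `adjuvantCEA` evaluates whether the targeted therapy is worth
its drug cost from the Chinese health-care-system perspective, in
cost per quality-adjusted life year (QALY).

## Model structure

The model is a deterministic three-state Markov cohort: disease-free
(DFS), progressive disease (PD), and death. Everyone starts
disease-free. Cycles are 21 days long; the horizon is 10 years, giving
`ceiling(3652.5 / 21) = 174` cycles; costs and QALYs are discounted at
3% per year.

Each arm carries two Weibull survival curves, one for DFS and one for
overall survival (OS), with survival function
$S(t) = \exp(-\lambda t^\gamma)$. The per-cycle conditional event
probability for the cycle ending at time $t$ with cycle length $u$ is

$$P_t = 1 - \exp\left[\lambda (t-u)^\gamma - \lambda t^\gamma\right]
      = 1 - S(t)/S(t-u).$$

Per cycle, both alive states die with the OS-derived conditional
probability, and disease-free patients progress with the DFS-event
probability net of death (DFS events include deaths, so subtracting
avoids double counting), floored at zero:

* DFS &rarr; Death and PD &rarr; Death: $P_t$ from the OS fit;
* DFS &rarr; PD: $\max(0,\ P_t^{\mathrm{DFS}} - P_t^{\mathrm{OS}})$;
* Death is absorbing.

Because both alive states share the OS hazard, the modeled cohort
survival curve reproduces the fitted OS curve exactly at every cycle
boundary -- a property the test suite checks to 1e-10. Transitions are
applied at cycle end; costs and utilities accrue on start-of-cycle
occupancy; discounting uses start-of-cycle time. No half-cycle
correction is applied (the original analysis environment applies none
by default); the discretization is fine enough that halving the cycle
length moves total QALYs by well under 1%.

## Survival calibration

The original analysis fitted Weibull curves to digitized Kaplan--Meier
coordinates that were never published. The package therefore offers
three calibration routes per curve:

1. **Median calibration** (the bundled default):
   `params_from_median(median, shape)` sets
   $\lambda = \ln 2 / \mathrm{median}^\gamma$, so survival at the
   printed median is exactly 0.5. The bundled fixture uses shape 1
   (exponential) because the original fitted shapes are unknown;
   exponential is the usual neutral choice when only a median is
   available, and it makes the per-cycle probabilities memoryless.
2. **Digitized curves**: `fit_weibull_to_km()` performs least squares
   on the linearized relation
   $\log(-\log S) = \log\lambda + \gamma \log t$, the standard
   procedure for curve coordinates without individual-level data.
   Points at $S = 1$ or $t = 0$ are dropped (the transform is
   undefined), duplicated time points keep the lower survival value,
   and at-risk counts, when present, serve as regression weights.
3. **Explicit parameters**, for users who fitted elsewhere.

Because the bundled calibration is not the authors' unpublished fit,
the package does not reproduce their absolute base-case totals
(their QALYs 1.55 vs 1.42). What it preserves by construction is the
ordering of the arms -- gefitinib gains QALYs through longer DFS at a
higher utility -- and the qualitative conclusion that the incremental
cost-effectiveness ratio falls below the willingness-to-pay threshold.
The arithmetic layer (`compare_arms`) does reproduce the published
incremental results exactly when fed the published per-arm totals.

## Costs and utilities

All costs are in USD (the source converted at 6.8409 CNY/USD, recorded
as metadata only). Per cycle:

* DFS state: follow-up surveillance \$55.60, plus drug acquisition
  while on treatment, plus expected adverse-event management
  (incidence &times; \$507.40) during treatment cycles;
* PD entry: a one-off \$1,877.25 charged to the incident fraction;
* PD state: supportive care \$337.50.

Drug costs: gefitinib is 21 daily \$23.33 tablets per cycle
(\$489.93) over a 24-month course -- 34 full cycles plus a final cycle
prorated at 0.786, so the total equals 730.5 daily tablets.
Chemotherapy is dosed on a reference 1.72 m^2 body surface area with
whole-vial rounding per administration: vinorelbine 43 mg &rarr; five
10 mg vials on each of days 1 and 8 (\$81.60), cisplatin 129 mg &rarr;
five 30 mg vials (\$14.00), \$95.60 per cycle for four cycles.

Utilities: DFS 0.80 under oral therapy and 0.76 under intravenous
therapy, PD 0.70, death 0. Grade 3--4 adverse events subtract 0.0731
in expectation (incidence &times; decrement) during treatment cycles;
the source's parameter table displays the decrement rounded to 0.07,
and the more precise text value is used. The adverse-event burden is
spread uniformly over treatment cycles (1--4 for chemotherapy, 1--35
for gefitinib) because only aggregate incidences and a per-cycle cost
are available; this is the simplest allocation consistent with both.

A QALY increment per cycle is the occupancy-weighted utility times
21/365.25 years. Outcomes are summarized as the incremental
cost-effectiveness ratio (ICER), per-arm average cost-effectiveness
ratios (ACER = cost/QALY), and net monetary benefit
(NMB = WTP &times; QALY &minus; cost) at the willingness-to-pay
threshold of \$30,828/QALY (three times per-capita GDP). Negative or
undefined ICERs are never printed as bare ratios; dominance labels are
reported instead.

## Sensitivity analyses

**One-way (tornado).** Each parameter moves to its low and high bound
with the others at base: costs vary &plusmn;30%, utilities and
probabilities &plusmn;20% (clamped to [0, 1]). Survival enters as a
multiplicative factor on the per-cycle event probabilities of one
curve (base 1, &plusmn;20%, resulting probabilities clamped to
[0, 1]) rather than on the Weibull parameters, matching how "survival
probability" ranges are specified in this literature. The outcome
metric is the incremental NMB at the default WTP -- well-defined even
where an ICER is not. Entries are sorted by spread, ties broken by
name.

**Probabilistic (PSA).** Monte-Carlo simulation, 1,000 iterations by
default. Costs are sampled from gamma distributions and utilities and
probabilities from beta distributions, parameterized by
method-of-moments from (mean, se). The source does not state its
dispersions, so the package interprets each one-way range as a 95%
central interval: se = (high &minus; low)/(2 &times; 1.96); this is
overridable per parameter. Two supports need care: the adverse-event
disutility is sampled as a beta on its magnitude and applied as a
decrement, and survival multipliers -- whose mean of 1 no beta can
have -- are sampled as 2 &times; Beta, i.e. a scaled beta on [0, 2]
with the requested mean and se. Parameters are sampled in sorted name
order from one seeded generator, so draws are invariant to
configuration reordering, and a draw that breaks the model is
resampled (capped at 100 attempts). Results are summarized as a
cost-effectiveness acceptability curve (probability of positive
incremental NMB) and the mean-incremental-NMB series over a WTP grid
from 0 to twice the threshold in 100 steps, always including \$1,500
and \$30,828. Where the acceptability curve crosses 0.5 depends
strongly on the survival calibration: with the bundled median
calibration the incremental cost is far larger than under the original
(unpublished) curve fits, so the probability of cost-effectiveness at
very low thresholds such as \$1,500 is near zero even though the
base-case ICER clears the \$30,828 threshold comfortably.

## The synthetic-data generator

`simulate_cohort()` draws event times from a known Weibull by inverse
transform, censors them by an independent exponential plus an
administrative cutoff at 80 months (the trial's median follow-up), and
`km_estimate()` summarizes them by the product-limit estimator. This
emulates what a digitized trial curve represents -- a step function
with at-risk counts -- with the decisive advantage of known ground
truth, so the full pipeline (simulate &rarr; estimate &rarr; refit)
can be required to recover its generating parameters (within 10% at
n = 2,000 in the tests). It does not emulate the trial's recruitment
process, stratification, or exact risk tables, and real digitized
curves add digitization error the generator does not model; passing
these tests validates the machinery, not the unpublished calibration.

## Numerical choices

* `1 - exp(x)` is computed as `-expm1(x)`; per-cycle survival factors
  chain to the continuous curve at 1e-10 over all 174 cycles.
* Time unit is months with 1 month = 365.25/12 days, so the 21-day
  cycle is u = 0.6899 months.
* Monetary values are rounded to cents only at CSV serialization.
* Problem sizes in the routine checks (simulated cohorts of 200 to
  10,000 subjects, 50 to 1,000 PSA iterations) were chosen as the
  smallest sizes at which the statistical assertions are stable.

## Known limitations

* The bundled exponential calibration understates late-time curvature
  if the true hazards are non-constant; users with digitized
  coordinates should refit with `fit_weibull_to_km()`.
* Post-progression care is a lump sum plus flat supportive care; no
  treatment lines after progression are modelled.
* Whether supportive care applied to DFS, PD or both in the original
  model is not stated; the package assigns it to PD and follow-up to
  DFS, the reading most consistent with "surveillance of disease-free
  patients".
* No extended dominance or >2-arm frontier; no EVPI; no correlated
  parameter sampling.

## A worked run

```{r run, eval = FALSE}
cfg <- make_fixture("paper-medians")
out <- run_pipeline(cfg, stages = c("fit", "base-case", "owsa", "psa"),
                    out_dir = "cea_output")
out$result
head(out$tornado)
```
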