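---
title: "Modelling the cost-utility of tranexamic acid for postpartum haemorrhage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-utility of tranexamic acid for postpartum haemorrhage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txacea)
```

## The decision problem

Postpartum haemorrhage (PPH) — blood loss of 500 ml or more within 24 hours
of birth — is the leading cause of maternal death in India and worldwide.
WHO guidance recommends adding early intravenous tranexamic acid (TXA) to
standard uterotonic-based care for all diagnosed PPH cases.  `txacea`
implements a decision-analytic model asking whether that addition is
cost-effective in Indian public health facilities and what it would do to
the national PPH-management budget.

The model compares two strategies for an annual cohort of 510,915 women
experiencing PPH in public facilities: standard care (SOC) and TXA added to
standard care.  The primary endpoint is the incremental cost-utility ratio
(ICUR), the incremental cost per quality-adjusted life year (QALY) gained,
judged against a willingness-to-pay threshold of INR 145,742 per QALY (the
2019-20 Indian GDP per capita).  Net monetary benefit
($\mathrm{NMB}=\Delta Q\lambda-\Delta C$) and net health benefit
($\mathrm{NHB}=\Delta Q-\Delta C/\lambda$) restate the same comparison.

## Model structure

The tree (built by `build_base_tree()`) stratifies the cohort by the level
of facility where care starts (primary health centre, secondary, tertiary)
and by PPH type (atonic, 80%; traumatic, 20%).  Each arm then follows the
Indian clinical pathway:

* **Medical management** (uterotonics and supportive care, plus TXA in the
  intervention arm) controls bleeding in most women.  The arm-specific risk
  of requiring *further intervention* is 0.23 under SOC and 0.22 under TXA
  — the clinical effect of TXA in this model.
* **Atonic PPH** failing medical management receives uterine balloon
  tamponade (UBT) with a level-specific insertion probability (0.19 / 0.33 /
  0.48 at primary/secondary/tertiary); UBT controls bleeding with
  probability 0.92.  Cases not receiving UBT are controlled by continued
  medical/conservative measures.  UBT failures undergo direct hysterectomy
  (0.15) or devascularization surgery, with a 0.22 probability of
  subsequent hysterectomy.
* **Traumatic PPH** needing further intervention is explored and repaired
  locally (success 0.45); failures escalate to the same surgical sequence.
* **ICU admission** (tertiary only) occurs with probability 0.77 after
  uncontrolled bleeding and 0.03 after controlled episodes; primary and
  secondary cases needing ICU care are referred.
* Every pathway ends **alive or dead**.

Primary-level presenters are stabilized, charged primary medical management
and a referral, and have subsequent admissions, surgery and ICU care priced
at the receiving level.

Branch probabilities are stored as symbolic expressions over parameter
names and evaluated on demand, so the identical tree object serves the
deterministic base case, one-way variation, vectorized probabilistic draws
and the microsimulation.

```{r tree}
model <- build_model()
validate_tree(model$tree)$ok
nrow(model$payoffs$pathways)
```

## Parameters

All inputs live in one packaged table (`default_parameter_file()`): event
probabilities, the TXA relative risks (further interventions 0.96,
bleeding death 0.69, all-cause mortality 0.88), unit costs in 2019-20 INR
at each facility level, utility weights, and analysis rates.  Limits for
sensitivity analysis come from source intervals where published and from a
20% variation otherwise (`apply_limit_rule()`, capped at 1 for
probabilities and utilities).  `relative_risk()` derives a relative risk
and its Wald 95% CI from 2x2 trial counts.

For probabilistic analysis, `fit_distribution()` assigns beta
distributions to probabilities and utilities, gamma to costs and resource
counts, and lognormal to relative risks.  Beta and gamma are
moment-matched with mean equal to the base value and standard deviation
`(high - low)/3.92`, treating the printed limits as a 95% interval; the
lognormal is centred so its *median* equals the base value with
`sdlog = (log(high) - log(low))/3.92`, mirroring how relative-risk
confidence intervals are constructed.  Parameters with zero-width limits
(utility at death) are fixed and never sampled.

## Costs, utilities and discounting

Costs are one-off episode costs and are never discounted.  Health-system
costs stack the unit packages a pathway consumes; the out-of-pocket
childbirth expenditure (INR 3,015) is kept in its own column so the
disaggregated societal perspective is the health-system perspective plus
OOP.  Survivors accrue utility over the remaining life expectancy (70.7
years overall, cohort age 21 at the event): 0.930 after uncomplicated
medical management, 0.895 during convalescence after conservative control,
0.565/0.909 (42-day/long-term) after devascularization, 0.560/0.880 after
hysterectomy, 0.490 during a 1.5-day ICU stay; death scores zero.

QALY discounting at 3% per annum supports three conventions
(`discount_weight()`): a continuous-time annuity, discrete annual
integration, and an *aggregate-horizon* convention that multiplies the
undiscounted lifetime QALYs by a single factor $(1+r)^{-t^*}$.  The
published discounted results imply exactly such a single factor (the
discounted/undiscounted ratio is identical in both arms), with an
effective horizon near 27 years — not derivable from any standard annuity
over the 49.7-year horizon, which yields 25.6-25.8 discounted years.  The
package therefore treats the convention, with its horizon $t^*$, as an
explicit calibrated quantity rather than guessing silently; the standard
conventions remain available for analyses that prefer them.

## Structural switches and mortality allocation

Published sources leave several structural choices open.  They are
explicit switches (`model_structure()`), not hidden constants:

* `traumatic_gated` — traumatic cases pass the same further-intervention
  gate as atonic cases (default) or all undergo exploration.  The gated
  reading is the only one whose surgery and ICU event masses are
  compatible with the published cohort event counts.
* `extra_ipd_further`, `escalation_referral` — further-intervention
  episodes incur one additional indoor-admission package (escalation as a
  renewed admission) and, from primary/secondary, an escalation referral.
* `oop` — the out-of-pocket childbirth expenditure attaches to
  further-intervention episodes (default) or to every case.  The published
  per-patient increments (societal 121 vs health-system 152) differ by
  almost exactly the OOP amount times the gate difference, which an
  arm-independent OOP cannot produce.
* `utility_conservative` — conservative control is a 42-day convalescence
  at 0.895 with recovery to 0.930 (default), or a lifetime weight.
  Conservative measures are uterus-preserving, so a lasting decrement is
  clinically hard to defend; the lifetime reading also inflates the
  incremental QALY gain well beyond the published value.
* `mortality` — arm-level death risks attach to pathways as: all-cause
  risk (0.03, RR 0.88 under TXA) on every pathway plus the bleeding-death
  risk (0.02, RR 0.69) added on ICU-containing pathways (default,
  `additive_icu`); or added on uncontrolled-bleeding pathways; or
  bleeding deaths plus a uniform residual.  The default reproduces the
  published death counts; the alternatives under-predict them by 2-4%.
* `surgeries_count` — a pathway containing devascularization and
  subsequent hysterectomy counts two surgeries (default) or one patient.

## Calibration of the free knobs

The facility-level case mix is never printed, the discounting horizon
$t^*$ is implicit, and the mortality allocation is unstated.
`calibrate_free_knobs()` searches exactly these knobs against the
published per-patient cost/QALY block and cohort event counts: a simplex
grid (step 0.05) plus Nelder-Mead refinement over the facility mix, for
every combination of structural switches, with $t^*$ solved in closed
form from the discounted-QALY targets.  The loss is a weighted
root-mean-square of relative errors with each target's contribution
capped at 5%: a target the structure cannot approach within the cap
contributes a constant there, so a structurally unmatchable quantity
cannot drag the matchable ones off their fit.  Residuals per target are
returned and flagged beyond 5%.

The calibrated configuration — facility mix (0, 0.784, 0.216),
$t^* = 26.96$ years, and the default switches above — ships as the
package default, so `analysis_config()` is "published mode".  Two event
differences remain structurally out of reach at calibrated settings:
surgeries averted and ICU admissions averted sit below the published
values because both are pinned to the single further-intervention gate
ratio 0.22/0.23 that also (correctly) reproduces the surgery and ICU
*levels*; matching the published differences would need a UBT insertion
rate above its tertiary maximum or ICU levels ~9% above the published
ones.  The calibration residual report quantifies this honestly.

```{r basecase}
cea <- run_base_case(model)
cea
```

## Sensitivity analyses

`run_owsa()` varies each parameter to its limits, reporting swings on the
NMB scale (default ranking; the ICUR ratio is unstable when a variation
pushes the QALY gain across zero — such entries are flagged).
`run_psa()` draws all sampled parameters (10,000 draws by default), with
both arms evaluated under common draws; pathway costs and QALYs are linear
forms in the drawn values, so each draw set evaluates as one vectorized
pass.  Draws yielding any pathway probability outside [0, 1] are redrawn
and counted (the capped mortality expressions make this rare to absent).
`ceac()` traces the acceptability curve over 0 to 3x the threshold in 200
steps; `psa_summary()` reports net-benefit means with both empirical
percentile intervals of the draws and normal-theory intervals of the mean.

## The microsimulation oracle

`simulate_cohort()` pushes individual women through the same tree by
multinomial splitting at every chance node — distributionally identical to
per-patient Bernoulli walks — and attaches each patient the payoffs of her
matched pathway from the same payoff tables the analytic engine uses, so a
simulation/analytics discrepancy isolates probability bugs rather than
payoff bugs.  `compare_to_tree()` checks every cohort mean against the
analytic expectation in standard-error multiples.  The validation scale
used by the test suite is 200,000 patients at 4 SE.

What the simulator emulates is exactly the cohort homogeneity the
deterministic tree assumes: no patient-level heterogeneity in age, parity
or risk beyond the branch probabilities, no time-to-event structure, no
parameter uncertainty within a run.  Agreement between the two engines
therefore validates the expectation arithmetic, not the model's fidelity
to real Indian facility data.

## Budget impact

`run_bia()` applies the shipped 2021-2025 uptake schedule (phased
primary-to-tertiary introduction, population-growth-driven PPH totals) to
per-patient costs from the calibrated base case.  The default costing mode
prices the TXA tranche at the gross medical-management increment of adding
TXA (about INR 210 per treated patient) — the budget-holder convention in
which downstream resource offsets are not credited against the new
allocation, and the arithmetic underlying the published budget table.  A
`"net"` mode instead uses the full between-arm cost difference (INR ~121),
which yields a cumulative impact of about 1.4% rather than 2.3%; the
difference between the two conventions is itself informative.

## Numerical choices

* 365.25 days per year; 42-day short-term windows; 1.5-day ICU stays.
* Probability-sum tolerance 1e-9 at every chance node; arm symmetry held
  to 1e-12 when TXA-specific parameters are neutralized.
* Mortality expressions are capped into [0, 1] (`pmin/pmax`), so extreme
  joint draws degrade gracefully instead of leaking probability.
* Beta moment fits falling outside the feasible variance region
  (`v >= m(1-m)`) degrade to fixed parameters with a warning; none of the
  packaged parameters does.
* One RNG stream with parameter-order-stable sampling: adding a reporting
  feature never shifts draws; identical seeds give bit-identical draw
  tables.
* Problem sizes: 10,000 PSA draws, 200,000-patient validation
  simulations, 1e5-draw distribution checks — each runs in seconds on one
  CPU.

## Known limitations

* The facility mix, discounting horizon and mortality allocation are
  calibrated, not observed; alternative values are one `analysis_config()`
  call away, and everything fitted is disclosed by the calibration object.
* Surgeries averted and ICU admissions averted cannot reach the published
  differences under any explored structure (see the calibration section).
* TXA adverse events are excluded; the trial evidence reported no
  significant between-arm differences.
* Unit costs come from one Indian state's facilities; the model inherits
  that scope.
* The tree is a single-episode model: no recurrence, no longer-term
  morbidity beyond the listed utility weights, no equity weighting.
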