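---
title: "Model and methods behind osteosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind osteosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(osteosim)
```

osteosim is a patient-level state-transition (Markov) microsimulation of
osteoporosis-related hip, clinical vertebral and wrist fractures in women
aged 40 and over, coupled to a cost-effectiveness / cost-utility pipeline
that compares sixteen prevention and screening strategies from a
public-payer perspective. This vignette is the package's own account of the
model: what is simulated, which inputs are published values and which are
synthetic stand-ins, the numerical choices made where the design was open,
and what the shipped tests do and do not demonstrate.

## The annual-cycle model

Each simulated woman carries an explicit state: age, bone-mineral-density
T-score, prior-fragility-fracture and glucocorticoid-use flags, current
behaviours (physical activity, vitamin D + calcium), treatment state,
residence (community or long-term care), fracture history and vital status.
Time advances in 1-year cycles until every woman has died. Within a cycle,
in order:

1. **Incident fractures.** Independent Bernoulli draws per site on the
   hazard-table probability for the woman's current age band and BMD
   category, multiplied by her treatment relative risk. A woman can have at
   most two hip fractures in a lifetime (each is assumed to lead to
   hemiarthroplasty); her hip hazard is zero afterwards.
2. **Care pathways.** Hip: surgery always, acute rehabilitation with
   probability 0.48, transfer to long-term care with probability 0.20
   (absorbing for residence), follow-up with probability 0.80. Wrist:
   surgery with probability 0.18, otherwise conservative. Clinical
   vertebral: hospitalization with probability 0.10.
3. **Post-fracture cascade.** A woman not already on pharmacotherapy is
   investigated for osteoporosis with probability 0.21; if investigated she
   starts risedronate with probability 0.756 / 0.294 / 0.09 for
   osteoporotic / low / normal BMD, and is otherwise proposed vitamin D +
   calcium. Compliance is drawn once at initiation (0.49).
4. **Death.** The female life-table probability at her age, multiplied by
   4.31 in the cycle of a hip fracture and the following cycle (2.85 for
   clinical vertebral; hip takes precedence), capped at 1.
5. **Accrual.** Costs and utility-weighted time for the cycle are computed
   and discounted by `1/(1+r)^cycle` (3% by default; year 0 undiscounted).

Treatment effects are multiplicative relative risks: risedronate 0.72 /
0.58 / 0.82 (hip / clinical vertebral / wrist), vitamin D + calcium 0.88
(all sites), physical activity 0.62 (hip only). When several preventive
measures apply, the *strongest single* effect is used (the minimum
applicable relative risk), never the product — there is no evidence for a
combined effect, so the conservative single-best assumption is wired in.

### Decisions the published description leaves open

* **Elevated-mortality window.** The duration of post-fracture excess
  mortality is not stated; the default applies the relative risk for the
  fracture cycle plus one further cycle (`mortality_rr_window = 2`,
  configurable). Hip supersedes vertebral when both are in window; the two
  are never compounded.
* **Compliance.** Women are compliant or not, drawn once at initiation.
  Non-compliant initiators receive neither the treatment effect nor the
  treatment cost — partial adherence is not modelled. The same adherence
  model applies to pharmacotherapy and to newly adopted lifestyle
  interventions; *prevalent* behaviours (women already active or already
  taking supplements) are effective by definition and are not costed as
  program expenses.
* **Half-cycle correction.** None; events are resolved within the cycle
  using within-cycle utility phases, and a woman who dies during a cycle
  accrues half the year (costs of the cycle's events accrue in full).
* **Discounting exponent.** Start-of-cycle (`cycle` index), identical for
  costs and QALYs.
* **Long-term care** is absorbing for residence and its annual cost recurs
  (configurable via `ltc_recurring`); residents remain at fracture and
  death risk.
* **Treatment duration** defaults to until death, matching the base case;
  5- and 10-year stopping rules are available for sensitivity analysis.

## Synthetic inputs and their anchors

Several inputs of the original analysis are not published as tables; the
package ships documented synthetic stand-ins, each calibrated to the
printed anchors that do exist:

* **Age distribution** (`default_age_table()`): 5-year band weights shaped
  like an industrialized-country female pyramid, normalised so that the
  deterministic largest-remainder apportionment of 500,000 women yields
  exactly 363,042 aged 40-64 and 136,958 aged 65+ (the published stratum
  sizes). Largest-remainder allocation (rather than multinomial sampling)
  keeps those counts exact.
* **T-score model** (`default_bmd_model()`): T-score ~ Normal(mean(age), 1)
  with the mean declining linearly in age, solved from two published
  prevalence anchors for densitometric osteoporosis (T <= -2.5): 4% at
  50-54 and 45% at 85-89. A woman's population percentile is fixed at
  entry; her T-score follows the declining population mean as she ages.
* **Life table** (`default_life_table()`): a Gompertz-Makeham curve for
  ages 40-110 (certain death at the terminal age), giving a remaining life
  expectancy at 40 of about 43.5 years.
* **Fracture hazards** (`default_hazard_table()`): per site, an
  exponential-in-age baseline times a BMD-category multiplier (~2.0 per
  category step for hip, 1.8 vertebral, 1.5 wrist). The absolute scale is
  set by `calibrate_lifetime_risk()`.
* **CAROC risk surface** (`caroc_ten_year_risk()`): a logistic surface in
  age and T-score anchored to give roughly 15% 10-year risk at the
  osteoporosis threshold at age 65, with one-category escalation for a
  prior fragility fracture or glucocorticoid use (high when both). A
  replacement lookup CSV can be supplied; every test that depends on the
  surface is property-based (monotonicity, escalation), not value-based.
* **Behaviour and risk-factor prevalences**: age-banded defaults (activity
  falling with age, supplement use and clinical risk factors rising); these
  are unpublished and configurable.

### Hazard calibration

`calibrate_lifetime_risk()` scales each site's hazard column so that the
lifetime fracture risk of a woman entering at 40 matches the validation
targets (17.9% hip, 16.07% wrist, 15.83% clinical vertebral) within the 5%
relative criterion. Each multiplier is first solved by bisection (on the
log scale, to a 10^-4 bracket) against a deterministic cohort recursion —
survival from the life table, first-fracture probability from the hazard
table, averaged over a 63-point T-score quantile grid. That recursion
deliberately omits the post-fracture cascade and excess mortality, which
reduce observed lifetime risks by several percent (a treated or dead woman
fractures less), so the multipliers are then refined against the full
microsimulation: two proportional updates on the cumulative-hazard scale,
each evaluated on a 20,000-woman cohort of 40-year-olds. At that size the
binomial standard error of a ~17% risk is about 0.27 points, comfortably
inside the 5% relative band.

## Economics

Unit costs are fiscal 2007-2008 $CAD from the public-payer perspective.
Items conditional on a care pathway are costed only when the pathway was
drawn — applicability probabilities are realised by the draws, never
multiplied in at costing time. The hip inpatient package (acute care
4,070 + hospitalization 19,760 + inpatient visits 229) applies to every hip
fracture; rehabilitation (24,639), long-term care (74,646 per resident
year) and follow-up (990) follow their draws. Vertebral fractures cost
1,004 + 146 + 550 always and 8,047 when hospitalized; wrist fractures cost
3,839 (surgical) or 1,250 (conservative) plus 467 follow-up. Annual
treatment costs: risedronate 162.25 (plus a 99.53 follow-up visit) for
compliant users, vitamin D + calcium 160 and physical-activity promotion 5
for program adopters. Screening costs 160 (visit) + 107.50 (DXA) once at
baseline; screened women get a 98.50 control DXA every 2 years (5 if low
risk). Physical-activity promotion is costed per participant-year at the
upper bound of the published $3-5 per-capita campaign range.

Utilities are published HUI3-derived phase values. A fracture year is a
time-weighted average of its phases (hip: 14 days at 0.30, 30 days at 0.56
if rehabilitation, remainder at 0.85; vertebral: 9 days at 0.33 if
hospitalized, 30 days at 0.68, remainder at 0.85; wrist: one ER day at
0.61, 30 days at 0.88, remainder at 1.00). The vertebral rehabilitation
and wrist phase durations are unpublished; the defaults mirror the hip
(30 days) and are configurable. Fracture-free time accrues at a baseline
utility of 1.0: the published inputs say nothing about non-fracture
utility, and because strategies are compared at (almost) identical
survival, an additive baseline shift cancels out of incremental ratios.
When fractures co-occur in one cycle the lowest site value applies.

## Strategies, ranking and uncertainty

The sixteen strategies are declarative records (`policy_catalog()`):
status quo; three universal primary-prevention arms (offered to women
lacking the behaviour, with a 0.531 participation draw); and twelve
screening arms — direct BMD testing or an OST / SCORE / ORAI prescreen
(sensitivity/specificity 0.768/0.514, 0.90/0.32, 0.933/0.464) followed by
BMD for positives — that categorise the 10-year CAROC risk (low < 10%,
moderate 10 to < 20%, high >= 20%; both boundaries documented and tested)
and treat: high risk with risedronate, moderate risk with risedronate when
another clinical risk factor is present, everyone else with the arm's
preventive package. Prescreen-negative and non-participating women follow
the status quo. Screening is a one-time baseline event; scheduled re-DXA
is costed but does not re-stratify risk.

`rank_and_frontier()` sorts by cost (ties broken by effect, descending),
removes strictly dominated strategies, then removes extended-dominated ones
until incremental ratios strictly increase; the result is asserted against
a brute-force convex-combination oracle in the tests. The presentation
tables (`ce_table()`, `cu_table()`) instead use the sequential-incremental
layout — each strategy against the immediately cheaper one — which can
produce negative "averted" entries for dominated options; that is the
published table layout, and the clean frontier is reported separately.

`run_psa()` re-draws every ranged parameter per replicate: uniforms on
their published ranges; relative risks from a log-normal with
`meanlog = log(base)` and `sdlog = (log(high) - log(low))/(2 * 1.96)`,
i.e. the published range is read as a 95% CI with the base value as
median. Some published utility ranges do not bracket their base value
(e.g. hip hospitalization 0.30 with range 0.51-0.60); both are stored
verbatim and the range is used as printed. Acceptability curves report,
per ceiling ratio, the fraction of replicates with positive incremental
net monetary benefit; exact ties count one half (a documented convention —
the published description is silent). The default grid spans 0-150,000
$CAD in steps of 2,500.

### Common random numbers

Every stochastic step consumes a fixed per-woman draw block (12 uniforms
per cycle, 4 at policy application), drawn in id order for the whole
population including the dead. Because the block layout never depends on
the policy, runs with the same seed and cohort share fate streams
woman-by-woman across strategies. Two useful consequences are tested: with
all treatment relative risks set to 1, every strategy produces *identical*
fracture histories; and a strategy that treats more (all RRs <= 1) can only
remove fracture events, which sharply reduces the variance of incremental
comparisons.

### Varying uptake in a one-way sensitivity analysis

`one_way_sa()` normally varies a parameter in both compared arms. For
uptake-style parameters this is uninformative by construction: a single
participation rate scales both arms' incremental costs and incremental
effects linearly, so the ratio is invariant and any observed change is
Monte-Carlo noise (we verified this — the apparent direction flips seed to
seed). The informative question is what happens when the uptake of the
*strategy under evaluation* changes while the comparator stays at the base
case, which is how tornado-style analyses usually treat uptake; with
`vary_in = "strategy"` the screening program's ratio against the
physical-activity program then falls deterministically as its uptake
rises, because the comparator's (cost-saving) contribution to the
increments is fixed. That is the reading the package tests.

### Discounting and the direction of sensitivity effects

One direction deserves a note. On the cost-utility scale a higher discount
rate raises the screening-versus-prevention incremental ratio, as expected:
the incremental QALYs arrive late and shrink faster than the (partly
upfront) incremental costs. On the cost-per-fracture-averted scale the
fracture counts are *undiscounted* totals, so a higher rate shrinks only
the numerator — which is dominated by the lifelong treatment-cost stream —
and the ratio can fall. The package reports both scales; the tested
discount-rate direction is therefore the cost-utility one, where the
prediction is unambiguous.

## What the tests show — and what they do not

The shipped test suite runs entirely on synthetic cohorts: calibration
recovers the target lifetime risks; the microsimulation agrees with a
closed-form cohort Markov recursion on a one-site, one-age-band toy model
at 50,000 women (within 3 Monte-Carlo standard errors); pathway,
participation and compliance frequencies match their published inputs
within 3 binomial standard errors; the frontier matches brute force on
1,000 random strategy sets; and the qualitative strategy orderings hold
(physical-activity promotion is cost-saving versus the status quo in women
40-64; screening is costlier but averts more fractures; participation and
risedronate-efficacy improvements lower the screening ICER).

Problem sizes were chosen to keep Monte-Carlo error well below each
assertion's tolerance: 20,000 women for calibration and lifetime-risk
checks (binomial SE ~0.27 points on 17.9%), 50,000 for the closed-form
comparison, 8,000-30,000 for the directional comparisons under common
random numbers, 100,000 draws for behavioural rates.

What passing does *not* show: the synthetic life table, hazard surfaces,
BMD trajectory, CAROC surface and behaviour prevalences are plausible
stand-ins anchored to a handful of published numbers, not the unpublished
registry data behind the original analysis. Absolute dollar totals and
ICERs therefore differ from the published tables (which also could not be
reproduced exactly at desk scale); the reproducible quantities are the
wiring of every published parameter, the validation lifetime risks, and
the qualitative structure of the results. Behaviours are independent
Bernoulli draws (no correlation structure), men are out of scope, and drug
side effects, non-skeletal benefits of exercise, other fracture sites,
non-clinical vertebral fractures and indirect costs are excluded by
design.
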