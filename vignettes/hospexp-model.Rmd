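---
title: "The hospexp model: agents, expenses and policy scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hospexp model: agents, expenses and policy scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospexp)
```

## The model

hospexp simulates how medical expenses arise in a tiered public-hospital
system through the interaction of five agent classes: patients, doctors,
medical institutions, the government and medical insurance. Time advances in
two-week cycles (26 per simulated year, the resolution at which disease
prevalence is measured in Chinese national health surveys), and each simulated
year is reported as one annual summary.

The model rests on four simplifying assumptions:

1. **Static population.** Residents are distributed over 16 administrative
   districts with fixed population shares; there is no mobility, birth/death
   process or disease transmission. Illness arrives as independent two-week
   prevalence draws over 30 disease classes.
2. **Uniform doctor income growth.** All professional titles share one annual
   income growth rate and one annual workload-change rate.
3. **Promotion acts on preferences.** Government promotion of the community
   first-visit system changes where minor/common patients *want* to go; it has
   no other channel.
4. **Insurance acts through reimbursement.** The only effect of an insurance
   scheme is its reimbursement proportion, which varies by institution level
   and doubles as the measure of prescription adherence.

### Disease and care-seeking subsystem

Each cycle, for each disease $d$ with two-week prevalence $p_d$, the cohort
size is drawn $n_d \sim \mathrm{Binomial}(N, p_d)$ from the resident
population $N$. Each patient receives independent categorical draws for
gender, age band, occupation, marital status, education and income band, an
insurance scheme by population share, and a district by population share with
a uniform location inside the district rectangle.

Care-seeking preference is a deterministic weight vector over the four
institution types, looked up on (severity class, age band, income band);
diseases flagged specialized-eligible multiply the specialized-hospital
weight. Severe disease always carries zero community-center weight. The
promotion degree $g$ of the community first-visit system multiplies the
community weight of minor/common patients before renormalization, so $g=1$ is
the identity and the scenario multipliers (0.5, 1.5, 2.0) map directly onto
the parameter. The institution type is then sampled from the normalized
weights and the patient is assigned the *nearest* institution of that type by
great-circle (haversine) distance on a 6371 km sphere, ties to the lowest id.

The categorical type draw is implemented by inverse-CDF sampling in a fixed
type order with community centers last. This matters for scenario analysis:
under common random numbers, increasing the community weight can only recruit
patients into community centers and only remove them from tertiary
comprehensive hospitals, which makes direction-of-effect comparisons exact
rather than statistical.

### Medical expenses subsystem

Every episode draws independent Bernoulli care events — outpatient visit,
hospitalization (at least one of the two is forced: a generated patient seeks
care), surgery conditional on hospitalization, physical examination — and is
priced from a per-disease, per-institution-type schedule of nine components
(outpatient base/medicine/exam, inpatient base/medicine/exam, treatment,
surgery, material). Year $y$ prices are compounded exactly:
$c_y = c_0 (1+\gamma_c)^y$ per component. Outpatient episodes use outpatient
components only; hospitalized episodes additionally use treatment, material
and (if operated) surgery.

The attending doctor's title is sampled from the institution's title mix.
Whether the doctor over-prescribes is a Bernoulli decision with probability

$$P(\text{over-prescribe}) = p_{\text{regime}} \cdot (1 - R),$$

where $p_{\text{regime}}$ is 10% in one income regime and 50% in the other,
selected by comparing expected income
$E(h) = -12{,}685.5 + 678.13\,h$ (weekly hours $h$) with actual income, and
$R \in [0,1]$ is the institution's public-welfare responsibility index. $R$
is piecewise linear in the subsidy ratio $s/s_0$ (current over baseline
subsidy proportion), saturating at 175% of baseline for community health
service centers: at that point public-welfare responsibilities are undertaken
perfectly and over-prescription is fully suppressed.

If the doctor over-prescribes, a degree $\delta$ drawn uniformly from the
configured range (default 0.1–0.5) inflates the episode's medicine and
physical-examination base $m$: the prescribed extra is $\delta m$, of which
the patient accepts the adherence fraction $a = 1 - \text{copay}(\text{scheme},
\text{level})$. Only the over-prescribed extra is adherence-scaled — the base
prescription is always dispensed; the adherence mechanism models marginal
prescriptions a patient may decline. Uninsured patients (copay 1 everywhere)
therefore accept no extras at all.

Annual summaries follow the yearbook convention: outpatient per-capita
figures average over episodes with an outpatient event, inpatient figures
over admissions; component ratios divide per-capita component by per-capita
total; expenses are reported to 0.1 CNY and percentage metrics to 0.1 point.

## Design choices

**Direction of the income comparison.** The published decision rule reads
"if expected incomes ≥ actual incomes, 10% of doctors would over-prescribe;
otherwise, 50%". Taken literally, raising doctors' incomes pushes more of
them into the 50% branch — the opposite of the reported intervention result
that higher income and lower workload *restrict* over-prescription, and the
opposite of the income-satisfaction literature the rule descends from. We
treat the literal wording as a transcription slip of the inequality's
direction. `over_prescription_rule()` defaults to the literal wording
(`condition_swapped = FALSE`) so the primitive matches its source, but
`generate_fixture()` configures `condition_swapped = TRUE`: a doctor whose
expectation exceeds their actual income (expectation unmet) over-prescribes
at 50%. Under that orientation all reported intervention directions, the
50% baseline rate and the monotonicity properties hold simultaneously.

**Scale of the expectation regression.** The units of
$E(h) = -12{,}685.5 + 678.13 h$ are unstated. Only the sign of
$E(h) - \text{actual income}$ enters the model, so the fixture places title
incomes (9,500–27,000 CNY) on the regression's own scale, straddling the
expectation line at baseline workloads (40–46 h/week, $E \approx$
14,400–18,500). Junior titles sit below their expectation, senior titles
above; income or workload interventions can therefore flip regimes in either
direction, which is what gives the doctor scenarios their reported signs.

**Responsibility index knee.** The index is
$R = \mathrm{clamp}\big((s/s_0 - r_0)/(r_{\max} - r_0),\, 0,\, 1\big)$ with
$r_0 = 0$ by default (proportional up to saturation) since only the
saturation point (175% for community centers) is documented; $r_{\max} = 3$
for the other three types, whose saturation threshold was reported as not
reached. Setting $r_0 = 1$ instead makes $R$ respond only to subsidy *growth*
above baseline; the acceptance analysis uses that setting to pin $R = 0$
exactly.

**"Rationalized preferences"** (patient tests 2–3) has no formal published
definition. We operationalize it as: severity gating strictly enforced
(always true here), the promotion multiplier applied, and additionally the
tertiary-comprehensive weight of minor/common patients divided by the
promotion degree — minor cases are steered away from topmost hospitals as
well as toward community centers. Patient test 1 (promotion halved, no
rationalization) then raises the tertiary-comprehensive share purely through
renormalization, matching the reported opposite direction.

**Time indexing.** The configuration holds year-0 values; simulated year
$y \in \{1,\dots,Y\}$ uses growth exponent $y$ for expense schedules, doctor
incomes/hours and subsidies. The first reported year is thus one growth step
after initialization, mirroring the validation protocol in which parameters
from one calendar year produce the next year's expenses. Scenario multipliers
are applied once to the baseline configuration, never compounded; scenario
growth-rate changes act from year 1.

**Subsidy growth signs.** All fixture subsidy growth rates are non-negative
(0.2–3.5% per year). Observed subsidy *shares* of some hospital types drift
slightly downward, but scenario transforms multiply growth rates, and
multiplying a negative rate would invert an intervention's sign.

**Randomness.** All stochasticity flows through substreams seeded
deterministically per (year, cycle), derived from one root seed kept below
$2^{31}$. Identical (configuration, scenario, seed) triples give identical
output; matched seeds across scenarios give common random numbers, which the
test suite exploits for exact direction-of-effect and dominance checks. Per
cycle, the same number of uniforms is consumed in the same order regardless
of scenario parameters, so streams stay aligned across counterfactuals.

## The synthetic parameter generator

The study's initial-parameter table (30 disease profiles, expense schedules,
demographic and institutional rosters elicited from yearbooks and expert
consultation) is not publicly available. `generate_fixture()` is therefore a
first-class, seeded stand-in that reproduces its *structure* and plausible
magnitudes, not its values:

* prevalences log-uniform on 0.0005–0.05 per two weeks (summing to a
  two-week morbidity around 25–35%, the order observed in national surveys);
* 12 minor, 12 common and 6 severe disease classes with event probabilities
  banded by severity; five diseases specialized-eligible;
* expense schedules drawn at community level and marked up multiplicatively
  so tertiary > district > community holds in every component, in line with
  tiered fee schedules (and required for the scenario effects to have the
  reported signs);
* 16 districts tiling the metropolitan latitude/longitude extent with
  gamma-distributed population shares; a 100-facility roster covering all
  four types;
* insurance schemes with primary copay 0.30 and tertiary copay 0.50
  (the documented reimbursement anchors); uninsured residents pay in full;
* baseline subsidy proportions around the observed 6–15% of revenue by type.

Because these are stand-ins, absolute CNY outputs of a simulation are not
comparable to the published baseline table — that comparison would require
the true parameter values. What the package targets instead, and what the
test suite verifies, is (a) exact reproduction of all published *arithmetic*
(validation percent differences, annual growth rates, component ratios),
(b) the published behavioral anchors that are parameter-free (the 50%
over-prescription rate in the expectation-unmet regime with zero damping;
perfect responsibility at 175% community subsidy), and (c) the direction and
dominance structure of all ten intervention scenarios. Passing tests
demonstrate the mechanism, not Shanghai's actual expense levels.

The generator also does not emulate several features of real data: joint
demographic structure (only marginals are sampled), comorbidity (one disease
per episode), facility capacity (no queueing or congestion), and real
geography (districts are axis-aligned rectangles; facility coordinates are
uniform). These are out of scope by construction.

## Problem sizes and numerics

Default analyses in the documentation and tests use populations of
1,200–5,000 residents over 1–3 years — enough for roughly $10^4$–$10^5$
episodes per year, which puts binomial standard errors on rate metrics below
half a percentage point while keeping any single run around a second. The
acceptance analysis uses 4,000 residents for one year (≈35,000–45,000
doctor decisions). Expense conservation (episode sums vs aggregated
per-capita × headcount) holds to numerical round-off (≤ $10^{-6}$ CNY);
compounding is exact closed form; exact distance ties resolve to the lowest
institution id; a cycle in which no patient falls ill is skipped; an episode
with neither an outpatient nor an inpatient draw is forced outpatient.

## Known limitations

* Absolute expense levels are fixture artifacts (see above).
* The preference lookup and title-income tables are synthetic; the published
  model elicited them from surveys and the physician White Book.
* Insurance-fund accounting, price regulation and case-mix adjustment are
  not modeled; the insurance channel is reimbursement-as-adherence only.
* The "marginal value" (saturation threshold) of an intervention is left to
  the comparison consumer: `compare_summaries()` reports per-metric deltas,
  and no automatic threshold detector is provided.
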