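---
title: "Risk stratification of hospital utilization: model, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification of hospital utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`riskstrata` evaluates what happens when a prospective, claims-based risk
model — the kind used to set capitated payments and financial benchmarks —
is pressed into service as an *allocation* rule for hospital-avoidance
resources. This vignette documents the statistical machinery, the synthetic
data-generating process and its calibration, and the design decisions that
were genuinely open.

## 1. The study design

Two disjoint populations are drawn from one sampling frame by a seeded
parity split (each beneficiary gets a pseudo-random integer; even goes to
the training arm, odd to the study arm). Each arm has its own
base-year/performance-year pairing — the training arm uses the first
simulated year's diagnoses to predict the second year's admissions, the
study arm uses the second year's diagnoses to predict the third year's —
so no pairing is shared across arms and the evaluation is genuinely
out-of-sample in both population and time.

Eligibility, applied per arm with its own pairing: age 65+ at the start of
the base year; 12/12 months of Part A and Part B in both years, except
decedents, who are retained when they die in the performance year while
enrolled every month alive; any Part C (Medicare Advantage) enrollment or
an ESRD flag excludes; dual-eligible (state buy-in) beneficiaries are
retained. Two operationalizations were open and are package choices: age is
evaluated at January 1 of the base year, and "continuous enrollment" means
12 enrolled months per year (prorated to the death month for decedents).
Beneficiaries dying in the *base* year are excluded — they have no
performance-year outcome to predict.

## 2. The prediction model

The design matrix has one 0/1 column per demographic cell (six 5-year age
bands from 65, top band open, crossed with sex) and one per condition
category. The cells are exhaustive and mutually exclusive, so the
demographic block is a partition of unity across rows and serves as the
intercept; this mirrors how CMS-style risk models carry demographic terms,
and it guarantees the fitted training mean equals the observed mean.
Category flags come from base-year inpatient/outpatient/carrier diagnosis
codes mapped through a pluggable table and then reduced by dominance rules
(a present dominant category removes its subordinates, iterated to a fixed
point; the batch-removal semantics make the result independent of rule
order).

Coefficients are the least-squares solution of the overdetermined system
`X b ≈ y`, computed from the normal equations via a Cholesky solve with an
eigen-pseudoinverse fallback; either route must pass the residual
orthogonality contract `max|X'(y − Xb)| ≤ 1e-6 · max|X'y|`. The fallback
yields the minimum-norm solution when `X'X` is singular — e.g. a category
absent from the training arm — with all-zero columns warned about and given
coefficient 0. Expected study-arm utilization is the plain product
`X_s b_t`, with column order checked, not assumed. Negative expectations
are retained: they occur in the lowest-risk cells, and since every
downstream statistic uses either ranks or group means, clipping would only
obscure the model's behavior.

Quintiles are assigned by a stable sort on (expected value, beneficiary
id); the id tie-break makes assignment deterministic, and when 5 does not
divide n the lower quintiles absorb the remainder (sizes differ by at most
one). Cumulative risk segments union quintiles from the top: top20 =
quintile 5, top40 = quintiles {4,5}, …, all100 = everyone.

Reported statistics: per-quintile predictive ratios (mean expected / mean
observed); 95% confidence half-widths `1.96·sd/√n` (the level is a package
choice — the source methodology names confidence intervals without one);
99% individual-outcome bounds as empirical 0.5th/99.5th percentiles with
the nearest-rank convention; the individual-level coefficient of
determination `R² = 1 − SSE/SST` on the study arm; and per-segment
admission totals, rates, capture fractions and zero fractions. Segment
"rates" are counts per beneficiary expressed as percent — they can exceed
100 — so the distinct any-admission probability is reported alongside to
prevent the two readings being conflated.

## 3. The synthetic data-generating process

Real data of this kind (Medicare fee-for-service limited data sets) are
restricted, so the package ships a generator whose *aggregate* behavior is
calibrated to the documented structure of such a cohort. Beneficiary `i` in
year `t` has latent admission rate

$$\lambda_{it} \;=\; b(\text{cell}_{it}) \prod_k e_k^{z_{ikt}}\,
\varepsilon_i,$$

with admission counts Poisson at `λ_it` times the fraction of the year
alive. The components, and what each is for:

* **Demographic base rates** `b(cell)` rise with age (0.10 to 0.30
  admissions/person-year before scaling, men ×1.1), giving the demographic
  block real signal. A single calibrated scale factor (0.1855) sets the
  overall level.
* **Category effects** `e_k` are multiplicative, log-spaced and paired so
  rarer categories are stronger: prevalences are log-spaced 0.005–0.20
  across 79 categories while effects run 3.0 down to 1.1, raised to a
  calibrated exponent (1.170). Multiplicative stacking of comorbidities is
  what produces the heavy right tail — individuals whose counts are an
  order of magnitude above their quintile's mean — while the fitted model
  remains deliberately *additive*, hence misspecified, as linear risk
  models are for real utilization.
* **A latent rate cap** of 12 admissions/person-year bounds the stacking.
  Without it, rare multi-category draws produce physically impossible rates
  (hundreds of admissions a year) whose realizations dominate the count
  variance and make R² erratic from seed to seed; a dozen admissions a year
  is about the plausible ceiling given typical inpatient lengths of stay.
* **Unit-mean gamma frailty** `ε_i` (calibrated shape 5.53) adds
  individual-level rate variation the model cannot see. The
  negative-binomial zero-probability identity `(r/(r+μ))^r = p₀` is the
  oracle for this knob: a homogeneous stratum with mean 0.689 and zero
  fraction 0.63 implies shape ≈ 0.60, and since within-quintile rate
  heterogeneity already supplies much of that dispersion, the *individual*
  frailty shape lands well above it.
* **Category persistence** 0.7: an active category stays active next year
  with probability 0.7, and incidence among inactives is set so marginal
  prevalence is stationary (a two-state Markov chain). Base-year flags are
  thus an imperfect proxy for performance-year state — the second
  unobservable noise source keeping R² near its empirical value even
  in-model.
* **Demography and attrition**: ages 65–100 with geometrically declining
  mass; 4%/year mortality, deaths uniform in-year, decedents enrolled while
  living; 10% Part C and 1% ESRD flags (exercising the exclusions); 20%
  dual buy-in (retained).

Drawn category sets respect the dominance rules, and each active
(beneficiary, year, category) emits one outpatient/carrier claim whose code
maps to exactly that category, so profiles recovered from claims equal the
drawn sets *exactly* — a round-trip the tests assert. Admissions emit one
inpatient claim each. All randomness flows from a single seed through a
private RNG stream; identical parameters and seed give byte-identical
tables.

### Calibration

`calibrate_defaults()` performs seeded moment matching at n = 100,000, one
full pipeline run per iteration: the base-rate scale is updated by the
ratio of target to current marginal admission rate, the effect exponent by
the ratio of log top-quintile/marginal rate ratios, and the frailty shape
through the zero-probability identity above. Targets (marginal rate 0.27,
top-quintile rate 0.69, top-quintile zero fraction 0.63, capture 0.51,
R² 0.12) are the documented cohort aggregates; the last two are emergent
and only checked. The converged values are frozen as the shipped defaults
and confirmed by independent runs at n = 500,000 under fresh seeds, where
all five statistics hold within ±0.03 (capture is arithmetically implied by
the first two — 0.2 × 0.69 / 0.27 ≈ 0.51 — so the constraint set is
internally consistent).

### What the generator does and does not emulate

It reproduces: the right-skewed, overdispersed count distribution; weak
individual-level predictability coexisting with strong group-level
gradients; base-to-performance-year drift; deaths, exclusions, and
claim-level plumbing. It does **not** emulate real ICD-10 semantics, coding
intensity or upcoding behavior, geographic or provider variation, costs, or
per-quintile predictive ratios exactly equal to 1 (the synthetic world is
calibrated to the five aggregates above, not to group-level calibration of
the misspecified fit — in practice its lowest quintile is visibly
miscalibrated). Passing tests therefore demonstrate that the *pipeline*
computes the study's statistics correctly under a realistic utilization
structure, not that any conclusion transfers to a particular real
population.

## 4. Numerical and testing choices

Problem sizes: module tests run at 10³–10⁵ beneficiaries; the confirmation
runs at 5 × 10⁵ (about 30 s and well under 2 GB). The 553,065-member
aggregate table published for this design is used as an exact worked
example: totals are converted to per-member vectors, pushed through the
quintile/segment code, and must reproduce every printed one-decimal rate
(26.8/31.7/38.7/49.2/68.9 actual; 27.4/32.7/39.9/50.4/70.0 expected) and
the ≈0.513 capture fraction.

Degenerate inputs have defined behavior: a quintile with zero mean observed
reports an `NA` predictive ratio rather than infinity; constant observed
values make R² `NA` with a warning; empty segments and empty id sets are
errors; unmapped diagnosis codes are ignored; cyclic dominance rules are
rejected at table construction (Kahn's algorithm), not at application time.

## 5. Known limitations

* Linear OLS is the only fitted model, by scope; generalized linear or
  count models would be the natural extensions.
* Partial-year decedent exposure is not weighted in the fit (rows enter
  unweighted), matching the simplest reading of the source design.
* The fixture mapping table is structural, not clinical; real mapping and
  hierarchy files can be supplied as CSVs via `read_mapping_table()`.
* Calibration matches five aggregates; higher moments of the count
  distribution are unconstrained beyond what the mechanism implies.
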