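---
title: "Resource-based severity scoring for pediatric trauma undertriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-based severity scoring for pediatric trauma undertriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtriage)
```

## The problem

Field triage sends an injured child either to a pediatric trauma center or
to a community hospital. Retrospective quality improvement needs a
reference standard for "this child needed trauma-center resources" and a
severity score that predicts it from data every hospital has. The ISS,
computed from Abbreviated Injury Scale (AIS) codes, is the conventional
standard, but it targets mortality and needs registry-grade AIS coding.
ICD-code-based scores need only administrative diagnosis lists: ICISS
aggregates per-code survival risk ratios (SRR), and ICASS aggregates
per-code critical-care risk ratios (CCRR). This package implements the
whole comparison pipeline — derive ratios on one span of years, apply them
to a held-out year, classify need for pediatric trauma center resources
(NFPTCR), and compare discrimination by ROC analysis.

## Scores and their estimands

For diagnosis code $j$ carried by $n_j$ derivation patients, of whom $s_j$
survived and $c_j$ had a critical-care episode,

$$\mathrm{SRR}_j = s_j / n_j, \qquad \mathrm{CCRR}_j = 100\, c_j / n_j .$$

A patient with distinct codes $J$ receives

$$\mathrm{ICISS}^{(100)} = \Big(1 - \prod_{j \in J}\mathrm{SRR}_j\Big)\times 100,
\qquad \mathrm{ICASS} = \max_{j \in J} \mathrm{CCRR}_j ,$$

both on a 0–100 scale with higher = more severe, alongside the ISS (sum of
squares of the three worst region AIS values, 75 if any AIS 6). Duplicate
codes within a patient count once, in derivation and scoring. The product
form is the conventional ICISS combination rule; a single-worst-SRR
variant is available via `variant = "worst"` in `score_iciss()` /
`apply_scores()`.

"Episodes" in the CCRR numerator are a patient-level indicator: a carrier
either had a critical-care episode or did not. This keeps CCRR ≤ 100, as
the 0–100 scale requires.

### The critical-care episode rule

What counts as a critical-care episode when deriving CCRR is a modelling
choice. The default (`default_critcare_rule()`) is: ICU admission from the
ED or any recorded ICU stay (≥ 1 day), mechanical ventilation, or
in-hospital death. It is deliberately **not** the NFPTCR composite: ICASS
estimates the general risk of needing critical-care services, while NFPTCR
enumerates trauma-specific center resources, and evaluating a score
against its own defining rule would be circular. The rule is an argument
of `derive_score_table()`, so analysts can substitute their institution's
definition.

### Unseen codes

Codes in the application cohort that never reached the derivation table
contribute, by default, no severity (`srr = 1`, `ccrr = 0`; policy
`"neutral"`). The alternatives are `"cohort_mean"` (impute the table's
mean ratio) and `"strict"` (drop unseen codes and fail a patient whose
codes are all unseen). Neutral is the default because a never-seen code
carries no evidence of severity in either direction and keeps scoring
total. `min_count` (default 1) additionally drops codes with fewer
derivation carriers than the cut-off, since small-$n$ ratios are noisy.

## The NFPTCR composite

`classify_nfptcr()` fires five independent criteria with a per-patient
audit trail (`fired`): transfusion within 4 h; an urgent procedure within
72 h; general anesthesia or mechanical ventilation at age ≤ 5 years; ICU
admission from the ED or ICU stay ≥ 3 days; physical child abuse
report/investigation. All time and age boundaries are inclusive — a
transfusion at exactly 4.0 h, a procedure at exactly 72.0 h, anesthesia at
exactly age 5 and an ICU stay of exactly 3 days all qualify. Death is not
a criterion; ICU days are treated as cumulative whole days, with a partial
day recorded as 1.

## The synthetic registry generator

Real registry extracts cannot be redistributed, so the generator is a
first-class, tested module whose cohorts have the statistical structure
the analysis assumes, with known ground truth.

Each vocabulary code gets a latent anatomic severity $z \sim
\mathrm{Beta}(0.7, 2)$ and an independent resource-need component $u$ from
the same distribution:

* mortality: $1 - p_{\mathrm{surv}} = 0.06\, z^2$ (+ Gaussian noise, sd
  0.005), giving per-code mortality averaging under 1%;
* critical care: $p_{cc} = 0.65\,(0.6 z + 0.4 u)^2$ (+ noise, sd 0.03),
  averaging about 8% per code;
* AIS severity: a noisy monotone discretization of $z$ into 1–6 (noise sd
  1.0, reflecting the coarseness of AIS coding).

The blend encodes the premise the analysis probes: anatomic severity
predicts death well but resource need only partly, because resource use
also depends on physiology, age and injury type. Mortality and
critical-care propensity remain positively coupled through their shared
dependence on $z$.

Patients carry 1–6 distinct codes (count 1 + geometric(0.5), truncated;
real injury records list few distinct codes — the distribution is a
configurable stand-in, as registry code-count distributions are rarely
published). A critical-care episode occurs with probability
$1 - \prod_j (1 - p^{(j)}_{cc})$ and death with marginal probability
$1 - \prod_j p^{(j)}_{\mathrm{surv}}$ — the simplest multiplicative
structure consistent with the SRR/CCRR estimands. Deaths are nested
within critical-care episodes (a child who dies in hospital is taken to
have received critical care), which keeps both marginal rates exact
provided $p_{cc} \ge 1 - p_{\mathrm{surv}}$ per code; the default
vocabulary guarantees this up to noise, and violating configurations are
capped. Every critical-care episode is realized so that the default
derivation rule fires (ICU admission from the ED with ≥ 1 ICU day, or
mechanical ventilation), and additionally plants one qualifying NFPTCR
event drawn from a configurable mix, with its timestamp uniform inside the
qualifying window. Patients without an episode receive qualifying events
only at a small background rate (default 1%), and a configurable fraction
of records (default 5%) get deliberately *out-of-window* events —
transfusions after 4 h, procedures after 72 h — to exercise the timeframe
filters. Demographics follow registry marginals: integer-uniform ages
0–15, mechanism mix ≈ 1.3% abuse / 1.9% penetrating / 32% transport / 65%
other blunt. Under the defaults a cohort shows roughly 1–2% in-hospital
death and a 13–16% NFPTCR+ rate, i.e. about one child in six to seven
needing trauma-center resources.

All randomness flows from a single integer seed through one generator
stream; identical specs give byte-identical cohorts, and `run_study()`
reruns reproduce every output file except the manifest timestamp.

What the generator does **not** emulate: real ICD-9/10 code semantics or
coding error, interfacility-transfer dynamics, hospital-level variation,
within-patient correlation of code counts with severity, and seasonal or
secular trends across years (years are exchangeable labels). Passing
tests therefore show that the *pipeline* recovers known structure — not
that any particular AUC value will transfer to real registry data.

## Evaluation choices

* **AUC** is the Mann–Whitney pair statistic with ties counted ½; ROC cut
  points enumerate all distinct score values (predicted positive = score
  strictly above the cut) plus a −∞ sentinel.
* **Variance** is DeLong's placement-value estimator; the 95% CI is formed
  on the logit scale and back-transformed so it cannot leave [0, 1].
* **Paired comparisons** use the DeLong correlated-ROC test with statistic
  $(\mathrm{AUC}_a - \mathrm{AUC}_b)^2 / \widehat{\mathrm{var}}$ referred
  to $\chi^2_1$ (equivalently a two-sided z-test) — the standard
  equivalent of a paired AUC contrast. When the variance of the
  difference is zero and the AUCs agree (a score versus a monotone
  transform of itself) the statistic is undefined and p = 1. Univariate
  logistic regression of a single score yields the same ROC as the raw
  score (AUC is invariant under strictly increasing transforms — a tested
  property), so no regression step is implemented.
* **Thresholds** default to `c(5, 10, 15, 20)` with the `strict_greater`
  convention ("score > 5"); `geq` is available because published
  threshold tables are not always explicit about the boundary, and the two
  conventions differ exactly at tied boundary values.
* **Descriptives** use Pearson chi-square without continuity correction
  for categorical variables and tie-corrected Kruskal–Wallis for
  continuous ones (with two groups this is the rank-sum test on 1 df).

## Inclusion and the temporal split

`apply_inclusion()` retains patients aged ≤ 15 with a computable ISS
(non-empty AIS profile; `require_iss = FALSE` disables the second check),
logging each exclusion with a reason. The derive/apply split is by
calendar year, not random, mirroring the prospective use of a score table
derived on past years: `run_config()` refuses configurations whose
application year sits among the derivation years, and `apply_scores()`
warns when scored records share years with the table it was given.

## Validation scale

The test suite validates the estimators at deliberately chosen problem
sizes: exact worked examples and boundary cases at $n \le 100$ against
brute-force oracles (pair counting for AUC, per-code recounts for the
score table, subset enumeration for ISS, a stratified paired bootstrap
for the DeLong variance); propensity recovery on single-code cohorts of
30,000 patients (±0.02 tolerance at ~10,000 carriers per code); and the
directional comparison — ICASS discriminating NFPTCR better than ISS,
with a significant paired DeLong test — on a 50,000-patient cohort under
the default generator (a fixed-seed property of those stated conditions,
not a universal law).

## Known limitations

* SRR/CCRR are raw proportions; no shrinkage or smoothing for rare codes
  beyond the `min_count` cut-off.
* "ICU stay ≥ 3 days" is interpreted as cumulative ICU days within the
  index admission; registries that record distinct stays may differ.
* The synthetic mechanism field is sampled independently of the abuse
  criterion flag; analyses of mechanism-specific NFPTCR rates on
  synthetic data reflect only the planted event mix.
* Scores are evaluated for discrimination only; calibration of ICISS as a
  survival probability is out of scope.
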