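---
title: "Claims-based Charlson comorbidity assessment and non-cancer mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based Charlson comorbidity assessment and non-cancer mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Administrative insurance claims are the usual source of pre-diagnosis
comorbidity information for cancer cohorts, because registries rarely record
comorbid conditions. But a diagnosis code on a claim is not a diagnosis: codes
are entered for billing and screening purposes ("up-coding"), chronic
conditions surface only when the patient seeks care, and hospitalizations
select for severity. How one turns a claims history into a Charlson
Comorbidity Index (CCI) therefore involves three consequential choices:

* **washout (rule-out) window** — accept a condition only if two claims
  carrying its codes lie strictly more than *W* days apart (*W* = 30 or 90),
  or accept any single claim (*W* disabled);
* **lookback period** — how far before the cancer index date to search
  (1, 2 or 3 years, half-open window excluding the index date itself);
* **claim types** — inpatient claims only, outpatient only, or either.

The full factorial gives 27 assessment methods. `comorbiscope` implements all
of them, scores the CCI, and estimates the non-cancer mortality hazard
associated with each CCI category under each method, so that the sensitivity
of both prevalence estimates and hazard ratios to the assessment method can
be studied on data with known ground truth.

## Condition coding

Conditions are identified with the ICD-10 coding algorithm of Quan et al.
(2005), shipped as a plain-text table
(`system.file("extdata", "quan_icd10_charlson.tsv", package = "comorbiscope")`)
so it can be audited or replaced by another dialect. Thirteen of the 19
Charlson conditions are in scope: malignancy and metastatic tumour are
excluded by design (every cohort member has cancer, and malignancy codes
C00–C97 define the index event instead), and dementia and AIDS/HIV are
excluded because the claims source this package emulates masks those codes.
Matching is by normalized prefix (`"K2510"` matches prefix `"K25"`); the
prefix sets are pairwise disjoint, which is asserted when the table is
loaded, so a code maps to at most one condition.

Scores use the original Charlson (1987) weights. The standard severity
hierarchy is applied by default — moderate/severe liver disease suppresses
mild liver disease, complicated diabetes suppresses uncomplicated diabetes —
because it is the usual companion of the Quan algorithm and prevents double
counting; `apply_hierarchy()` is a separate, idempotent step, so users who
want the unhierarchical sum can skip it. After the hierarchy, the maximum
attainable score over the 13 conditions is 16. Categories follow the
conventional grouping: 0, 1–2 (mild), 3–4 (moderate), ≥ 5 (severe).

## Ascertainment semantics

Three points in the rule-out algorithm are genuinely open in the literature,
and we fixed them as follows:

* **Disabled washout means a single claim suffices.** The alternative
  reading ("two claims ≥ 0 days apart") would make single-claim histories
  unusable and cannot produce the sharp prevalence increase that removing
  the washout is known to cause.
* **The rule-out applies to every claim stream, including inpatient-only.**
  Klabunde's original algorithm ruled out only outpatient claims; we apply
  the selected washout uniformly to whichever stream the method selects,
  because inpatient-only prevalence is also sensitive to the washout in
  claims data (isolated inpatient screening codes exist too).
* **Under "either", the confirming pair may mix claim types.** This is the
  set-union reading: one inpatient plus one outpatient claim more than *W*
  days apart confirms. `claim_type_breakdown()` makes the consequence
  visible as a `cross_type` bucket — patients confirmed by the union stream
  whom neither single stream would confirm.

These choices imply a lattice of set inclusions — flags(90) ⊆ flags(30) ⊆
flags(none), flags(1y) ⊆ flags(2y) ⊆ flags(3y), and
flags(inpatient) ∪ flags(outpatient) ⊆ flags(either) — which the test suite
verifies per patient and condition on randomized databases.

## Survival model

Non-cancer mortality is modelled with a cause-specific Cox proportional
hazards model on the **age timescale** with **delayed entry**: a patient
diagnosed at age 60 contributes to risk sets only at event ages *t* with
60 < *t* ≤ exit age. Age, not time-since-diagnosis, is the natural timescale
for non-cancer mortality, and entry at diagnosis makes the data
left-truncated — ignoring the truncation leaves patients in risk sets at
ages before they were observed, which biases effects whose covariates
correlate with entry age. The acceptance suite demonstrates this with a
simulation in which a naive fit is biased by more than three standard errors
while the delayed-entry fit is not.

Deaths from the index cancer or another cancer are censored at the death
age (cause-specific hazard convention); competing-risks cumulative-incidence
modelling is out of scope. The partial likelihood is maximized by
`survival::coxph()` with **Efron** tie handling — ties are rare with ages in
days, and Efron has lower bias than Breslow; the difference is negligible at
this tie density. The fitted log partial likelihood is checked against an
independent brute-force risk-set evaluator (tolerance 1e-6) in the tests.
Confidence intervals are Wald, exp(β ± 1.96·SE). Fits with zero events
raise an error; monotone likelihoods and empty risk sets raise explicit
diagnostics rather than returning silent numbers, and `hr_table()` records
them per method without aborting the sweep.

## The synthetic cohort generator

No public claims database links diagnosis codes, enrollment and cause of
death at the granularity needed here, so the package ships a generator whose
output has *known* truth. Its defaults describe the study conditions the
pipeline is meant for: 2979 patients, 50.8% male, age at index normal with
mean 57.4 and SD 15.4 years (truncated to 18–100), index diagnoses uniform
over calendar year 2006, enrollment from 1 January 2002, administrative
censoring on 31 December 2015. Cancer deaths are split ~5:1 between the
index cancer and other cancers, mirroring the cause-of-death mix of large
cancer cohorts.

Mechanisms, chosen as the simplest processes with tunable density:

* **Condition streams.** Each condition is present with its `onset_prob`
  (defaults ranked like claims-cohort prevalence: peptic ulcer 0.19,
  chronic pulmonary 0.16, mild liver 0.095, down to 0.015 for the rare
  conditions); onset is uniform between enrollment start and the index
  date, and from onset the condition emits outpatient and inpatient claims
  as independent homogeneous Poisson processes (defaults 4 and 0.3
  claims/year) carrying random codes from the condition's prefix set.
* **Up-coding.** Spurious codes appear as isolated single claims at
  `upcoding_rate` (default 0.6/patient-year) drawn uniformly from the whole
  coding table, with the intensity multiplied by `upcoding_index_boost`
  (default 6) in the 90 days before the index date — the diagnostic-workup
  burst that makes washout windows necessary. Up-coded claims are
  outpatient with probability 0.8, inpatient otherwise, since screening
  codes occur in both settings.
* **Mortality.** Competing independent exponential cause-specific hazards
  on time since index; the non-cancer hazard is
  `baseline_hazard · exp(log-HR[true CCI category] + sex_log_hr·male)`,
  with default log-HRs 0.3/0.7/1.6 for mild/moderate/severe and defaults
  chosen so that roughly 8% of the cohort dies of non-cancer causes over
  follow-up. The earliest of the competing event times wins; this matches
  the cause-specific Cox estimand exactly, so parameter recovery is a
  well-posed check.
* **`onset_buffer_days`** (default 0) forces onsets to precede the index by
  a margin. It exists because an onset a few days before the index can
  never satisfy a 30-day rule-out, so exact truth recovery is only a
  meaningful target when conditions predate diagnosis by at least the
  washout; validation scenarios set it to several months, which is also
  clinically the typical situation for chronic Charlson conditions.
* **`inpatient_frailty_mode`** (default off) emits condition-related
  inpatient claims only for a random "frail" subpopulation that also
  carries an extra non-cancer hazard (`frailty_log_hr`). This reproduces
  the mechanism by which inpatient-only ascertainment selects sicker
  patients and yields higher hazard-ratio estimates for the same CCI
  category.

All bookkeeping is in days; ages are reported as days/365.25 years. A year
of lookback is 365.25 days. The database is a deterministic function of the
configuration including `rng_seed`, and round-trips exactly through the
plain-CSV on-disk format (`write_claims_db()` / `read_claims_db()`).

What the generator does **not** emulate: seasonal or weekday claim
patterns, correlated comorbidity onset (conditions are independent),
code-position effects (primary vs secondary diagnosis), provider- or
region-level coding variation, procedure and prescription claims, and any
dependence of cancer mortality on comorbidity. Passing tests therefore show
that the pipeline's logic is correct under a transparent data-generating
process — not that any particular assessment method is optimal on real
claims, where these un-modelled features matter.

## Validation design and problem sizes

The suite pairs every non-trivial operation with an independent oracle:
rule-out confirmation against a brute-force all-pairs scan (1000+ random
instances), CCI scoring against an independent summation over all 2^13 flag
vectors, the Cox fit's log partial likelihood against a direct risk-set
evaluator on small fixtures, and ascertainment against the generator truth
on noise-free dense databases. Calibration checks use n = 5000 patients for
log-HR recovery (each true effect within 3 SE), 200 null replicates of
n = 800 records for pooled 95% CI coverage (accepted range 90–98%), 10
databases of n = 2000 for the monotonicity lattice, and n = 3000–6000 for
the qualitative up-coding and claim-type-severity patterns. These sizes keep
Monte-Carlo error comfortably below the tested tolerances while the whole
suite runs in a few minutes on one CPU.

## Limitations

The generator's claim-frequency parameters are plausible rather than
calibrated to any real claims system; prevalence and hazard-ratio *values*
produced on synthetic data are illustrative, and only their qualitative
ordering across assessment methods is meaningful. Dementia and AIDS/HIV are
not scored. There is no ICD-9 support, no age-adjusted or reweighted CCI
variant, no Fine–Gray modelling, and no proportional-hazards diagnostics
beyond convergence checks.
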