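# comorbiscope

Claims-based Charlson comorbidity ascertainment and non-cancer mortality
risk for cancer cohorts.

## The problem

When a cancer cohort is built from administrative insurance claims, each
patient's comorbidity burden must be reconstructed from diagnosis codes on
billed encounters. That reconstruction depends on three analytic choices:
the **washout (rule-out) window** *W* (a condition counts only if two
claims with its codes lie strictly more than *W* days apart, *W* ∈ {30, 90},
or any single claim if the washout is disabled), the **lookback period**
(1, 2 or 3 years before the cancer index date, half-open, excluding the
index date), and the **claim types** searched (inpatient only, outpatient
only, or either). The 3 × 3 × 3 factorial gives 27 assessment methods, and
both comorbidity prevalence and the mortality hazards attached to the
Charlson Comorbidity Index (CCI) can vary severalfold across them.

`comorbiscope` implements the full sweep:

* **Coding** — ICD-10 → Charlson condition mapping after Quan et al.
  (2005), restricted to the 13 conditions meaningful in a cancer cohort
  with masked dementia/AIDS codes; malignancy codes (C00–C97) are excluded
  from comorbidity and instead define the index diagnosis.
* **Scoring** — Charlson 1987 weights with the liver/diabetes severity
  hierarchy; score *s* categorized as 0, 1–2 (mild), 3–4 (moderate),
  ≥ 5 (severe).
* **Survival** — sex-adjusted cause-specific Cox model of non-cancer
  mortality on the **age timescale with delayed entry** (risk set at event
  age *t*: patients with entry age < *t* ≤ exit age), Efron ties, Wald 95%
  CIs; cancer deaths are censored.
* **Simulation** — a synthetic claims generator with known condition truth,
  isolated "up-coded" claims concentrated before the index date, and a
  known CCI-category hazard structure, so the whole pipeline is testable
  end-to-end without restricted data.

## Worked example

```r
library(comorbiscope)

cfg <- generator_config(n_patients = 1000, rng_seed = 42)
db  <- generate_cohort(cfg)
db
#> <claims_db> 1000 patients, 42767 claims, truth for 1000 patients
#>   deaths: 218 index-cancer, 41 other-cancer, 95 non-cancer

cases <- identify_index_cases(db, 2006)        # first C00-C97 claim in 2006,
idx   <- cases[, c("patient_id", "index_date")] # no prior cancer, >=3y enrolled

# prevalence under the reference method: 30-day washout, 2-year lookback,
# either claim type
prev <- prevalence_table(db, idx)
ref  <- subset(prev, washout == 30 & lookback == 2 & claim_types == "either")
head(ref[order(-ref$prevalence), c("condition", "prevalence")], 3)
#>          condition prevalence
#>       peptic_ulcer       17.3
#>  chronic_pulmonary       13.8
#>         liver_mild       10.5

flags <- ascertain_all(db, idx, assessment_method(30, 2, "either"))
cci   <- cci_score(apply_hierarchy(flags[1, ]))  # per patient, or vectorized
recs  <- build_survival_records(db, cases,
          cbind(comorbiscope:::cci_from_flag_matrix(flags),
                patient_id = rownames(flags)), cfg$study_end_date)
fit_left_truncated_cox(recs)
#> <ltcox_fit> n = 1000, events = 95, log PL = -447.182
#>                   term  coef    se   hr ci_low ci_high
#> 1     cci_categorymild 0.407 0.235 1.50  0.947    2.38
#> 2 cci_categorymoderate 0.675 0.358 1.96  0.974    3.96
#> 3   cci_categorysevere 1.607 0.542 4.99  1.723   14.44
#> 4              sexmale 0.664 0.226 1.94  1.248    3.03
```

Read: under the reference method, patients ascertained as mild / moderate /
severe CCI have 1.5× / 2.0× / 5.0× the non-cancer mortality hazard of
CCI-0 patients of the same sex and age — close to the generating log-HRs
(0.3, 0.7, 1.6) despite ascertainment noise. `hr_table(db, enumerate_methods(),
2006, cfg$study_end_date)` repeats this fit for all 27 methods, and
`run_study(cfg, "out/")` writes the full comparison surfaces (prevalence,
comorbidity-count distribution, claim-type composition, hazard ratios,
truth recovery, manifest) as CSV/JSON.

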