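# haisentry

Rule-based surveillance of healthcare-associated infections (HAIs) for
inpatient cohorts.

HAIs — infections acquired during hospitalization, excluding those present
or incubating at admission — must be detected, reviewed and reported, and
screening thousands of inpatients by chart review is prohibitively
labor-intensive. `haisentry` implements the semi-automated alternative: a
knowledge-based pipeline that screens every episode daily, raises detailed
warnings (infection time, site, diagnosis, probability, and the rule that
fired), and adapts its rule confidences to physician feedback. It is
written for clinical informaticians and infection-prevention researchers
who want a transparent, fully testable reference implementation of this
surveillance pattern.

## What it computes

* **Case representation** — each episode-day is an 8-tuple of typed factor
  groups (DE demographics, PS hospitalization status, PN progress-note
  flags, IR imaging-report flags, VS vital signs, CL clinical laboratory,
  OP operations, MO medical orders), built from multi-source records with
  documented conventions (daily maximum temperature, latest-result-wins
  laboratories, keyword lexicons with sentence-level negation cues).
* **Knowledge rules** — conjunctive production rules in a decision-table
  CSV dialect, each row one rule with an id, a target diagnosis, an
  infection probability in (0, 1], and a source tier (clinical guideline or
  expert common understanding). A packaged catalog covers 40 infection
  diagnoses in 12 infection sites; exemplar tables are shipped for pleural
  cavity, urinary tract, lower respiratory tract and soft tissue infection.
* **Inference engine** — a rule fires iff all its conditions hold; per
  diagnosis only the highest-probability rule executes. Post-processing
  classifies onset against the 48-hour rule (onset > 48 h after admission
  ⇒ hospital-acquired), gates on per-diagnosis probability thresholds, and
  suppresses repeats for the same patient and infection site within the
  14-day repeat-infection timeframe (RTI). Every exclusion carries an
  explicit status.
* **Confidence feedback** — monthly, per rule, from the confirmed fraction
  `Acc(i)` of its alerts, solving the implicit update

  ```
  Pr(i) = Pr(i-1) + α (Acc(i) − Pr(i)) / Pr(i-1),   α = 0.75
  ```

  exactly: `Pr(i) = (Pr(i-1)² + α Acc(i)) / (Pr(i-1) + α)`.
* **Evaluation** — episode-level confusion counts and
  `ACC = (TP+TN)/(P+N)`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
  stratified by month, diagnosis and site, comparing the guideline-only
  scenario with guideline-plus-expert.
* **Synthetic cohorts** — a deterministic generator emulating the shape of
  a real surveillance cohort (low prevalence, long-tail diagnosis mixture
  led by LRI, then UTI, then ST) with rule-consistent infection injection,
  factor dropout and note noise, so the whole pipeline is testable without
  hospital data.

See `vignette("hai-surveillance")` for the model, its assumptions and the
design decisions.

## Worked example

```r
library(haisentry)

spec    <- cohort_spec(n_patients = 300, prevalence = 0.05, seed = 2024)
cohort  <- generate_cohort(spec)
cases   <- build_cases(cohort$records)
warnings <- run_surveillance(cases, load_rule_base())
table(warnings$status)
#>        alerted suppressed_rti
#>              9              3

score_episode_level(warnings, cohort$gold)
#> <hai_confusion> TP=9 FP=0 FN=0 TN=291  acc=1 sen=1 spe=1

stratified_report(list(guideline_plus_expert = warnings),
                  cohort$gold, by = "site")
#>   stratum              scenario TP FP FN  TN sen spe
#> 1     RTI guideline_plus_expert  7  0  0 293   1   1
#> 2     SST guideline_plus_expert  1  0  0 299   1   1
#> 3     USI guideline_plus_expert  1  0  0 299   1   1
#> 4 overall guideline_plus_expert  9  0  0 291   1   1
```

The cohort's 12 case-days that satisfied a rule collapse to 9 alerts (one
per infected episode; later firings of the same episode and site fall in
the RTI window and are suppressed). All 9 alerts sit at the correct site,
and none of the 291 clean episodes fires a rule, so sensitivity and
specificity are both 1 — the expected outcome on a noise-free cohort, where
every injected infection satisfies one packaged rule by construction. With
`cohort_spec(dropout = 0.5)` half of the supporting records are omitted and
sensitivity falls while specificity stays 1.

Feedback then adapts the confidences:

```r
fb <- feedback_from_gold(warnings, cohort$gold)
state <- confidence_state(load_rule_base())
state <- monthly_update(state, fb[fb$month == "2020-01", ])
state$rules[["60101"]]$pr     # 0.5 -> 0.8 after a fully confirmed month
#> [1] 0.8
```

A command-line wrapper over the same functions ships in
`inst/cli/hais-cli.R`:

```sh
Rscript inst/cli/hais-cli.R simulate extract infer evaluate \
    --seed 7 --n 80 --prevalence 0.1 --out run1
```

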