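---
title: "Knowledge-based surveillance of healthcare-associated infections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based surveillance of healthcare-associated infections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haisentry)
```

## The surveillance problem

Healthcare-associated infections (HAIs) are infections acquired during a
hospital stay, excluding those present or incubating at admission. In a
semi-automated surveillance workflow, an electronic system screens every
inpatient daily and raises warnings; infection preventionists then review
and confirm each warning before an infection is reported. Because every
confirmed case must be reported, sensitivity is the primary concern, with
specificity as the guard on reviewer workload.

`haisentry` implements this workflow as a transparent, rule-based pipeline:
typed case tuples are built from multi-source records, matched against
conjunctive knowledge rules expressed as decision tables, and post-processed
into auditable warnings; rule confidences adapt monthly to confirmation
feedback; and output is scored against gold labels with stratified accuracy,
sensitivity and specificity. Transparency is the design driver throughout:
every warning cites the rule that produced it, and every excluded warning
carries an explicit status saying why it was excluded.

## Case representation

Each episode-day is an 8-tuple of factor groups:

| Group | Content |
|-------|---------|
| DE | demographics (age, gender) |
| PS | hospitalization status (admission time, hospital day) |
| PN | progress-note keyword flags |
| IR | imaging-report keyword flags |
| VS | vital signs (daily maximum temperature, defecation frequency) |
| CL | clinical laboratory and microbiology (PCT, CRP, fluid leukocytes, culture flags) |
| OP | operations |
| MO | medical orders (urinary catheter, ventilator) |

Factors are typed (`integer`, `real`, `date`, `binary`) and registered in a
declarative registry (`hais_extdata("factor_registry.yaml")`) with unit and
owning group. Binary factors encode suspicion: 0 unsuspected, 1 suspected.
The registry is the extension point: a new factor is declared once and can
then be referenced by lexicon entries and rules. Unregistered factors in a
case are validation *issues*, not errors — the engine degrades gracefully on
unexpected data.

Two missingness regimes are deliberate and distinct:

* text-derived and flag-like binary factors are never missing; absence of
  evidence is 0;
* numeric factors are missing when unmeasured, which is different from 0. A
  rule condition on a missing factor evaluates **false** by default (a rule
  cannot fire on unknown data). This is conservative with respect to false
  alarms and costs sensitivity; `engine_config(missing_fires = TRUE)`
  flips it.

One tuple is built per episode per in-hospital calendar day, so the engine
can be run as a daily review. Conventions, fixed and tested: the admission
day is hospital day 1 and days are counted on the calendar (a 23:50
admission is on day 2 nine hours later); day windows are half-open
`[00:00, 24:00)`; for same-day duplicate laboratory results the later
timestamp wins; keyword flags consider all notes of the episode up to the
surveillance day (a configurable choice — same-day-only would be the
alternative).

## Text factors

Keyword extraction is intentionally minimal: case-folded,
whitespace-normalized substring search per sentence, driven by a
configurable lexicon. A sentence that contains a negation cue (defaults:
"no ", "denies", "without", "rule out", "free of") contributes no evidence.
Sentence-level negation is an extension beyond bare substring matching,
added because without it sensitivity/specificity measurements on any text
containing "no chest pain" would be misleading. This is not clinical NLP:
there is no parsing, no section detection, no word sense handling, and the
shipped lexicon is English while a deployed system would carry a
site-specific one. Keyword flags are monotone in the lexicon by
construction: adding a keyword can only turn 0 into 1.

## The rule dialect

Rules are conjunctive production rules with an action that records an
infection event: rule id, diagnosis, and an infection probability
(confidence) in (0, 1]. They are stored as decision tables — plain CSV with
a four-line header (ruleset name and source tier; target diagnosis; column
kinds `CONDITION`/`ACTION`; a `factor operator` binding per condition
column) followed by one rule per row. A blank condition cell means
*don't care*; a row whose condition cells are all blank is rejected.
Operators are `eq, ne, lt, le, gt, ge, in_range, contains_flag`, with
`in_range` closed-open `[low, high)`. Rules carry a source tier:
`guideline` (derived from clinical guidelines) or `expert` (from infection
preventionists' common understanding); evaluation compares the
guideline-only scenario against guideline-plus-expert.

Four exemplar tables are packaged: pleural cavity infection (PCI, guideline;
its diagnosis rests on five elements — temperature range, progress-note
flag, imaging-report flag, pleural effusion leukocyte count with the
1000 × 10⁶/L cutoff, microbiology), urinary tract infection (UTI, guideline;
seven elements including the hospital-days gate), lower respiratory tract
infection (LRI, expert; using hospital day, age and has-a-PCT-result —
factors outside the guidelines), and soft tissue infection (ST, expert).
The cell values of these tables (temperature ranges, day cutoffs, initial
confidences) are *authored*: they satisfy the documented element constraints
but are not transcriptions of any hospital's production rule base, and every
packaged row is flagged `authored` in the provenance sidecar. Initial
confidences default to 0.5, with 0.9 for etiologically confirmed rules
(positive culture); both are configuration, not estimates. A full deployment
would carry on the order of two hundred rules; the dialect and the engine
are indifferent to the count.

## Engine semantics

The pipeline order is: **match → select → onset → threshold → RTI.**

1. *Match*: a rule fires iff every condition holds. Output is ordered by
   rule id, so matching is deterministic.
2. *Select*: if several rules fire for the same diagnosis on one case, only
   the highest-probability rule is executed; exact ties go to the lowest
   rule id.
3. *Onset*: an infection is hospital-acquired iff its onset is strictly
   more than 48 hours after admission (configurable). For a daily case the
   onset time is the end of the surveillance day. Earlier onsets get status
   `community_acquired`. The 48-hour rule is stated in the source guidelines
   in both directions depending on where one reads; the convention adopted
   here (greater than 48 h ⇒ hospital-acquired) is the international
   standard and is documented rather than silently assumed.
4. *Threshold*: each diagnosis may carry a minimum probability; a warning
   strictly below it gets `below_threshold` and is not sent. Unconfigured
   diagnoses default to threshold 0. Thresholds balance alert precision
   against reviewer workload.
5. *RTI*: the repeat-infection timeframe (default 14 days, per clinical
   guidance) suppresses a warning when the same patient already has an
   earlier surviving alert for the same infection site strictly less than
   14 days before. Keying by site follows the recurrence semantics of the
   timeframe; keying by diagnosis is available via `engine_config(rti_key =
   "diagnosis")`.

The order is itself a design decision: onset classification precedes
thresholding so community-acquired cases are labeled rather than silently
thresholded away, and RTI runs last so that a warning which was rejected
anyway never consumes the suppression window. Every fired rule leaves the
pipeline with exactly one status, so each exclusion is auditable. A
confirmed-infection list can be supplied so physicians who already reported
a case are not re-alerted for the same episode and site.

Boundary semantics are strict everywhere and covered by tests: onset
exactly 48 h after admission is community-acquired; a probability exactly
at the threshold passes; day differences exactly equal to the RTI window
are not suppressed; `in_range` excludes its upper bound.

## Confidence feedback

Each rule's confidence is updated monthly from review outcomes. With
`Acc(i)` the month's confirmed fraction of the rule's alerts and `α` an
adjusting parameter (default 0.75), the update is defined implicitly by

$$Pr(i) = Pr(i-1) + \alpha\,\frac{Acc(i) - Pr(i)}{Pr(i-1)}.$$

The equation places `Pr(i)` on both sides; solving it exactly gives the
closed form used by default:

$$Pr(i) = \frac{Pr(i-1)^2 + \alpha\,Acc(i)}{Pr(i-1) + \alpha}.$$

This form is self-normalizing to (0, 1], has its unique fixed point at
`Acc = Pr(i-1)`, is strictly increasing in `Acc` with slope
`α / (Pr(i-1) + α)`, and contracts toward a constant accuracy under
repeated updates — all properties the test suite verifies, including that
the closed form satisfies the implicit equation to below 1e-12 residual
over a dense grid. A literal non-implicit variant (replacing the
numerator's `Pr(i)` with `Pr(i-1)`) is available via
`update_confidence(explicit_form = TRUE)`; since that variant can leave
(0, 1] (e.g. `0.5 + 0.75·(1−0.5)/0.5 = 1.25`), it is clamped to
[0.01, 1].

Two denominators needed a decision. The accuracy denominator is the rule's
*alerted* warnings in the calendar month (suppressed and thresholded
warnings were never reviewed, so they carry no evidence). A month with zero
alerts for a rule yields no update: the confidence is carried forward and
the empty month is still recorded in the rule's history. Thresholds do not
co-update with confidences; they remain operator-controlled.

## Evaluation

The scoring unit is the episode. With site matching (the default), an
infected episode is a true positive iff at least one alerted warning shares
its gold infection site; matching by diagnosis or by any alert is a
parameter, because which granularity should count as detection is a
genuine choice that changes per-stratum numbers. Metrics follow

$$ACC = \frac{TP + TN}{P + N},\qquad SEN = \frac{TP}{TP + FN},\qquad
SPE = \frac{TN}{TN + FP},$$

and a metric whose denominator is zero is reported as `NA`, never 0, so
averages are not silently deflated. Reports stratify by reporting month
(a partition — per-month confusion counts sum to the overall counts, which
is tested), by diagnosis, or by site, with scenarios side by side.
Diagnosis and site strata score every episode for involvement with the
stratum, so the many uninvolved episodes count as true negatives; this is
why per-diagnosis specificity is structurally inflated and should be read
accordingly. Average rows over strata are unweighted means over defined
values (`report_average()`).

## The synthetic cohort generator

No hospital data ships with the package; the generator exists so that every
pipeline stage is testable end to end. It emulates the *shape* of a
surveillance cohort:

* low prevalence (default 0.03) over mostly short, uneventful episodes
  (mean stay 6 calendar days, Poisson);
* a long-tail diagnosis mixture, heaviest for lower respiratory tract
  infection, then urinary tract infection, then soft tissue infection
  (default weights LRI 0.50, UTI 0.25, ST 0.15, PCI 0.10 over the
  diagnoses that have packaged rules — the ranking mirrors the cohorts such
  systems are built for; the exact weights are the package's own choice);
* uninfected episodes with physiologic baselines: temperature readings in
  36–37.2 °C, occasional normal CRP results, benign notes;
* each infected episode realized *by construction*: an onset more than 48 h
  after admission and record edits that satisfy every condition of one
  randomly chosen packaged rule for its diagnosis — a temperature reading
  inside the rule's range, a laboratory row above its cutoff, a positive
  culture, a note containing a lexicon keyword, an order spanning onset.

Two noise dials make recovery imperfect on purpose: factor dropout `q`
omits each supporting record independently with probability `q` (sensitivity
degrades monotonically in `q`, and exactly coupled across `q` values at a
fixed seed), and note noise plants lexicon keywords in clean episodes'
notes (harmless alone, since no packaged rule fires on a note flag without
corroborating temperature or laboratory evidence). Generation is a
deterministic function of the spec's seed, with the caller's RNG state
restored.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: correlated physiology and comorbidity, real
clinical language (negation beyond the cue list, abbreviations, section
structure), coding and timestamp errors, inter-reviewer disagreement in the
gold standard, and infections that satisfy no rule. Perfect recovery on
noise-free synthetic cohorts validates the *plumbing* (extraction, matching,
post-processing, scoring), not clinical performance; on real cohorts,
sensitivity is bounded by rule coverage and extraction fidelity, which is
exactly why the expert tier and the confidence feedback exist.

## Problem sizes and numerical choices

The shipped tests run at desk scale, as the package's own choice of test
conditions: end-to-end recovery on 500-episode cohorts (about 3,000
case-days), engine-versus-oracle equivalence on 200 randomized cases
against the full exemplar base, the confidence grid at 100 × 100, and
mixture/prevalence checks on pooled cohorts of a few thousand episodes.
An n ≈ 10⁵ cohort — the scale such a system sees in production over a
year — is a matter of the same generator with a larger `n_patients` and is
not exercised by default. All randomized tests fix their seeds; there is no
global randomness anywhere in the package.

Remaining sharp edges, documented rather than hidden: the catalog's OTH
("could not be confirmed") diagnosis ships with no rules targeting it;
rule ids are opaque strings (any site/diagnosis encoding in them is not
relied upon); timestamps are timezone-naive calendar times held in UTC; and
`validate` surfaces — rather than repairs — configuration inconsistencies.
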