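---
title: "Methods: screening, triage, and engagement analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, triage, and engagement analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhtriage)
```

This vignette documents the models and procedures the package implements,
the tunable parameters and why their defaults are what they are, what the
synthetic-cohort simulator does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## Instruments and severity classification

Three self-report instruments are scored:

* **GAD-7** — 7 anxiety items, each 0 ("not at all") to 3 ("nearly every
  day"); total 0–21.
* **PHQ-9** — 9 depression items on the same 0–3 scale; total 0–27. Item
  9 (thoughts of self-harm or of being better off dead) is carried
  through scoring verbatim because the alert rule consumes it.
* **Burnout screen** — 2 emotional-exhaustion questions modelled on the
  Maslach Burnout Inventory frequency scale, 0 ("never") to 6 ("every
  day"); the burnout score is the item mean (0–6 in steps of 0.5).

Severity banding uses the canonical cutoffs shared by both scales — none
0–4, mild 5–9, moderate 10–14, severe ≥ 15 — plus a grouped band that
collapses mild and moderate into *mild-to-moderate* (5–14), the grouping
used when stratifying feasibility cohorts. The PHQ-9's five-band variant
(with "moderately severe" at 20) is deliberately not used: the engine's
triage logic only ever branches at 5, 10, and 15, and carrying an unused
band invites misreading.

Presence flags use the instruments' conventional screening cutoffs
(total ≥ 5 for anxiety and depression). The burnout presence cutoff is a
mean score of 1.0 — i.e. any recurring exhaustion — exposed as
`burnout_threshold` because published burnout screens vary widely in
where they draw this line and the underlying two-question screen has no
canonical cutoff.

## The treatment-plan recommender

The recommender is a rule table, not code: each rule names a source
(instrument total, burnout presence, or a single item), a threshold, and
target modules among the twelve (1 depressed mood, 2 anxiety,
3 apathy-anhedonia, 4 depressive cognitions, 5 suicidal thoughts,
6 restlessness, 7 decreased concentration, 8 overthinking,
9 irritability, 10 sleep disturbance, 11 work-related stress,
12 burnout). The default table:

| trigger | targets |
|---|---|
| GAD-7 total ≥ 10 | 2, 8, 9, 10 |
| PHQ-9 total ≥ 10 | 1, 3, 4, 5, 6, 7, 10 |
| burnout present | 11, 12 |
| PHQ-9 item 1/2/3/6/7/8 ≥ 2 | 3 / 1 / 10 / 4 / 7 / 6 |
| PHQ-9 item 9 ≥ 1 | 5 |
| GAD-7 item 1, 4 or 7 ≥ 2 | 2 |
| GAD-7 item 2 or 3 ≥ 2 | 8 |
| GAD-7 item 5 ≥ 2 | 6 |
| GAD-7 item 6 ≥ 2 | 9 |

Design choices that were genuinely open:

* **Family rules fire at 10 (moderate), not 15.** The simulated scenarios
  the engine reproduces show identical module sets for moderate and
  severe presentations of the same syndrome, which pins the gate at or
  below 10; mild totals (5–9) fall through to the item rules. Behaviour
  below 10 is a package choice; clinics can load a different table.
* **Item rules are gated on the family rule not firing** for that
  instrument. Without the gate, the "isolated symptom" scenarios would be
  unreachable: a single item endorsed at 3 would coexist with item rules
  of the same instrument but the family set would swallow the plan
  anyway whenever a total crossed 10.
* **Item threshold 2 ("more than half the days"), except suicidality at
  1.** Item 9 mirrors the alert rule: any endorsement is acted on.
* **Module 5 stays in the depressive family set** regardless of item 9 —
  the scenario catalog lists it even for "moderate depression without
  suicidal thoughts", so family membership, not the item, carries it.
* **Plans are sorted ascending by module id** (the modules are short and
  sequential); the union of fired targets is deduplicated, and a
  symptom-free response yields an empty plan.

One scenario in the catalog (burnout with moderate depression) expects
only the two work modules, contradicting the depressive family set that
its own totals trigger; the package treats the produced superset as the
correct algorithmic output and flags the scenario (`exact_expected =
FALSE`) rather than special-casing the rule table.

Raising any single item can only add rules that fire, and family-rule
firing only suppresses item rules whose targets are subsets of the family
set, so plans are monotone in item scores — a property the test suite
checks over randomized responses.

## Suicide-risk alerting

Two detectors feed the alert stream:

* the **item-9 rule**: PHQ-9 item 9 at or above `threshold` (default 1)
  emits exactly one alert per assessment, carrying the emergency-
  department recommendation, the configured phone resources, and a team
  notification;
* **intent detection** on free text: deterministic phrase matching
  against a bilingual (Spanish/English) lexicon after lower-casing and
  folding diacritics to ASCII. The first intent in lexicon order wins;
  within an intent, the first listed phrase found is reported. Suicidal
  matches carry the full emergency action set; insult matches are logged
  with a team notification only.

Lexicon matching was chosen over a trained classifier deliberately: the
detector must be auditable line by line in a clinical-safety context, and
its behaviour is exactly reproducible. Lower-casing and diacritic folding
are the only normalizations — no stemming — so the lexicon should list
inflected variants explicitly. The lexicon is editable YAML; detection
quality is bounded by the list, which is a safety floor, not a ceiling.

## User-engagement indicators

Objective UEIs are computed from a typed, timestamped event log, with day
indices counted per user from their first event (day 0, half-open window
of `study_days` = 30 days):

* **completion** — fraction of the baseline cohort with a completion
  event within the window; the default completion event is returning the
  end-of-study MAUQ questionnaire, configurable to the final
  self-assessment.
* **adherence** — fraction with any *active* event after the fourth week
  (day ≥ 28).
* **compliance** — mean over users of (active days)/(expected days).
* **engagement** — engaged user-weeks over expected user-weeks, a week
  counting as engaged with ≥ 5 active days (`week_active_days`,
  configurable within the 5–7 range such definitions quote).

An **active day** requires at least one event of kind
`self_assessment`, `module_start`, `module_complete`,
`weekly_objective_rated`, or `message`. Setting a reminder or recording
an audio note alone does not count: scheduling and passive capture are
not use. This definition is the package's; event-log studies rarely state
theirs.

MAUQ responses (18 statements, 1 = strongly disagree to 7 = strongly
agree) summarize as the mean of per-user means with the SD taken across
users — the between-user spread of overall ratings, which is what a
"mean (SD)" usability headline describes — plus per-statement agreement
(fraction of respondents at ≥ 5).

The feasibility verdict combines a subjective level (MAUQ mean ≥ 5 is
high) and an objective level (all four metrics ≥ 0.5 is high): matching
levels pass through, a mismatch is `moderate`. The 5 and 0.5 cutoffs are
declared in configuration because published verdicts ("high usability",
"low engagement") come without numeric thresholds; 5 is the agreement
point of the 1–7 scale and 0.5 is the natural half-of-expected line.

## The evaluation pipeline

`evaluate_outcomes()` reproduces a small feasibility study's analysis
plan as one deterministic function:

1. pair baseline with a follow-up timepoint by user, per scale;
2. gate on Shapiro-Wilk normality of the paired differences at
   `alpha = 0.05` — paired two-tailed *t* when normal, Wilcoxon
   signed-rank otherwise. Gating on the differences (not the raw
   margins) matches what the paired t assumes;
3. rerun anxiety/depression in the mild-to-moderate baseline subgroup
   (total 5–14) and all scales in the high-engagement subgroup (active-
   day fraction ≥ 0.5);
4. correlate modules completed and days of use with score change
   (Pearson, two-tailed).

Analyses with fewer than 3 pairs are flagged, not fatal, since attrition
makes tiny subgroups routine.

The signed-rank test drops zero differences, ranks |d| with average ranks
under ties, and takes V = sum of ranks of positive d (d = pre − post, so
positive means improvement). Up to 12 retained pairs (`exact_limit`) the
two-sided p comes from full enumeration of all 2^n sign assignments,
implemented as a convolution over doubled ranks so tied (half-integer)
ranks stay exact; beyond that, a normal approximation with tie-corrected
variance and a 0.5 continuity correction reports z. Both modes are
exposed because published small-sample analyses sometimes report z even
at n = 9, and `effect_size_r()` converts z to r = |z|/√N. N defaults to
the retained (non-zero-difference) pairs and is configurable: published
r/z pairs do not always resolve to a stated n, so the convention must be
overridable.

The paired t, Pearson correlation, and Shapiro-Wilk test delegate to R's
stats implementations; the test suite verifies them against closed forms,
and the signed-rank enumeration against an independent brute-force oracle
and the reference implementation.

## The cohort simulator

`generate_cohort()` emulates the conditions of a one-month feasibility
study with biweekly self-assessments:

* **cohort**: 34 baseline users; continuation to the week-2 and week-4
  assessments is memoryless Bernoulli with probabilities 9/34 and 2/9 —
  the attrition margins such studies report, treated as per-step rates;
* **baselines**: GAD-7 totals from a rounded Normal(13.4, 4.9) clamped
  to 0–21, PHQ-9 from Normal(13.2, 6.6) on 0–27, and a right-skewed
  burnout item-sum distribution calibrated to a median score of 2.0;
* **item allocation**: sampled totals are decomposed into item vectors by
  capped largest-remainder allocation toward per-item quotas. PHQ-9
  item 9 is down-weighted (weight 0.15 vs 1) because suicidality is
  endorsed far less often than mood/somatic items at equal totals; equal
  weighting would make most moderate-severity users trip the suicide
  alert, which real alert rates (a few per cohort) contradict;
* **longitudinal change**: per biweekly step, −0.4 points GAD-7 and −0.5
  PHQ-9 plus discretized Normal noise with SD 2.0 (a realistic biweekly
  test–retest fluctuation for these scales — follow-up tables print only
  cross-sectional SDs, so the change SD is a package choice), clamped to
  scale bounds; burnout decays multiplicatively by 0.25 per step plus
  unit-SD noise, putting the week-2 median near 0;
* **usage**: while enrolled, each day is active with probability 0.425
  (the day-level compliance such studies print); active days emit a
  message event and, with probability 0.3, a module start/complete pair
  drawn from the user's own baseline treatment plan; completers return a
  MAUQ with ratings concentrated at 6–7 (mean ≈ 6.5);
* **reproducibility**: one root seed draws a per-user seed sequence, so
  cohorts are byte-identical under a fixed seed and users are
  independent.

The 17 deterministic clinical profiles (`profile_catalog()`) are separate
from the stochastic cohort: hand-constructed item templates that, pushed
through scoring → recommendation → alerting, reproduce each scenario's
expected module set and alert behaviour.

What the simulator does **not** emulate — and therefore what passing
tests do not show about real data: item-level covariance structure
(allocation is quota-based, not factor-based), demographic structure and
its correlates, informative dropout (attrition is independent of
severity), within-day usage patterns beyond fixed event times,
free-text content, and any relationship between usage and symptom change
(dose-response correlations on simulated data are null by construction).

## Numerical choices and degenerate inputs

* Reported percentages and display statistics round half away from zero
  (`round_half_up()`, `pct()`); R's default half-to-even would disagree
  with conventionally printed rates like 24% from 8/34.
* Constant samples: the normality check refuses them; the paired t on
  zero-variance differences returns statistic 0, p 1; correlations on
  constant input are errors.
* All-zero differences in the signed-rank test return a no-change record
  (statistic undefined, p = 1 by convention).
* Validation errors name the offending item index or file line;
  assessment CSVs are schema-strict (exact column set), unknown event
  kinds and configuration keys are rejected.
* Timestamps are ISO-8601 UTC throughout; study days are 0-indexed and
  half-open.

## Problem sizes in the test suite

The suite verifies the signed-rank enumeration exhaustively for n ≤ 10
against a brute-force oracle, the pipeline's type-I error on 500
replicate null cohorts of 30 users (observed fraction of p < 0.05 within
the binomial 95% interval around 0.05), parameter recovery on a
500-user cohort (estimated mean changes within 2 standard errors of the
configured effects), and attrition calibration on replicate cohorts of
34. These sizes were chosen so each property is decided by sampling
theory rather than by luck, while the whole suite stays quick to run.

## Limitations

The recommender and alert lexicon are reference policies, not clinical
guidance; thresholds are configurable precisely because deployments
differ. The burnout screen's two questions have no canonical published
scoring, so its 0–6 scale and cutoff are modelling choices. Intent
detection is list-bounded and language-specific. The evaluation pipeline
applies no multiple-testing correction, matching the descriptive analysis
plans of small feasibility studies it mirrors; interpret subgroup and
correlation p-values accordingly.
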