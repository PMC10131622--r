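# mhtriage

Screening, triage, and engagement analytics for chatbot-style digital
mental-health interventions.

Primary-care systems see large volumes of people with anxiety-depressive
symptoms and work-related burnout, and digital interventions are
increasingly used to screen, monitor, and deliver brief psychological
content between (or instead of) face-to-face visits. `mhtriage` implements
the computational core such an intervention needs — and the analytics a
feasibility study of one needs — as a tested, reusable R package:

- **Instrument scoring** — GAD-7 (7 items, 0–3, total 0–21), PHQ-9
  (9 items, 0–3, total 0–27), and a 2-item work-related burnout screen on
  the Maslach emotional-exhaustion 0–6 frequency scale (score = item
  mean). Severity bands use the canonical cutoffs (none 0–4, mild 5–9,
  moderate 10–14, severe ≥ 15) plus a three-way grouping that collapses
  mild and moderate (5–14).
- **Treatment-plan recommender** — a serializable trigger-rule table maps
  global severity (GAD-7 ≥ 10 → anxiety module family {2, 8, 9, 10};
  PHQ-9 ≥ 10 → depressive family {1, 3, 4, 5, 6, 7, 10}; burnout present
  → {11, 12}) and item-level scores (isolated symptoms endorsed at ≥ 2,
  suicidality at ≥ 1) to the twelve psychological modules.
- **Suicide-risk alerting** — any endorsement of PHQ-9 item 9, or a
  lexicon match (case-insensitive, diacritic-folded, bilingual
  Spanish/English) on free text, emits an alert carrying the emergency
  actions (emergency-department recommendation, phone resources, team
  notification).
- **Engagement analytics** — objective user-engagement indicators from
  timestamped event logs: *completion* (end-of-study questionnaire
  returned), *adherence* (active use after week 4), *compliance*
  (fraction of expected active days), *engagement* (fraction of expected
  weeks with ≥ 5 active days); subjective UEIs via MAUQ scoring (18
  statements, 1–7); combined feasibility verdict.
- **Evaluation pipeline** — Shapiro-Wilk normality gate per scale, then
  paired two-tailed *t* (t = mean(d)/(sd(d)/√n), d = pre − post) or
  Wilcoxon signed-rank with exact sign-assignment enumeration up to
  n = 12 and a tie/continuity-corrected normal approximation beyond;
  effect size r = |z|/√N; mild-to-moderate and high-engagement subgroup
  reruns; dose-response Pearson correlations.
- **Cohort simulator** — 17 deterministic clinical profiles plus
  stochastic cohorts with calibrated baseline distributions, biweekly
  treatment effects, memoryless attrition, and usage event streams, so
  the entire pipeline is testable end to end without patient data.

All user-facing functions are data-frame-first and return tibbles; report
objects have `tidy()`, `glance()`, and `autoplot()` methods.

## Worked example

Score one response, derive its treatment plan, and screen it for risk:

```r
library(mhtriage)
resp <- tibble::tibble(
  user_id = "pc-015", timepoint_index = 0,
  timestamp = as.POSIXct("2022-03-01 10:00:00", tz = "UTC"),
  g1 = 2, g2 = 2, g3 = 2, g4 = 1, g5 = 1, g6 = 1, g7 = 1,
  p1 = 2, p2 = 2, p3 = 2, p4 = 1, p5 = 1, p6 = 1, p7 = 1, p8 = 0, p9 = 1,
  b1 = 4, b2 = 3
)
scored <- score_assessments(resp)
scored[c("gad7_total", "gad7_band", "phq9_total", "phq9_band",
         "burnout_score", "burnout_present")]
#> # A tibble: 1 × 6
#>   gad7_total gad7_band phq9_total phq9_band burnout_score burnout_present
#>        <int> <ord>          <int> <ord>             <dbl> <lgl>
#> 1         10 moderate          11 moderate            3.5 TRUE
```

Both scales are moderate (total ≥ 10) and burnout is present, so all
three family rules fire and the plan covers every module:

```r
plan <- build_plans(scored)
plan$module_ids[[1]]
#>  [1]  1  2  3  4  5  6  7  8  9 10 11 12
plan$rationale[[1]]
#> [1] "anxiety_family"    "depression_family" "work_family"
check_assessment(scored)[c("user_id", "source", "trigger")]
#> # A tibble: 1 × 3
#>   user_id source trigger
#>   <chr>   <chr>  <chr>
#> 1 pc-015  item9  1
```

The endorsed suicidality item (p9 = 1) also raises an alert with the
emergency action set.

Engagement analytics run on event logs; the packaged fixture encodes a
reference feasibility study's headline counts (130 invited, 34 baseline
users, 9 and 2 biweekly follow-ups, 8 completers, 112 modules over 25
users):

```r
counts <- study_counts()
log <- counts_to_log(counts)
usage_summary(log, n_invited = counts$invited)
#> # A tibble: 8 × 5
#>   metric                      num   den    value   pct
#>   <chr>                     <dbl> <int>    <dbl> <dbl>
#> 1 signup_conversion         34      130   0.262   26.2
#> 2 baseline_selfassessment   34       34   1      100
#> 3 second_selfassessment      9       34   0.265   26.5
#> 4 third_selfassessment       2       34   0.0588   5.9
#> 5 modules_performed        112       NA 112       NA
#> 6 users_performing_modules  25       34   0.735   73.5
#> 7 modules_per_active_user    4.48    NA   4.48    NA
#> 8 suicide_alert_users        0       34   0        0
compute_objective_uei(log)
#> # A tibble: 1 × 5
#>   n_users completion adherence compliance engagement
#>     <int>      <dbl>     <dbl>      <dbl>      <dbl>
#> 1      34      0.235    0.0588      0.154      0.184
```

A completion of 8/34 reports as 24% and adherence 2/34 as 6% — both well
below the 0.5 objective cutoff, so with a high MAUQ mean the feasibility
verdict is `moderate` (highly rated, barely used).

A command-line surface wraps the same functions
(`inst/cli/mhtriage score|plan|alerts|uei|evaluate|simulate|report`), and
`vignettes/triage-engine-methods.Rmd` documents the models, thresholds,
and simulator design in detail.

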