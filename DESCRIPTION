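Package: mhtriage
Title: Screening, Triage, and Engagement Analytics for Digital Mental-Health Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested engine for chatbot-style digital mental-health
    interventions in primary care: scoring and severity banding for the
    GAD-7, PHQ-9, and a two-item work-related burnout screen; a rule-based
    treatment-plan recommender mapping global and item-level severity to
    twelve psychological modules; suicide-risk alerting from the PHQ-9
    suicidality item and lexicon-based intent detection on free text;
    objective user-engagement indicators (completion, adherence,
    compliance, engagement) computed from timestamped usage-event logs plus
    MAUQ usability scoring; a paired pre/post statistical evaluation
    pipeline with a normality gate, paired t and exact Wilcoxon
    signed-rank tests, effect sizes, and dose-response correlations; and a
    reproducible synthetic-cohort simulator with clinical profiles,
    baseline score distributions, treatment effects, and attrition, so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
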