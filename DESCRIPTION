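Package: delirispeech
Title: Speech and Language Assessment Scoring for Delirium Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores bedside speech and language assessments used in delirium
    and dementia research: a conversational relevance score adapted from the
    Western Aphasia Battery, Cookie Theft picture-description measures
    (content elements, fluency, grammar, semantic paraphasias, mean utterance
    length) and verbal/written comprehension. Provides an annotated-transcript
    JSON format, tie-corrected nonparametric group comparisons (Kruskal-Wallis,
    Mann-Whitney U with Cohen's r), Kendall tau-b correlations with
    bootstrap confidence intervals, intraclass correlation for inter-rater
    agreement, and a calibrated synthetic cohort generator for three clinical
    groups (delirium, dementia, cognitively unimpaired).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
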