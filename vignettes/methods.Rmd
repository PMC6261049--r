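---
title: "Scoring and analysing bedside speech and language assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analysing bedside speech and language assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delirispeech)
```

## The assessment

Delirium is an acute neuropsychiatric syndrome of disturbed attention and
cognition; language disturbance is part of its diagnostic picture but is
rarely measured directly. `delirispeech` implements a short bedside battery
for quantifying speech production and comprehension in hospitalized older
adults, together with the nonparametric case-control statistics used to
compare three clinical groups (delirium, dementia without delirium,
cognitively unimpaired), and a calibrated synthetic cohort generator so the
entire pipeline can be exercised and tested without patient data.

The battery has three parts.

**Conversational speech.** Three open questions adapted from the Western
Aphasia Battery-Revised ("How are you feeling today?", "What brought you to
the hospital?", "How are you finding it here?"). The rater segments the
recorded response into *utterances* — fragmented or complete sentences
bounded by a significant pause — and tags each utterance relevant or
irrelevant to the question. Per question, the percentage of relevant
utterances maps to a score: 3 for 100% relevant, 2 for 51–99%, 1 for 0–50%.
The three questions sum to a 0–9 conversational score, higher meaning more
relevant speech.

A rubric that starts at 1 cannot reach a total of 0, yet 0 is the stated
floor of the scale; we therefore assign 0 to a *mute* question — one on
which no utterances were produced. This is the only convention consistent
with the published scale range, and it is applied only when the utterance
list is empty, never for merely irrelevant speech.

**Cookie Theft picture description.** Semi-spontaneous speech elicited with
the Boston Diagnostic Aphasia Examination's Cookie Theft picture. From the
annotated transcript the package computes:

| variable | definition |
|---|---|
| content | # relevant content elements − # irrelevant content elements |
| fluency | 100 × (word/utterance repetitions + fillers + utterance repairs) / total words |
| grammar | 100 × (incorrect tenses + ambiguous articles) / total words |
| semantic errors | 100 × semantic paraphasias / total words |
| mean utterance length | total words / total utterances |

**Comprehension.** Four verbal and four written commands; one point per
action performed correctly, scored 0–4 per modality.

## The transcript model

All annotation is a rater decision made while listening to the audio:
utterance boundaries (a pause threshold cannot be recovered from text),
relevance, disfluency events, grammar errors and paraphasias. The package
therefore stores *pre-annotated* transcripts in a fixed JSON schema
(`system.file("extdata", "transcript-schema.json", package =
"delirispeech")`) and never attempts to infer annotations from raw text.
Serialisation is canonical — fixed key order, two-space indent — so
`write_transcript()` ∘ `parse_transcript()` is the identity on canonical
files, a property the test-suite verifies on randomly generated transcripts.

Conventions the format fixes, and why:

* **Fillers count as words.** The fluency numerator counts filler items and
  the denominator is "total number of words produced"; with no published
  exclusion rule, the least surprising reading is that every produced token
  counts. `word_count(s, include_fillers = FALSE)` gives the alternative.
* **A whole-utterance repetition is one event**, carried as a flag on the
  utterance, regardless of its length; word-level repetitions are token
  annotations contributing one event per annotated token. The same holds
  for utterance repairs.
* **Duplicate relevant content elements count once** (an element is either
  named or not — the usual content-element convention); irrelevant
  intrusions count per occurrence. Both are configurable in
  `content_score()`. The element inventory is a configuration input
  (shipped default: an 18-item Cookie Theft list), since published studies
  rarely enumerate theirs.
* **Undefined is not zero.** A sample with no words (or no utterances)
  makes the rate scores undefined; they propagate as `NA` and the analysis
  treats them as missing. Coding them 0 would manufacture spurious group
  differences in exactly the patients (mute, severely impaired) where it
  matters most.
* **Missing comprehension responses are not incorrect**: a command that was
  never administered simply reduces the number administered and flags the
  panel incomplete.

## Statistical analysis

Ordinal, tie-heavy, non-normal scores call for rank methods throughout:

* `kruskal_wallis()` — omnibus H with the tie correction
  $1 - \sum(t^3-t)/(N^3-N)$, p from $\chi^2_{k-1}$.
* `mann_whitney_u()` — pairwise U, reported as $\min(U_x, U_y)$ (the
  convention of the major commercial packages), Z from the tie-corrected
  normal approximation *without* continuity correction, and Cohen's effect
  size $r = |Z|/\sqrt{N}$. An exact-enumeration p is available for small
  tie-free samples. The suite checks the statistic against exhaustive
  permutation enumeration for all $n_1+n_2 \le 10$ and the two-group
  identity $H = Z^2$ to $10^{-9}$.
* `kendall_tau_b()` — tau-b (tie-adjusted denominator) with the normal
  approximation p, and a percentile bootstrap CI over paired case
  resampling (default `n_boot = 2000`, fixed default seed). Percentile
  bootstrap and B were chosen as the plainest defensible defaults; both are
  arguments. Coverage is verified by simulation (~95% for
  bivariate-normal-derived data at n = 40).
* `icc()` — ICC(2,1): two-way random effects, absolute agreement, single
  rater. This is the conventional model when a random pair of trained
  raters independently re-scores a subset of transcripts; mean squares come
  from the standard two-way ANOVA.
* `group_summary()` — medians and quartiles by inclusive linear
  interpolation (`quantile` type 7); the convention is an argument because
  published IQRs rarely state theirs.
* Significance is two-sided at α = 0.01 with no further multiple-testing
  correction, matching the design this battery comes from; the choice is a
  parameter of `compare_groups()`.
* RASS (agitation–sedation) is signed, with 0 = alert; arousal *abnormality*
  is its magnitude. `correlate_scores()` therefore uses |RASS| by default
  (`rass_absolute = FALSE` for the signed scale). Normality screening never
  switches the pipeline to parametric tests.

## The synthetic cohort generator

Published group-level evidence constrains only medians and IQRs, so the
generator uses the simplest observation model matching support and skew,
with one latent severity variable per participant inducing realistic
cross-correlations:

* utterance lengths: lognormal (positive, right-skewed; matches the skewed
  printed IQRs), rounded to whole words, minimum 1;
* utterance counts: Poisson truncated to ≥ 1;
* every per-token event (filler, repetition, grammar error, paraphasia):
  independent Bernoulli at the profile rate; per-utterance repair and
  repetition flags likewise;
* content elements: per-element Bernoulli recall over the inventory, plus a
  Poisson number of irrelevant intrusions;
* comprehension: per-command Bernoulli;
* covariates (age, OMCT, BAT, DRS-R98, OSLA, RASS, pain): rounded,
  range-clamped draws around the group's published medians.

The latent severity $s_i \sim N(0,1)$ shifts utterance length, relevance,
content recall, comprehension and the cognitive/arousal covariates together
(coefficients in the profile), which is what gives the Kendall correlations
between attention/arousal and language their moderate-to-strong magnitudes.

Default profiles (`default_profiles()`, shipped as
`inst/extdata/default_profiles.yaml`) were calibrated once by moment
matching: parameters were set so the induced per-group medians of the
headline scores (mean utterance length 4.2/7.5/8.69 for
delirium/dementia/control, content 4/6/12, conversational score 7/7/9,
written comprehension 3/4/4) sit at the published medians, then frozen. No
optimisation happens at run time. Over 200 seeded cohorts the per-group
median of each headline score falls inside the corresponding published IQR
in well over 80% of cohorts, and the delirium-vs-control utterance-length
comparison rejects at α = 0.01 in essentially all cohorts, while
identical-profile groups reject at the nominal ~1%.

What the generator does *not* emulate: real lexical content (tokens are
placeholder vocabulary), within-interview fluctuation of delirium, motor
subtypes, and any dispersion structure beyond what medians/IQRs pin down —
distribution tails are unconstrained by the published evidence and follow
from the chosen parametric forms. Passing tests on synthetic cohorts
demonstrates that the scoring and statistics behave correctly under a
*plausible* observation model, not that the battery has clinical validity.

## Problem sizes used in the test-suite

The oracle-equivalence checks run on 1,000 generated samples; MWU
enumeration covers every size with $n_1+n_2\le10$; bootstrap coverage uses
500 replicates of 200 resamples at n = 40; calibration and type-I checks
use 200 cohorts of 45 participants each; the contrast-pattern check uses 60
cohorts. These sizes give simulation standard errors comfortably below the
asserted margins while keeping the default suite quick to run.

## Worked example

```{r example, eval = FALSE}
library(delirispeech)

cohort <- generate_cohort(sim_config(n_per_group = 15, seed = 42))
report <- compare_groups(cohort$scores, alpha = 0.01)
print(report)

correlate_scores(cohort$scores, predictors = "bat",
                 variables = c("ct_content", "written_comp"))
```

## Known limitations

* The battery itself is unvalidated as a clinical instrument; this package
  reproduces its arithmetic and statistics, not its psychometrics.
* Whether a repeated whole utterance's words should enter "total words"
  once or twice is unspecified in the source rubric; we count every
  produced token.
* The exact-p option for `mann_whitney_u()` is unavailable under ties
  (as with `wilcox.test`); the tie-corrected normal approximation is the
  default everywhere.
* Synthetic cohorts inherit every simplification listed above; in
  particular, agreement between synthetic results and published group
  statistics beyond medians/IQR/significance-pattern should not be
  expected.
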