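# delirispeech

Scoring and nonparametric analysis of bedside speech-and-language
assessments for delirium and dementia research.

Language disturbance is part of the delirium syndrome, but most delirium
instruments only observe it indirectly. This package implements a short,
quantitative battery for case-control studies in hospitalized older adults
— three groups: delirium, dementia without delirium, cognitively
unimpaired — covering:

* **Conversational speech** — three open questions; each scored from the
  percentage of relevant utterances (3 for 100% relevant, 2 for 51–99%,
  1 for 0–50%, 0 for a mute question), summing to a 0–9 conversational
  score.
* **Cookie Theft picture description** — content elements
  (relevant − irrelevant), fluency
  (100 × (repetitions + fillers + repairs) / words), grammar
  (100 × tense/article errors / words), semantic errors
  (100 × paraphasias / words) and mean utterance length (words/utterance).
* **Comprehension** — four verbal and four written commands, one point per
  correctly performed action.

Around the scoring battery the package provides:

* an annotated-transcript **JSON format** (rater-segmented utterances with
  token-level disfluency/error annotations; schema shipped in
  `inst/extdata/`), with lossless canonical round trips;
* the **statistics** of a three-group case-control analysis: tie-corrected
  Kruskal–Wallis *H*, pairwise Mann–Whitney *U* (reported as min(*U*ₓ, *U*ᵧ))
  with *Z* and Cohen's *r* = |*Z*|/√*N*, Kendall τb with seeded
  percentile-bootstrap CIs, ICC(2,1) for inter-rater agreement, and an
  age-regression screen — two-sided α = 0.01 by default;
* a calibrated **synthetic cohort generator** (lognormal utterance lengths,
  truncated-Poisson utterance counts, Bernoulli per-token events, a latent
  severity coupling language with attention/arousal covariates), so the
  whole pipeline is testable without patient data.

## Worked example

```r
library(delirispeech)

cohort <- generate_cohort(sim_config(n_per_group = 15, seed = 42))
report <- compare_groups(cohort$scores,
                         variables = c("wab_score", "ct_mean_utt_len",
                                       "written_comp"))
print(report)
```

```
Group comparison report (alpha = 0.01 , two-sided)

wab_score: H(2) = 17.93, p = 0.0001279 *
  delirium  n = 15  median = 7 (IQR 5.5-8)
  dementia  n = 15  median = 8 (IQR 7-8.5)
  control   n = 15  median = 9 (IQR 9-9)
  delirium vs dementia: U = 73.00, p = 0.09299, r = 0.31
  delirium vs control: U = 22.50, p = 7.333e-05, r = 0.72 *
  dementia vs control: U = 45.00, p = 0.002009, r = 0.56 *

ct_mean_utt_len: H(2) = 23.02, p = 1.004e-05 *
  delirium  n = 15  median = 4.067 (IQR 3.278-5.375)
  dementia  n = 15  median = 7.778 (IQR 6.581-10.23)
  control   n = 15  median = 9.167 (IQR 7.3-11.44)
  delirium vs dementia: U = 21.00, p = 0.0001475, r = 0.69 *
  delirium vs control: U = 9.00, p = 1.763e-05, r = 0.78 *
  dementia vs control: U = 83.00, p = 0.2211, r = 0.22

written_comp: H(2) = 7.78, p = 0.02046
  delirium  n = 15  median = 3 (IQR 1-4)
  dementia  n = 15  median = 4 (IQR 3-4)
  control   n = 15  median = 4 (IQR 4-4)
  delirium vs dementia: U = 80.50, p = 0.1565, r = 0.26
  delirium vs control: U = 58.00, p = 0.00863, r = 0.48 *
  dementia vs control: U = 77.00, p = 0.06672, r = 0.33
```

Reading it: each variable gets the omnibus *H* across the three groups,
per-group medians (IQR), and the three pairwise *U* tests with effect size
*r*; `*` marks p < 0.01. In this simulated cohort patients with delirium
speak in markedly shorter utterances than either comparison group (median
4.1 words/utterance vs 7.8 and 9.2; *r* ≈ 0.7–0.8), produce less relevant
conversational speech than controls, and show a written-comprehension
deficit relative to controls — the pattern the generator's group profiles
encode.

Correlating attention with language over the whole sample:

```r
kendall_tau_b(cohort$scores$bat, cohort$scores$written_comp)
#> Kendall tau-b = 0.39, p = 0.002065, 95% CI = 0.20, 0.58 (n = 45, 2000 bootstrap resamples)
```

A command-line wrapper is shipped at
`system.file("cli", "delirispeech.R", package = "delirispeech")` with
subcommands `score`, `compare`, `correlate`, `icc`, `simulate`,
`validate`.

See `vignettes/methods.Rmd` for the model, the annotation conventions, the
generator's calibration and its limitations.

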