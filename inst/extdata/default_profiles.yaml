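# Default generative profiles for the three clinical groups.
# Calibrated once by moment-matching the induced per-group score medians to
# the published group medians/IQRs for the language battery; frozen here.
# Rates are per word (token) unless suffixed _utt (per utterance).
# severity_* coefficients couple each outcome to a per-participant latent
# severity (standard normal), inducing realistic cross-correlations between
# attention/arousal covariates and language scores.
control:
  speech:
    conv_utterances_mean: 4.0
    ct_utterances_mean: 11.0
    utt_len_meanlog: 2.01
    utt_len_sdlog: 0.55
    severity_utt_len: 0.25
    p_relevant_utterance: 0.97
    severity_relevance: 0.5
    filler_rate: 0.05
    word_repetition_rate: 0.015
    grammar_error_rate: 0.015
    paraphasia_rate: 0.005
    repair_rate_utt: 0.05
    repetition_rate_utt: 0.02
  content:
    recall_prob: 0.70
    severity_recall: 0.5
    irrelevant_mean: 0.3
  comprehension:
    p_verbal: 0.97
    p_written: 0.95
    severity: 0.8
  covariates:
    age_mean: 78.0
    age_sd: 5.0
    p_female: 0.60
    omct_mean: 26.5
    omct_sd: 1.2
    omct_severity: 1.0
    bat_mean: 6.3
    bat_sd: 0.7
    bat_severity: 0.6
    drs_r98_mean: 0.7
    drs_r98_sd: 0.8
    drs_r98_severity: 1.5
    osla_mean: 0.2
    osla_sd: 0.5
    osla_severity: 0.8
    rass_mag_mean: -0.7
    rass_mag_sd: 0.6
    rass_mag_severity: 0.4
    rass_p_negative: 0.7
    pain_mean: 2.0
    pain_sd: 2.0
dementia:
  speech:
    conv_utterances_mean: 4.0
    ct_utterances_mean: 10.0
    utt_len_meanlog: 1.864
    utt_len_sdlog: 0.55
    severity_utt_len: 0.25
    p_relevant_utterance: 0.82
    severity_relevance: 0.5
    filler_rate: 0.06
    word_repetition_rate: 0.02
    grammar_error_rate: 0.02
    paraphasia_rate: 0.01
    repair_rate_utt: 0.08
    repetition_rate_utt: 0.03
  content:
    recall_prob: 0.40
    severity_recall: 0.5
    irrelevant_mean: 1.0
  comprehension:
    p_verbal: 0.93
    p_written: 0.88
    severity: 0.8
  covariates:
    age_mean: 86.0
    age_sd: 6.0
    p_female: 0.67
    omct_mean: 4.5
    omct_sd: 2.0
    omct_severity: 1.5
    bat_mean: 4.0
    bat_sd: 1.2
    bat_severity: 0.6
    drs_r98_mean: 11.0
    drs_r98_sd: 4.0
    drs_r98_severity: 2.0
    osla_mean: 1.0
    osla_sd: 1.2
    osla_severity: 0.8
    rass_mag_mean: -0.5
    rass_mag_sd: 0.7
    rass_mag_severity: 0.4
    rass_p_negative: 0.7
    pain_mean: 2.5
    pain_sd: 2.0
delirium:
  speech:
    conv_utterances_mean: 4.0
    ct_utterances_mean: 10.0
    utt_len_meanlog: 1.284
    utt_len_sdlog: 0.55
    severity_utt_len: 0.25
    p_relevant_utterance: 0.80
    severity_relevance: 0.5
    filler_rate: 0.08
    word_repetition_rate: 0.03
    grammar_error_rate: 0.03
    paraphasia_rate: 0.015
    repair_rate_utt: 0.10
    repetition_rate_utt: 0.05
  content:
    recall_prob: 0.28
    severity_recall: 0.5
    irrelevant_mean: 1.5
  comprehension:
    p_verbal: 0.85
    p_written: 0.70
    severity: 0.8
  covariates:
    age_mean: 88.0
    age_sd: 5.0
    p_female: 0.53
    omct_mean: 0.5
    omct_sd: 3.5
    omct_severity: 2.0
    bat_mean: 2.5
    bat_sd: 1.8
    bat_severity: 0.6
    drs_r98_mean: 22.0
    drs_r98_sd: 6.0
    drs_r98_severity: 2.0
    osla_mean: 5.5
    osla_sd: 3.0
    osla_severity: 1.0
    rass_mag_mean: 1.2
    rass_mag_sd: 1.0
    rass_mag_severity: 0.4
    rass_p_negative: 0.7
    pain_mean: 3.0
    pain_sd: 2.0
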