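# Synthetic cohort generator.
#
# Emulates the observation model of a three-group case-control study of
# speech and language (delirium, dementia, cognitively unimpaired; N = 15
# per group by default).  The published evidence constrains only group
# medians and IQRs, so the generator uses the simplest distributions that
# match support and skew: utterance lengths are lognormal (positive,
# right-skewed), utterance counts truncated Poisson (>= 1), every per-token
# disfluency/error a Bernoulli event, content-element recall per-element
# Bernoulli.  A per-participant latent severity (standard normal) shifts
# speech, comprehension and the cognitive/arousal covariates together,
# inducing the attention/arousal-language correlations seen in real
# cohorts.  Token text is synthetic placeholder vocabulary, not natural
# language.

SYNTH_LEXICON <- c("cup", "table", "garden", "window", "nurse", "morning",
                   "tea", "chair", "doctor", "yesterday", "home", "dinner",
                   "walking", "raining", "family", "bed", "tired", "fine",
                   "hospital", "breakfast")

#' Default group profiles for the synthetic cohort
#'
#' Loads the shipped generative parameters for the three clinical groups
#' (`inst/extdata/default_profiles.yaml`).  The defaults were calibrated by
#' moment-matching so that the induced per-group medians of the headline
#' language scores (mean utterance length, content, conversational score,
#' written comprehension) fall inside the published interquartile ranges;
#' they are frozen, not re-fit at run time.
#'
#' @param path Optional path to an alternative profiles YAML file.
#' @return Named list of group profiles (`delirium`, `dementia`,
#'   `control`), each with `speech`, `content`, `comprehension` and
#'   `covariates` parameter blocks.
#' @export
default_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_profiles.yaml",
                        package = "delirispeech", mustWork = TRUE)
  profiles <- yaml::read_yaml(path)
  if (!setequal(names(profiles), GROUPS))
    stop("profiles must define exactly the groups ",
         paste(GROUPS, collapse = ", "), call. = FALSE)
  for (g in names(profiles)) validate_profile(profiles[[g]], g)
  profiles
}

validate_profile <- function(p, group) {
  probs <- c(p$speech$p_relevant_utterance, p$content$recall_prob,
             p$comprehension$p_verbal, p$comprehension$p_written,
             p$covariates$p_female, p$covariates$rass_p_negative)
  if (any(probs < 0 | probs > 1))
    stop("profile '", group, "': probabilities must lie in [0, 1]",
         call. = FALSE)
  rates <- c(p$speech$filler_rate, p$speech$word_repetition_rate,
             p$speech$grammar_error_rate, p$speech$paraphasia_rate,
             p$speech$repair_rate_utt, p$speech$repetition_rate_utt,
             p$content$irrelevant_mean)
  if (any(rates < 0))
    stop("profile '", group, "': rates must be >= 0", call. = FALSE)
  if (p$speech$utt_len_meanlog <= 0 && exp(p$speech$utt_len_meanlog) <= 0)
    stop("profile '", group, "': utterance length scale must be positive",
         call. = FALSE)
  invisible(p)
}

# Poisson truncated to >= 1, by inverse-CDF restricted above 0
rpois_pos <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# one speech sample; severity shifts utterance length and relevance
generate_sample <- function(task, sp, severity, inventory, content_par) {
  lambda <- if (task == "cookie_theft") sp$ct_utterances_mean else
    sp$conv_utterances_mean
  n_utt <- rpois_pos(1, lambda)
  mulog <- sp$utt_len_meanlog - sp$severity_utt_len * severity
  lens <- pmax(1, round(stats::rlnorm(n_utt, mulog, sp$utt_len_sdlog)))
  p_rel <- stats::plogis(stats::qlogis(sp$p_relevant_utterance) -
                           sp$severity_relevance * severity)
  relevant <- if (task == "cookie_theft") rep(TRUE, n_utt) else
    stats::rbinom(n_utt, 1, p_rel) == 1

  total <- sum(lens)
  is_filler <- stats::rbinom(total, 1, sp$filler_rate) == 1
  is_rep <- stats::rbinom(total, 1, sp$word_repetition_rate) == 1
  is_gram <- stats::rbinom(total, 1, sp$grammar_error_rate) == 1
  is_para <- stats::rbinom(total, 1, sp$paraphasia_rate) == 1
  words <- sample(SYNTH_LEXICON, total, replace = TRUE)
  words[is_filler] <- "erm"
  tok_utt <- rep(seq_len(n_utt), lens)

  utts <- vector("list", n_utt)
  repair <- stats::rbinom(n_utt, 1, sp$repair_rate_utt) == 1
  utt_rep <- stats::rbinom(n_utt, 1, sp$repetition_rate_utt) == 1
  for (j in seq_len(n_utt)) {
    sel <- which(tok_utt == j)
    toks <- lapply(sel, function(i) {
      ann <- c("filler", "repetition", "grammar_error",
               "semantic_paraphasia")[c(is_filler[i], is_rep[i],
                                        is_gram[i], is_para[i])]
      token(words[i], ann)
    })
    utts[[j]] <- utterance(toks,
                           relevance = if (relevant[j]) "relevant" else
                             "irrelevant",
                           repetition_of_utterance = utt_rep[j],
                           repair_flag = repair[j])
  }

  ce <- list()
  if (task == "cookie_theft") {
    p_recall <- stats::plogis(stats::qlogis(content_par$recall_prob) -
                                content_par$severity_recall * severity)
    hit <- stats::rbinom(length(inventory), 1, p_recall) == 1
    ce <- lapply(inventory[hit], content_mention, relevant = TRUE)
    n_irr <- stats::rpois(1, content_par$irrelevant_mean)
    if (n_irr > 0)
      ce <- c(ce, lapply(paste0("intrusion_", seq_len(n_irr)),
                         content_mention, relevant = FALSE))
  }
  speech_sample(task, utts, ce)
}

#' Generate one synthetic participant
#'
#' Draws a full annotated transcript (three conversational questions, the
#' Cookie Theft description, eight comprehension responses) and the matching
#' participant record from one group profile.  Uses the current R RNG
#' stream; seed outside (or via [generate_cohort()]) for reproducibility.
#'
#' @param profile One group profile from [default_profiles()].
#' @param participant_id Identifier for the transcript and record.
#' @param group Group label for the record.
#' @param inventory Content-element inventory.
#' @return List with elements `transcript` ([transcript()]) and `record`
#'   ([participant_record()]).
#' @export
generate_participant <- function(profile, participant_id, group,
                                 inventory = content_element_inventory()) {
  severity <- stats::rnorm(1)
  sp <- profile$speech

  samples <- lapply(TASKS, generate_sample, sp = sp, severity = severity,
                    inventory = inventory, content_par = profile$content)

  cm <- profile$comprehension
  comp <- list()
  for (mod in MODALITIES) {
    p0 <- if (mod == "verbal") cm$p_verbal else cm$p_written
    p <- stats::plogis(stats::qlogis(p0) - cm$severity * severity)
    for (cid in 1:4)
      comp[[length(comp) + 1L]] <-
        comprehension_response(mod, cid, stats::rbinom(1, 1, p) == 1)
  }

  cv <- profile$covariates
  draw <- function(mean, sd, sev_coef, lo, hi, sign = 1)
    clamp(round(mean + sign * sev_coef * severity + stats::rnorm(1, 0, sd)),
          lo, hi)
  rass_mag <- max(0, round(cv$rass_mag_mean + cv$rass_mag_severity * severity +
                             stats::rnorm(1, 0, cv$rass_mag_sd)))
  rass <- clamp(if (stats::rbinom(1, 1, cv$rass_p_negative) == 1)
    -rass_mag else rass_mag, -5, 4)
  record <- participant_record(
    participant_id, group,
    age = clamp(round(stats::rnorm(1, cv$age_mean, cv$age_sd)), 65, 97),
    sex = if (stats::rbinom(1, 1, cv$p_female) == 1) "female" else "male",
    omct = draw(cv$omct_mean, cv$omct_sd, cv$omct_severity, 0, 28, -1),
    bat = draw(cv$bat_mean, cv$bat_sd, cv$bat_severity, 0, 7, -1),
    drs_r98 = draw(cv$drs_r98_mean, cv$drs_r98_sd, cv$drs_r98_severity,
                   0, 39, 1),
    osla = draw(cv$osla_mean, cv$osla_sd, cv$osla_severity, 0, 15, 1),
    rass = rass,
    pain = clamp(round(stats::rnorm(1, cv$pain_mean, cv$pain_sd)), 0, 10))

  list(transcript = transcript(participant_id, samples, comp),
       record = record)
}

#' Simulation configuration
#'
#' @param n_per_group Participants per clinical group (>= 2).
#' @param seed Integer seed; `NULL` to use the current RNG state.
#' @param profiles Group profiles ([default_profiles()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 15, seed = NULL,
                       profiles = default_profiles()) {
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop("n_per_group must be >= 2", call. = FALSE)
  if (!setequal(names(profiles), GROUPS))
    stop("profiles must cover exactly the groups ",
         paste(GROUPS, collapse = ", "), call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), seed = seed,
                 profiles = profiles),
            class = "sim_config")
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_group` participants per clinical group from the configured
#' profiles and scores every transcript with [score_panel()], so the
#' returned table is by construction the score table of the returned
#' transcripts.  Fully deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()] (or list with the same fields).
#' @param inventory Content-element inventory used for generation and
#'   scoring.
#' @return List with `transcripts` (list of [transcript()]), `records`
#'   (list of [participant_record()]) and `scores` (score-table data frame,
#'   one row per participant).
#' @export
generate_cohort <- function(config = sim_config(),
                            inventory = content_element_inventory()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  transcripts <- list(); records <- list(); rows <- list()
  for (g in GROUPS) {
    for (i in seq_len(config$n_per_group)) {
      pid <- sprintf("%s_%02d", substr(g, 1, 3), i)
      part <- generate_participant(config$profiles[[g]], pid, g, inventory)
      transcripts[[pid]] <- part$transcript
      records[[pid]] <- part$record
      panel <- score_panel(part$transcript, inventory = inventory)
      rec <- part$record
      rows[[pid]] <- data.frame(
        participant_id = pid, group = g, age = rec$age, sex = rec$sex,
        omct = rec$omct, bat = rec$bat, drs_r98 = rec$drs_r98,
        osla = rec$osla, rass = rec$rass, pain = rec$pain,
        wab_score = panel$wab_score, ct_words = panel$ct_words,
        ct_utterances = panel$ct_utterances,
        ct_mean_utt_len = panel$ct_mean_utt_len,
        ct_content = panel$ct_content, ct_fluency = panel$ct_fluency,
        ct_grammar = panel$ct_grammar, ct_semantic = panel$ct_semantic,
        verbal_comp = panel$verbal_comp, written_comp = panel$written_comp)
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(transcripts = transcripts, records = records, scores = scores)
}

#' Write a generated cohort to disk
#'
#' Writes one transcript JSON per participant, the score table as
#' `cohort.csv`, and a `profiles.yaml` snapshot of the generative
#' parameters used.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param profiles Profiles to snapshot alongside the data.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, profiles = default_profiles()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in cohort$transcripts)
    write_transcript(t, file.path(dir, paste0(t$participant_id, ".json")))
  write_score_table(cohort$scores, file.path(dir, "cohort.csv"))
  yaml::write_yaml(profiles, file.path(dir, "profiles.yaml"))
  invisible(dir)
}
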