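# Fixture builders and independent flat-count oracles used across tests.

# tokens with exact annotation counts, positions deterministic
tokens_with <- function(n, filler = 0, repetition = 0, grammar = 0,
                        paraphasia = 0) {
  ann <- rep(list(character()), n)
  idx <- seq_len(n)
  assign_ann <- function(ann, k, label) {
    free <- which(lengths(ann) == 0)
    for (i in head(free, k)) ann[[i]] <- c(ann[[i]], label)
    ann
  }
  ann <- assign_ann(ann, filler, "filler")
  ann <- assign_ann(ann, repetition, "repetition")
  ann <- assign_ann(ann, grammar, "grammar_error")
  ann <- assign_ann(ann, paraphasia, "semantic_paraphasia")
  lapply(idx, function(i)
    token(if ("filler" %in% ann[[i]]) "erm" else paste0("word", i),
          ann[[i]]))
}

# a cookie-theft sample with exact word/utterance/annotation counts
make_ct_sample <- function(words_per_utt, filler = 0, repetition = 0,
                           grammar = 0, paraphasia = 0,
                           repair_utts = 0, relevant_elems = character(),
                           irrelevant_elems = character()) {
  toks <- tokens_with(sum(words_per_utt), filler, repetition, grammar,
                      paraphasia)
  start <- cumsum(c(1, head(words_per_utt, -1)))
  utts <- lapply(seq_along(words_per_utt), function(j)
    utterance(toks[start[j]:(start[j] + words_per_utt[j] - 1)],
              repair_flag = j <= repair_utts))
  ce <- c(lapply(relevant_elems, content_mention, relevant = TRUE),
          lapply(irrelevant_elems, content_mention, relevant = FALSE))
  speech_sample("cookie_theft", utts, ce)
}

# conversational sample from a relevance pattern, 1 token per utterance
make_conv_sample <- function(task, relevance) {
  utts <- lapply(relevance, function(r)
    utterance(list(token("word")), relevance = r))
  speech_sample(task, utts)
}

# full transcript: per-question relevance patterns + comprehension outcomes
make_transcript <- function(id = "p1",
                            q1 = c("relevant"), q2 = c("relevant"),
                            q3 = c("relevant"),
                            ct = make_ct_sample(c(3, 2)),
                            verbal_correct = rep(TRUE, 4),
                            written_correct = rep(TRUE, 4)) {
  samples <- list(make_conv_sample("conv_q1", q1),
                  make_conv_sample("conv_q2", q2),
                  make_conv_sample("conv_q3", q3))
  if (!is.null(ct)) samples <- c(samples, list(ct))
  comp <- c(
    lapply(seq_along(verbal_correct), function(i)
      comprehension_response("verbal", i, verbal_correct[i])),
    lapply(seq_along(written_correct), function(i)
      comprehension_response("written", i, written_correct[i])))
  transcript(id, samples, comp)
}

# random annotated sample for property/oracle tests (independent of the
# cohort generator's observation model)
random_sample <- function(task = "cookie_theft", max_utts = 8,
                          allow_empty_utt = TRUE) {
  n_utt <- sample.int(max_utts, 1)
  utts <- lapply(seq_len(n_utt), function(j) {
    n_tok <- if (allow_empty_utt) sample(0:6, 1) else sample.int(6, 1)
    toks <- lapply(seq_len(n_tok), function(i) {
      ann <- ANNS[runif(5) < 0.15]
      token(paste0("w", i), ann)
    })
    utterance(toks,
              relevance = sample(c("relevant", "irrelevant"), 1),
              repetition_of_utterance = runif(1) < 0.1,
              repair_flag = runif(1) < 0.1)
  })
  speech_sample(task, utts)
}
ANNS <- c("filler", "repetition", "repair", "grammar_error",
          "semantic_paraphasia")

# ---- independent flat-count oracles --------------------------------------
# These enumerate the raw structure directly rather than calling the
# scoring module's counting helpers.

flat_annotations <- function(s)
  unlist(lapply(s$utterances, function(u)
    lapply(u$tokens, function(tk) tk$annotations)))

oracle_word_count <- function(s)
  length(unlist(lapply(s$utterances, function(u)
    lapply(u$tokens, `[[`, "text"))))

oracle_fluency <- function(s) {
  w <- oracle_word_count(s)
  if (w == 0) return(NA_real_)
  ann <- flat_annotations(s)
  flags <- sum(vapply(s$utterances, function(u)
    u$repetition_of_utterance + u$repair_flag, 0))
  100 * (sum(ann %in% c("filler", "repetition", "repair")) + flags) / w
}

oracle_rate <- function(s, label) {
  w <- oracle_word_count(s)
  if (w == 0) return(NA_real_)
  100 * sum(flat_annotations(s) == label) / w
}

oracle_relevance_pct <- function(utts) {
  if (!length(utts)) return(NA_real_)
  rel <- vapply(utts, function(u) u$relevance, "")
  100 * mean(rel == "relevant")
}

# ---- exact permutation oracle for the Mann-Whitney U test ----------------
# Enumerates every assignment of the pooled values to the two groups and
# returns min(U1, U2) plus the exact two-sided permutation p based on the
# distance of U1 from its null mean.
mwu_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u1_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u1_of(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  all_u1 <- apply(utils::combn(n, n1), 2, u1_of)
  p <- mean(abs(all_u1 - mid) >= abs(obs - mid) - 1e-9)
  # probability mass sitting exactly on the rejection boundary: the lattice
  # resolution limiting how closely any continuous approximation can track p
  atom <- mean(abs(abs(all_u1 - mid) - abs(obs - mid)) < 1e-9)
  list(u = min(obs, n1 * (n - n1) - obs), p = p, atom = atom)
}

# ---- O(n^2) pair-counting oracle for Kendall's tau-b ---------------------
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# degenerate profile: no disfluencies, perfect relevance and comprehension
perfect_profile <- function() {
  p <- default_profiles()[["control"]]
  p$speech$p_relevant_utterance <- 1
  p$speech$filler_rate <- 0
  p$speech$word_repetition_rate <- 0
  p$speech$grammar_error_rate <- 0
  p$speech$paraphasia_rate <- 0
  p$speech$repair_rate_utt <- 0
  p$speech$repetition_rate_utt <- 0
  p$comprehension$p_verbal <- 1
  p$comprehension$p_written <- 1
  p
}
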