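test_that("question relevance percentage and rubric behave as specified", {
  u3 <- list(utterance(list(token("a")), "relevant"),
             utterance(list(token("b")), "relevant"),
             utterance(list(token("c")), "irrelevant"))
  expect_equal(question_relevance_pct(u3), 200 / 3, tolerance = 1e-12)
  all_rel <- lapply(1:4, function(i) utterance(list(token("x")), "relevant"))
  expect_equal(question_relevance_pct(all_rel), 100)
  expect_true(is.na(question_relevance_pct(list())))

  expect_identical(question_score(100), 3L)
  expect_identical(question_score(99.9), 2L)
  expect_identical(question_score(66.67), 2L)
  expect_identical(question_score(50.1), 2L)
  expect_identical(question_score(50), 1L)
  expect_identical(question_score(0), 1L)
  expect_identical(question_score(NA), 0L)   # mute question
  expect_error(question_score(101), "outside")
  expect_error(question_score(-1), "outside")

  set.seed(5)
  for (rep in 1:50) {
    s <- random_sample("conv_q1")
    expect_equal(question_relevance_pct(s$utterances),
                 oracle_relevance_pct(s$utterances))
  }
})

test_that("conversational score spans 0-9 and handles mute/missing questions", {
  expect_identical(conversational_score(make_transcript()), 9L)

  half <- c("relevant", "irrelevant")   # 50% -> score 1 per question
  expect_identical(
    conversational_score(make_transcript(q1 = half, q2 = half, q3 = half)),
    3L)

  mute <- transcript("p_mute", list(
    speech_sample("conv_q1"), speech_sample("conv_q2"),
    speech_sample("conv_q3")))
  expect_identical(conversational_score(mute), 0L)

  # missing question: computed over the present ones, panel incomplete
  partial <- transcript("p_partial", list(
    make_conv_sample("conv_q1", "relevant"),
    make_conv_sample("conv_q2", "relevant")))
  expect_identical(conversational_score(partial), 6L)
  expect_false(score_panel(partial)$complete)
})

test_that("content score is relevant minus irrelevant, deduped on inventory labels", {
  s <- make_ct_sample(c(3), relevant_elems = c("boy", "girl", "woman",
                                               "cookie", "jar"),
                      irrelevant_elems = c("dog", "spaceship"))
  expect_identical(content_score(s), 3L)
  expect_identical(content_score(speech_sample("cookie_theft",
                                               list(utterance(list(token("a")))))),
                   0L)
  neg <- make_ct_sample(c(2), irrelevant_elems = paste0("x", 1:4))
  expect_identical(content_score(neg), -4L)

  # duplicate relevant mentions count once; irrelevant per occurrence
  dup <- make_ct_sample(c(2), relevant_elems = c("boy", "boy", "stool"),
                        irrelevant_elems = c("dog", "dog"))
  expect_identical(content_score(dup), 0L)
  expect_identical(content_score(dup, dedupe_relevant = FALSE), 1L)

  expect_error(content_score(make_conv_sample("conv_q1", "relevant")),
               "cookie_theft")
  bad <- make_ct_sample(c(2), relevant_elems = "flying_saucer")
  expect_error(content_score(bad), "not in inventory")

  # adding an unseen relevant element increases the score by exactly 1
  s2 <- make_ct_sample(c(3), relevant_elems = c("boy", "girl", "woman",
                                                "cookie", "jar", "stool"),
                       irrelevant_elems = c("dog", "spaceship"))
  expect_identical(content_score(s2), content_score(s) + 1L)
})

test_that("fluency, grammar and semantic rates match their formulas", {
  # 50 words: 2 word repetitions + 3 fillers + 0 repairs -> 10%
  s <- make_ct_sample(c(25, 25), filler = 3, repetition = 2)
  expect_equal(fluency_score(s), 10.0)

  clean <- make_ct_sample(c(10, 10))
  expect_equal(fluency_score(clean), 0.0)
  expect_equal(grammar_score(clean), 0.0)
  expect_equal(semantic_error_score(clean), 0.0)

  expect_equal(grammar_score(make_ct_sample(c(20, 20), grammar = 2)), 5.0)
  expect_equal(semantic_error_score(make_ct_sample(c(25), paraphasia = 1)),
               4.0)

  # whole-utterance repetition and repair flags add one event each
  s_flag <- make_ct_sample(c(10, 10), repair_utts = 1)
  su <- s_flag$utterances
  su[[2]] <- utterance(su[[2]]$tokens, repetition_of_utterance = TRUE)
  s_flag <- speech_sample("cookie_theft", su)
  expect_equal(fluency_score(s_flag), 100 * 2 / 20)

  # zero words: undefined marker, never 0
  wordless <- speech_sample("cookie_theft", list(utterance(list())))
  expect_true(is.na(fluency_score(wordless)))
  expect_true(is.na(grammar_score(wordless)))
  expect_true(is.na(semantic_error_score(wordless)))
})

test_that("mean utterance length is words per utterance", {
  # 42 words over 10 utterances -> 4.2
  s <- make_ct_sample(c(rep(4, 8), 5, 5))
  expect_equal(mean_utterance_length(s), 4.2)
  expect_equal(mean_utterance_length(make_ct_sample(c(8))), 8.0)
  expect_true(is.na(mean_utterance_length(speech_sample("cookie_theft"))))
})

test_that("comprehension scoring counts correct responses out of four", {
  t <- make_transcript()
  expect_identical(as.integer(comprehension_score(t$comprehension, "verbal")),
                   4L)
  t0 <- make_transcript(verbal_correct = rep(FALSE, 4))
  expect_identical(as.integer(comprehension_score(t0$comprehension, "verbal")),
                   0L)

  # 2 of 3 recorded correct -> 2, flagged incomplete
  partial <- make_transcript(written_correct = c(TRUE, TRUE, FALSE))
  wc <- comprehension_score(partial$comprehension, "written")
  expect_identical(as.integer(wc), 2L)
  expect_identical(attr(wc, "n_administered"), 3L)
  expect_false(score_panel(partial)$complete)
})

test_that("score_panel equals the individually-called operations", {
  t <- make_transcript(
    q1 = c("relevant", "relevant"), q2 = c("relevant", "irrelevant"),
    q3 = "relevant",
    ct = make_ct_sample(c(6, 5, 4), filler = 2, grammar = 1, paraphasia = 1,
                        repair_utts = 1,
                        relevant_elems = c("boy", "sink", "stool"),
                        irrelevant_elems = "dragon"),
    written_correct = c(TRUE, TRUE, TRUE, FALSE))
  p <- score_panel(t)
  ct <- t$samples[[4]]
  expect_identical(p$wab_score, conversational_score(t))
  expect_identical(p$ct_words, word_count(ct))
  expect_identical(p$ct_utterances, utterance_count(ct))
  expect_equal(p$ct_mean_utt_len, mean_utterance_length(ct))
  expect_identical(p$ct_content, content_score(ct))
  expect_equal(p$ct_fluency, fluency_score(ct))
  expect_equal(p$ct_grammar, grammar_score(ct))
  expect_equal(p$ct_semantic, semantic_error_score(ct))
  expect_identical(p$verbal_comp, 4L)
  expect_identical(p$written_comp, 3L)
  expect_true(p$complete)

  empty <- score_panel(transcript("nobody"))
  expect_false(empty$complete)
  expect_identical(empty$wab_score, 0L)
  expect_true(is.na(empty$ct_mean_utt_len))
  expect_identical(empty$verbal_comp, 0L)
})

test_that("scores are invariant to utterance order and monotone in relevance", {
  set.seed(33)
  for (rep in 1:25) {
    s <- random_sample()
    perm <- speech_sample(s$task, sample(s$utterances), s$content_elements)
    expect_equal(fluency_score(s), fluency_score(perm))
    expect_equal(grammar_score(s), grammar_score(perm))
    expect_equal(semantic_error_score(s), semantic_error_score(perm))
    expect_equal(mean_utterance_length(s), mean_utterance_length(perm))

    # adding an irrelevant utterance never increases relevance pct
    conv <- random_sample("conv_q1")
    before <- question_relevance_pct(conv$utterances)
    more <- c(conv$utterances,
              list(utterance(list(token("x")), "irrelevant")))
    if (!is.na(before))
      expect_lte(question_relevance_pct(more), before)
  }
})
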