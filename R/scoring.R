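# Language assessment scoring battery.
#
# Conversational speech: three questions adapted from the Western Aphasia
# Battery-Revised, scored 1-3 each from the percentage of relevant utterances
# (0 for a mute question), total 0-9.  Cookie Theft picture description:
# content elements, fluency, grammar and semantic-error rates, and mean
# utterance length.  Comprehension: one point per correctly performed
# command, four per modality.
#
# Division-by-zero cases (no words, no utterances) yield NA_real_, an
# explicit "undefined" marker that the stats module treats as missing --
# never as 0, which would silently inflate group differences.

#' Percentage of relevant utterances for a conversational question
#'
#' @param utterances List of [utterance()] objects for one question.
#' @return `100 * relevant / total`, or `NA_real_` for an empty list (a mute
#'   question, which [question_score()] maps to 0).
#' @export
#' @examples
#' u <- list(utterance(list(token("fine")), "relevant"),
#'           utterance(list(token("pardon")), "irrelevant"))
#' question_relevance_pct(u)  # 50
question_relevance_pct <- function(utterances) {
  if (!is.list(utterances) ||
      !all(vapply(utterances, inherits, TRUE, "utterance")))
    stop("expected a list of utterance() objects", call. = FALSE)
  if (!length(utterances)) return(NA_real_)
  rel <- vapply(utterances, function(u) u$relevance == "relevant", TRUE)
  100 * sum(rel) / length(rel)
}

#' Score one conversational question from its relevance percentage
#'
#' Rubric: 3 when 100% of utterances are relevant, 2 for 51--99%, 1 for
#' 0--50%.  A mute question (no utterances, `pct = NA`) scores 0, which is
#' what makes the printed 0--9 total attainable.
#'
#' @param pct Percentage in \[0, 100\], or `NA` for a mute question.
#' @return Integer 0--3.
#' @export
question_score <- function(pct) {
  if (length(pct) != 1L) stop("pct must be a scalar", call. = FALSE)
  if (is.na(pct)) return(0L)
  if (pct < 0 || pct > 100)
    stop("relevance percentage outside [0, 100]: ", pct, call. = FALSE)
  if (pct >= 100) 3L else if (pct > 50) 2L else 1L
}

#' Total conversational speech score (0--9)
#'
#' Sum of the per-question scores over the three conversational questions.
#' Higher scores indicate more relevant speech content.  A missing question
#' sample contributes nothing and marks the participant's panel incomplete
#' (see [score_panel()]); a present-but-mute question contributes 0.
#'
#' @param t A [transcript()].
#' @return Integer 0--9.
#' @export
conversational_score <- function(t) {
  stopifnot(inherits(t, "transcript"))
  total <- 0L
  for (task in CONV_TASKS) {
    s <- get_sample(t, task)
    if (is.null(s)) next
    total <- total + question_score(question_relevance_pct(s$utterances))
  }
  total
}

#' Cookie Theft content score
#'
#' Number of relevant content elements minus number of irrelevant content
#' elements.  Repeated mentions of the same inventory element count once
#' (the picture either contains the element or it does not); irrelevant
#' mentions count per occurrence.  The score may be negative.
#'
#' @param s A `cookie_theft` [speech_sample()].
#' @param inventory Character vector of canonical content-element labels;
#'   default is the shipped Cookie Theft inventory
#'   ([content_element_inventory()]).  Relevant mentions must use inventory
#'   labels.
#' @param dedupe_relevant Count duplicate relevant mentions once?
#' @return Integer (possibly negative).
#' @export
content_score <- function(s, inventory = content_element_inventory(),
                          dedupe_relevant = TRUE) {
  stopifnot(inherits(s, "speech_sample"))
  if (s$task != "cookie_theft")
    stop("content_score applies to the cookie_theft sample only",
         call. = FALSE)
  rel <- vapply(s$content_elements, `[[`, TRUE, "relevant")
  labels <- vapply(s$content_elements, `[[`, "", "label")
  bad <- setdiff(labels[rel], inventory)
  if (length(bad))
    stop("relevant content element(s) not in inventory: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n_rel <- if (dedupe_relevant) length(unique(labels[rel])) else sum(rel)
  n_rel - sum(!rel)
}

# disfluency events: word-level repetition annotations (1 per token) +
# whole-utterance repetition flags (1 per utterance) + fillers +
# repairs (utterance repair flags and repair-annotated tokens)
fluency_events <- function(s) {
  ev <- count_annotation(s, "repetition") + count_annotation(s, "filler") +
    count_annotation(s, "repair")
  for (u in s$utterances) {
    if (u$repetition_of_utterance) ev <- ev + 1L
    if (u$repair_flag) ev <- ev + 1L
  }
  ev
}

#' Cookie Theft fluency score
#'
#' `100 * (word/utterance repetitions + filler items + utterance repairs) /
#' total words produced`.  Higher values mean more disfluent speech.
#'
#' @param s A `cookie_theft` [speech_sample()].
#' @return Percentage (>= 0), or `NA_real_` when the sample contains no
#'   words (undefined, panel flagged incomplete).
#' @export
fluency_score <- function(s) {
  stopifnot(inherits(s, "speech_sample"))
  if (s$task != "cookie_theft")
    stop("fluency_score applies to the cookie_theft sample only",
         call. = FALSE)
  w <- word_count(s)
  if (w == 0L) return(NA_real_)
  100 * fluency_events(s) / w
}

#' Cookie Theft grammar score
#'
#' `100 * incorrect tenses and ambiguous articles / total words`.  Ambiguous
#' articles are uses of "that", "this", "it" etc. where no object or person
#' is named; the rater marks the offending token with the `grammar_error`
#' annotation.
#'
#' @inheritParams fluency_score
#' @return Percentage, or `NA_real_` for a wordless sample.
#' @export
grammar_score <- function(s) {
  stopifnot(inherits(s, "speech_sample"))
  if (s$task != "cookie_theft")
    stop("grammar_score applies to the cookie_theft sample only",
         call. = FALSE)
  w <- word_count(s)
  if (w == 0L) return(NA_real_)
  100 * count_annotation(s, "grammar_error") / w
}

#' Cookie Theft semantic-error score
#'
#' `100 * semantic paraphasias / total words`.  A semantic paraphasia is the
#' substitution of a related or unrelated word for the intended one (e.g.
#' "chair" for "stool"), marked on the token by the rater.
#'
#' @inheritParams fluency_score
#' @return Percentage, or `NA_real_` for a wordless sample.
#' @export
semantic_error_score <- function(s) {
  stopifnot(inherits(s, "speech_sample"))
  if (s$task != "cookie_theft")
    stop("semantic_error_score applies to the cookie_theft sample only",
         call. = FALSE)
  w <- word_count(s)
  if (w == 0L) return(NA_real_)
  100 * count_annotation(s, "semantic_paraphasia") / w
}

#' Mean utterance length (words per utterance)
#'
#' Total words divided by total utterances -- the headline language
#' productivity measure.
#'
#' @param s A [speech_sample()].
#' @return Words/utterance, or `NA_real_` when the sample has no utterances.
#' @export
mean_utterance_length <- function(s) {
  stopifnot(inherits(s, "speech_sample"))
  n_utt <- utterance_count(s)
  if (n_utt == 0L) return(NA_real_)
  word_count(s) / n_utt
}

#' Comprehension score for one modality
#'
#' One point per command performed correctly, out of the four commands in
#' the modality.  Missing responses are treated as not administered: the
#' score is the count of correct responses among those recorded, and the
#' panel is flagged incomplete when fewer than four were recorded.
#'
#' @param responses List of [comprehension_response()] objects (both
#'   modalities may be mixed; the function filters).
#' @param modality `"verbal"` or `"written"`.
#' @return Integer 0--4 with attribute `n_administered`.
#' @export
comprehension_score <- function(responses, modality) {
  modality <- match.arg(modality, MODALITIES)
  if (!is.list(responses) ||
      !all(vapply(responses, inherits, TRUE, "comprehension_response")))
    stop("expected a list of comprehension_response() objects", call. = FALSE)
  sel <- Filter(function(r) r$modality == modality, responses)
  if (length(sel) > 4L)
    stop("more than 4 ", modality, " responses", call. = FALSE)
  score <- sum(vapply(sel, `[[`, TRUE, "correct"))
  structure(as.integer(score), n_administered = length(sel))
}

#' Score a full participant panel
#'
#' Computes every language variable for one participant: the conversational
#' (WAB-adapted) score, the Cookie Theft measures, and verbal/written
#' comprehension.  `complete` is `TRUE` only when all three conversational
#' questions, the Cookie Theft sample and all eight comprehension commands
#' are present and every Cookie Theft rate is defined.
#'
#' @param t A [transcript()].
#' @param inventory Content-element inventory passed to [content_score()].
#' @return A `score_panel` object: a list with elements `participant_id`,
#'   `wab_score`, `ct_words`, `ct_utterances`, `ct_mean_utt_len`,
#'   `ct_content`, `ct_fluency`, `ct_grammar`, `ct_semantic`,
#'   `verbal_comp`, `written_comp`, `complete`.
#' @export
score_panel <- function(t, inventory = content_element_inventory()) {
  stopifnot(inherits(t, "transcript"))
  complete <- TRUE
  for (task in CONV_TASKS)
    if (is.null(get_sample(t, task))) complete <- FALSE

  ct <- get_sample(t, "cookie_theft")
  if (is.null(ct)) {
    complete <- FALSE
    ct_words <- NA_integer_; ct_utts <- NA_integer_
    mul <- NA_real_; cont <- NA_integer_
    flu <- NA_real_; gra <- NA_real_; sem <- NA_real_
  } else {
    ct_words <- word_count(ct)
    ct_utts <- utterance_count(ct)
    mul <- mean_utterance_length(ct)
    cont <- content_score(ct, inventory = inventory)
    flu <- fluency_score(ct)
    gra <- grammar_score(ct)
    sem <- semantic_error_score(ct)
    if (anyNA(c(mul, flu, gra, sem))) complete <- FALSE
  }

  vc <- comprehension_score(t$comprehension, "verbal")
  wc <- comprehension_score(t$comprehension, "written")
  if (attr(vc, "n_administered") < 4L || attr(wc, "n_administered") < 4L)
    complete <- FALSE

  structure(list(
    participant_id = t$participant_id,
    wab_score = conversational_score(t),
    ct_words = ct_words,
    ct_utterances = ct_utts,
    ct_mean_utt_len = mul,
    ct_content = cont,
    ct_fluency = flu,
    ct_grammar = gra,
    ct_semantic = sem,
    verbal_comp = as.integer(vc),
    written_comp = as.integer(wc),
    complete = complete
  ), class = "score_panel")
}

#' The Cookie Theft content-element inventory
#'
#' The canonical list of picture elements against which relevant content
#' mentions are scored.  The default ships with the package
#' (`inst/extdata/cookie_theft_elements.txt`, one label per line); studies
#' using a different inventory supply their own file.
#'
#' @param path Optional path to an alternative inventory file.
#' @return Character vector of element labels.
#' @export
content_element_inventory <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cookie_theft_elements.txt",
                        package = "delirispeech", mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}
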