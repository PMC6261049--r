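# Annotated-transcript data model.
#
# A transcript holds one participant's speech samples (three conversational
# questions and the Cookie Theft picture description) plus their responses to
# four verbal and four written comprehension commands.  Utterance segmentation
# and all disfluency/error annotations are rater decisions recorded at
# transcription time; nothing here is inferred from raw text.

TASKS <- c("conv_q1", "conv_q2", "conv_q3", "cookie_theft")
CONV_TASKS <- c("conv_q1", "conv_q2", "conv_q3")
ANNOTATIONS <- c("filler", "repetition", "repair", "grammar_error",
                 "semantic_paraphasia")
MODALITIES <- c("verbal", "written")

#' Create an annotated token
#'
#' A token is a single transcribed word (or non-lexical filler such as
#' "erm") together with the disfluency/error annotations assigned to it by
#' the rater.
#'
#' @param text Token text; must be non-empty after trimming whitespace.
#' @param annotations Character vector drawn from `"filler"`, `"repetition"`,
#'   `"repair"`, `"grammar_error"`, `"semantic_paraphasia"`.  A token may
#'   carry several annotations.
#' @return A `speech_token` object.
#' @export
#' @examples
#' token("erm", "filler")
#' token("chair", "semantic_paraphasia")
token <- function(text, annotations = character()) {
  text <- as.character(text)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("token text must be a single non-empty string", call. = FALSE)
  annotations <- unique(as.character(annotations))
  bad <- setdiff(annotations, ANNOTATIONS)
  if (length(bad))
    stop("unknown token annotation(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(text = text, annotations = annotations),
            class = "speech_token")
}

#' Create an utterance
#'
#' An utterance is a unit of speech -- a fragmented or complete sentence
#' bounded by a significant pause, as segmented by the rater on the audio.
#' An empty token list records an utterance that was audible as speech but
#' could not be transcribed; it counts towards the utterance total but not
#' the word total.
#'
#' @param tokens List of [token()] objects (possibly empty).
#' @param relevance `"relevant"` or `"irrelevant"` -- whether the utterance
#'   addresses the question asked.
#' @param repetition_of_utterance Logical; `TRUE` when the whole utterance
#'   repeats an earlier one (counts as one disfluency event).
#' @param repair_flag Logical; `TRUE` when the utterance contains a
#'   self-correction ("utterance repair").
#' @return An `utterance` object.
#' @export
utterance <- function(tokens = list(), relevance = "relevant",
                      repetition_of_utterance = FALSE, repair_flag = FALSE) {
  if (!is.list(tokens) || !all(vapply(tokens, inherits, TRUE, "speech_token")))
    stop("tokens must be a list of token() objects", call. = FALSE)
  relevance <- match.arg(relevance, c("relevant", "irrelevant"))
  structure(list(tokens = tokens,
                 relevance = relevance,
                 repetition_of_utterance = isTRUE(repetition_of_utterance),
                 repair_flag = isTRUE(repair_flag)),
            class = "utterance")
}

#' Create a content-element mention
#'
#' Cookie Theft speech content is scored against an inventory of canonical
#' picture elements (boy, stool, overflowing sink, ...).  A relevant mention
#' names an inventory element; an irrelevant mention is free text not
#' depicted in the picture.
#'
#' @param label Element label (inventory label if `relevant`).
#' @param relevant Logical.
#' @return A `content_mention` object.
#' @export
content_mention <- function(label, relevant = TRUE) {
  label <- as.character(label)
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label)))
    stop("content element label must be a non-empty string", call. = FALSE)
  structure(list(label = label, relevant = isTRUE(relevant)),
            class = "content_mention")
}

#' Create a speech sample
#'
#' @param task One of `"conv_q1"`, `"conv_q2"`, `"conv_q3"` (the three
#'   conversational questions, e.g. "How are you feeling today?") or
#'   `"cookie_theft"` (picture description).
#' @param utterances List of [utterance()] objects, in spoken order.
#' @param content_elements List of [content_mention()] objects; only allowed
#'   for the Cookie Theft task.
#' @return A `speech_sample` object.
#' @export
speech_sample <- function(task, utterances = list(), content_elements = list()) {
  task <- match.arg(task, TASKS)
  if (!is.list(utterances) ||
      !all(vapply(utterances, inherits, TRUE, "utterance")))
    stop("utterances must be a list of utterance() objects", call. = FALSE)
  if (!is.list(content_elements) ||
      !all(vapply(content_elements, inherits, TRUE, "content_mention")))
    stop("content_elements must be a list of content_mention() objects",
         call. = FALSE)
  if (task != "cookie_theft" && length(content_elements))
    stop("content_elements are only recorded for the cookie_theft task",
         call. = FALSE)
  structure(list(task = task, utterances = utterances,
                 content_elements = content_elements),
            class = "speech_sample")
}

#' Create a comprehension response
#'
#' Four verbal and four written commands are administered; one point per
#' action performed correctly.  A command that was not administered is simply
#' absent from the transcript (recorded neither correct nor incorrect), and
#' the score panel is flagged incomplete.
#'
#' @param modality `"verbal"` or `"written"`.
#' @param command_id Integer 1..4 identifying the command within its modality.
#' @param correct Logical.
#' @return A `comprehension_response` object.
#' @export
comprehension_response <- function(modality, command_id, correct) {
  modality <- match.arg(modality, MODALITIES)
  command_id <- as.integer(command_id)
  if (is.na(command_id) || command_id < 1L || command_id > 4L)
    stop("command_id must be an integer in 1..4", call. = FALSE)
  structure(list(modality = modality, command_id = command_id,
                 correct = isTRUE(correct)),
            class = "comprehension_response")
}

#' Create a participant transcript
#'
#' @param participant_id Unique participant identifier.
#' @param samples List of [speech_sample()] objects, at most one per task.
#' @param comprehension List of [comprehension_response()] objects, at most
#'   one per (modality, command).
#' @return A `transcript` object.
#' @export
transcript <- function(participant_id, samples = list(),
                       comprehension = list()) {
  participant_id <- as.character(participant_id)
  if (length(participant_id) != 1L || !nzchar(participant_id))
    stop("participant_id must be a non-empty string", call. = FALSE)
  if (!is.list(samples) ||
      !all(vapply(samples, inherits, TRUE, "speech_sample")))
    stop("samples must be a list of speech_sample() objects", call. = FALSE)
  if (!is.list(comprehension) ||
      !all(vapply(comprehension, inherits, TRUE, "comprehension_response")))
    stop("comprehension must be a list of comprehension_response() objects",
         call. = FALSE)
  tasks <- vapply(samples, `[[`, "", "task")
  if (anyDuplicated(tasks))
    stop("duplicate task in transcript: ",
         paste(unique(tasks[duplicated(tasks)]), collapse = ", "),
         call. = FALSE)
  key <- vapply(comprehension,
                function(r) paste(r$modality, r$command_id), "")
  if (anyDuplicated(key))
    stop("duplicate comprehension command: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  structure(list(participant_id = participant_id, samples = samples,
                 comprehension = comprehension),
            class = "transcript")
}

#' Create a participant record
#'
#' Group label, demographics and the cognitive/arousal covariates from the
#' reference-standard assessment.  The instruments enter downstream analyses
#' only as numeric totals.
#'
#' @param participant_id Identifier matching the transcript.
#' @param group `"delirium"`, `"dementia"` or `"control"`.
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param omct Orientation-Memory-Concentration Test total, 0--28.
#' @param bat Brief Attention Task total, 0--7.
#' @param drs_r98 Delirium Rating Scale-Revised-98 severity score.
#' @param osla Observational Scale of Level of Arousal score.
#' @param rass Richmond Agitation-Sedation Scale, integer -5..+4.
#' @param pain Pain rating, 0--10.
#' @return A `participant_record` object (a one-row list).
#' @export
participant_record <- function(participant_id, group, age, sex,
                               omct = NA, bat = NA, drs_r98 = NA,
                               osla = NA, rass = NA, pain = NA) {
  group <- match.arg(group, c("delirium", "dementia", "control"))
  sex <- match.arg(sex, c("female", "male"))
  chk <- function(x, lo, hi, name) {
    if (!is.na(x) && (x < lo || x > hi))
      stop(name, " out of range [", lo, ", ", hi, "]: ", x, call. = FALSE)
    x
  }
  structure(list(participant_id = as.character(participant_id), group = group,
                 age = as.numeric(age), sex = sex,
                 omct = chk(as.numeric(omct), 0, 28, "omct"),
                 bat = chk(as.numeric(bat), 0, 7, "bat"),
                 drs_r98 = as.numeric(drs_r98),
                 osla = as.numeric(osla),
                 rass = chk(as.numeric(rass), -5, 4, "rass"),
                 pain = chk(as.numeric(pain), 0, 10, "pain")),
            class = "participant_record")
}

# ---------------------------------------------------------------------------
# JSON serialisation

#' Parse a transcript file
#'
#' Reads the UTF-8 JSON transcript format (one participant per file; see the
#' schema shipped at `system.file("extdata", "transcript-schema.json",
#' package = "delirispeech")`).  All annotations are preserved losslessly and
#' every structural invariant is re-validated, so a parsed transcript is
#' always safe to score.
#'
#' @param path Path to a transcript JSON file.
#' @return A [transcript()] object.
#' @seealso [write_transcript()]
#' @export
parse_transcript <- function(path) {
  if (!file.exists(path))
    stop("transcript file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("transcript parse error in ", basename(path),
           ": missing field '", field, "' in ", where, call. = FALSE)
    x[[field]]
  }
  pid <- need(raw, "participant_id", "top level")
  samples <- lapply(raw$samples, function(s) {
    task <- need(s, "task", "sample")
    utts <- lapply(s$utterances, function(u) {
      toks <- lapply(u$tokens, function(tk)
        token(need(tk, "text", "token"),
              as.character(unlist(tk$annotations))))
      utterance(toks,
                relevance = need(u, "relevance", "utterance"),
                repetition_of_utterance = isTRUE(u$repetition_of_utterance),
                repair_flag = isTRUE(u$repair_flag))
    })
    ce <- lapply(s$content_elements, function(m)
      content_mention(need(m, "label", "content element"),
                      relevant = isTRUE(m$relevant)))
    speech_sample(task, utts, ce)
  })
  comp <- lapply(raw$comprehension, function(r)
    comprehension_response(need(r, "modality", "comprehension response"),
                           need(r, "command_id", "comprehension response"),
                           isTRUE(r$correct)))
  transcript(pid, samples, comp)
}

transcript_to_list <- function(t) {
  list(
    participant_id = t$participant_id,
    samples = lapply(t$samples, function(s) list(
      task = s$task,
      utterances = lapply(s$utterances, function(u) list(
        tokens = lapply(u$tokens, function(tk) list(
          text = tk$text,
          annotations = as.list(tk$annotations))),
        relevance = u$relevance,
        repetition_of_utterance = u$repetition_of_utterance,
        repair_flag = u$repair_flag)),
      content_elements = lapply(s$content_elements, function(m) list(
        label = m$label, relevant = m$relevant)))),
    comprehension = lapply(t$comprehension, function(r) list(
      modality = r$modality, command_id = r$command_id, correct = r$correct))
  )
}

#' Write a transcript file
#'
#' Canonical serialisation: fixed key order, two-space indentation, UTF-8.
#' `write_transcript(parse_transcript(f), f2)` reproduces a canonicalised
#' file byte for byte, so transcripts survive round trips unchanged.
#'
#' @param t A [transcript()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(t, path) {
  stopifnot(inherits(t, "transcript"))
  json <- jsonlite::toJSON(transcript_to_list(t), auto_unbox = TRUE,
                           pretty = 2, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Basic counts (the denominators of every Table-2-style formula)

#' Count words in a speech sample
#'
#' The total number of words produced: the number of tokens summed over all
#' utterances.  Non-lexical fillers ("erm", "uhm") count as words by default
#' because the fluency formula divides disfluency events by total words and
#' no exclusion rule is part of the battery; set `include_fillers = FALSE`
#' to drop them.
#'
#' @param s A [speech_sample()].
#' @param include_fillers Count filler-annotated tokens as words?
#' @return Non-negative integer.
#' @export
word_count <- function(s, include_fillers = TRUE) {
  stopifnot(inherits(s, "speech_sample"))
  n <- 0L
  for (u in s$utterances) {
    if (include_fillers) {
      n <- n + length(u$tokens)
    } else {
      n <- n + sum(!vapply(u$tokens, function(tk)
        "filler" %in% tk$annotations, TRUE))
    }
  }
  n
}

#' Count utterances in a speech sample
#'
#' Includes recorded-but-inaudible utterances (those with no transcribed
#' tokens), which count as utterances but contribute no words.
#'
#' @param s A [speech_sample()].
#' @return Non-negative integer.
#' @export
utterance_count <- function(s) {
  stopifnot(inherits(s, "speech_sample"))
  length(s$utterances)
}

# annotation event counts over a sample, used by the scoring formulas
count_annotation <- function(s, which) {
  n <- 0L
  for (u in s$utterances)
    for (tk in u$tokens)
      if (which %in% tk$annotations) n <- n + 1L
  n
}

get_sample <- function(t, task) {
  for (s in t$samples) if (s$task == task) return(s)
  NULL
}
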