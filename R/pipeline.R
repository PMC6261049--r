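# End-to-end orchestration: directory scoring, report rendering, inter-rater
# agreement over a ratings table.  These functions back the thin command-line
# wrapper shipped at inst/cli/delirispeech.R.

#' Score a directory of transcript files
#'
#' Parses every `*.json` transcript in `dir` and computes the full score
#' panel per participant.  Parse or validation failures are collected (and
#' reported as warnings) without aborting the run, so one corrupt file does
#' not discard a cohort.  Group/covariate columns are filled from `records`
#' when supplied, otherwise left missing.
#'
#' @param dir Directory containing transcript JSON files.
#' @param records Optional data frame (or CSV path) with
#'   `participant_id, group, age, sex, omct, bat, drs_r98, osla, rass, pain`.
#' @param inventory Content-element inventory for scoring.
#' @return List with `scores` (score-table data frame), `failures` (named
#'   character vector of error messages per failed file).
#' @export
score_transcript_dir <- function(dir, records = NULL,
                                 inventory = content_element_inventory()) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files))
    warning("no transcript files found in ", dir, call. = FALSE)
  if (is.character(records)) records <- utils::read.csv(records)
  rows <- list(); failures <- character()
  for (f in files) {
    panel <- tryCatch({
      t <- parse_transcript(f)
      score_panel(t, inventory = inventory)
    }, error = function(e) e)
    if (inherits(panel, "error")) {
      failures[basename(f)] <- conditionMessage(panel)
      warning("failed to score ", basename(f), ": ",
              conditionMessage(panel), call. = FALSE)
      next
    }
    row <- data.frame(
      participant_id = panel$participant_id, group = NA_character_,
      age = NA_real_, sex = NA_character_, omct = NA_real_, bat = NA_real_,
      drs_r98 = NA_real_, osla = NA_real_, rass = NA_real_, pain = NA_real_,
      wab_score = panel$wab_score, ct_words = panel$ct_words,
      ct_utterances = panel$ct_utterances,
      ct_mean_utt_len = panel$ct_mean_utt_len,
      ct_content = panel$ct_content, ct_fluency = panel$ct_fluency,
      ct_grammar = panel$ct_grammar, ct_semantic = panel$ct_semantic,
      verbal_comp = panel$verbal_comp, written_comp = panel$written_comp)
    if (!is.null(records)) {
      m <- match(panel$participant_id, records$participant_id)
      if (!is.na(m))
        for (col in intersect(names(records), SCORE_COLUMNS[1:10]))
          row[[col]] <- records[[col]][m]
    }
    rows[[length(rows) + 1L]] <- row
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(SCORE_COLUMNS))),
                    SCORE_COLUMNS)
  rownames(scores) <- NULL
  list(scores = scores, failures = failures)
}

#' Write a comparison report to disk
#'
#' Renders a [compare_groups()] result as three CSVs (`summaries.csv`,
#' `omnibus.csv`, `pairwise.csv`) plus a human-readable
#' `comparison.txt` laid out as per-variable group medians (IQR), the
#' omnibus H, and the pairwise U/p/r with significance marks.
#'
#' @param report A `comparison_report` from [compare_groups()].
#' @param dir Output directory.
#' @param age_table Optional [age_regression_table()] result, written as
#'   `age_regression.csv`.
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir, age_table = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$omnibus, file.path(dir, "omnibus.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairwise, file.path(dir, "pairwise.csv"),
                   row.names = FALSE)
  if (!is.null(age_table))
    utils::write.csv(age_table, file.path(dir, "age_regression.csv"),
                     row.names = FALSE)
  con <- file(file.path(dir, "comparison.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}

#' Write a correlation report to disk
#'
#' @param cor_table Result of [correlate_scores()].
#' @param dir Output directory (writes `correlations.csv`).
#' @return `dir`, invisibly.
#' @export
write_correlation_report <- function(cor_table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cor_table, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Inter-rater agreement report over a ratings CSV
#'
#' The ratings file has one row per subject and one column per rater for
#' each scored variable, named `<variable>_<rater>` (e.g.
#' `ct_content_r1, ct_content_r2`).  For each variable with >= 2 rater
#' columns the two-way random-effects absolute-agreement single-rater ICC
#' is computed.
#'
#' @param ratings Data frame or CSV path.
#' @return Data frame: variable, raters, subjects, icc.
#' @export
icc_report <- function(ratings) {
  if (is.character(ratings)) ratings <- utils::read.csv(ratings)
  rater_cols <- grep("_r[0-9]+$", names(ratings), value = TRUE)
  if (!length(rater_cols))
    stop("no rater columns found (expected names like score_r1, score_r2)",
         call. = FALSE)
  vars <- unique(sub("_r[0-9]+$", "", rater_cols))
  rows <- lapply(vars, function(v) {
    cols <- grep(paste0("^", v, "_r[0-9]+$"), names(ratings), value = TRUE)
    if (length(cols) < 2L) return(NULL)
    res <- icc(ratings[, cols])
    data.frame(variable = v, raters = res$raters, subjects = res$subjects,
               icc = res$icc)
  })
  do.call(rbind, rows)
}
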