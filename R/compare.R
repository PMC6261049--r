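# Case-control comparison and correlation reports over a score table.
#
# The score table is one row per participant: group label, demographics,
# cognitive/arousal covariates and the language variables.  Comparisons
# follow the omnibus-then-pairwise flow: Kruskal-Wallis across the three
# groups, then Mann-Whitney U for each pair, with Cohen's r for the pairwise
# contrasts and significance flagged at alpha (default 0.01, two-sided).

GROUPS <- c("delirium", "dementia", "control")

SCORE_COLUMNS <- c("participant_id", "group", "age", "sex", "omct", "bat",
                   "drs_r98", "osla", "rass", "pain", "wab_score",
                   "ct_words", "ct_utterances", "ct_mean_utt_len",
                   "ct_content", "ct_fluency", "ct_grammar", "ct_semantic",
                   "verbal_comp", "written_comp")

LANGUAGE_VARS <- c("wab_score", "ct_mean_utt_len", "ct_content",
                   "ct_fluency", "ct_grammar", "ct_semantic",
                   "verbal_comp", "written_comp")

#' Read a per-participant score table
#'
#' Reads the score-table CSV (columns `participant_id, group, age, sex,
#' omct, bat, drs_r98, osla, rass, pain, wab_score, ct_words,
#' ct_utterances, ct_mean_utt_len, ct_content, ct_fluency, ct_grammar,
#' ct_semantic, verbal_comp, written_comp`; empty cells are missing).  A
#' column mapping allows loading externally deposited datasets whatever
#' their native headers.
#'
#' @param path CSV path.
#' @param mapping Optional named character vector mapping canonical column
#'   names to the file's native names, e.g.
#'   `c(wab_score = "WAB_total", group = "Group")`.  Unmapped canonical
#'   columns must be present under their own names or are filled with `NA`.
#' @param group_labels Optional named vector mapping the file's group codes
#'   to `"delirium"`, `"dementia"`, `"control"`, e.g.
#'   `c(`1` = "delirium", ...)`.
#' @return A data frame with the canonical columns.
#' @export
read_score_table <- function(path, mapping = NULL, group_labels = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  unmatched <- character()
  for (col in SCORE_COLUMNS) {
    native <- if (!is.null(mapping) && col %in% names(mapping))
      mapping[[col]] else col
    if (native %in% names(raw)) {
      out[[col]] <- raw[[native]]
    } else {
      out[[col]] <- NA
      unmatched <- c(unmatched, col)
    }
  }
  if (!is.null(mapping)) {
    missing_native <- setdiff(unname(mapping), names(raw))
    if (length(missing_native))
      stop("mapped column(s) absent from ", basename(path), ": ",
           paste(missing_native, collapse = ", "), call. = FALSE)
  }
  if (length(unmatched))
    warning("score table is missing column(s), filled with NA: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  if (!all(is.na(out$group))) {
    if (!is.null(group_labels))
      out$group <- unname(group_labels[as.character(out$group)])
    bad <- setdiff(unique(stats::na.omit(out$group)), GROUPS)
    if (length(bad))
      stop("unmappable group label(s): ", paste(bad, collapse = ", "),
           "; expected ", paste(GROUPS, collapse = "/"), call. = FALSE)
  }
  out
}

#' Write a score table CSV
#'
#' @param scores Data frame with the canonical score-table columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores[, intersect(SCORE_COLUMNS, names(scores))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Compare the three clinical groups on the language variables
#'
#' For each variable: group medians and IQRs, the Kruskal-Wallis omnibus
#' test, and the three pairwise Mann-Whitney U tests with effect size r.
#' Undefined (missing) scores are excluded per test, so the n entering each
#' comparison is reported.  A variable with fewer than 2 non-missing values
#' in any group is skipped with a warning.
#'
#' @param scores Score-table data frame ([read_score_table()]).
#' @param variables Character vector of score columns to compare; defaults
#'   to the full language battery.
#' @param alpha Two-sided significance threshold (default 0.01).
#' @return A `comparison_report`: list with `summaries` (data frame of
#'   per-group median/IQR), `omnibus` (data frame of H, df, p),
#'   `pairwise` (data frame of U, Z, p, r per contrast), `alpha`.
#' @export
compare_groups <- function(scores, variables = LANGUAGE_VARS, alpha = 0.01) {
  if (!all(GROUPS %in% scores$group))
    stop("score table must contain all three groups (",
         paste(GROUPS, collapse = ", "), ")", call. = FALSE)
  pairs <- list(c("delirium", "dementia"),
                c("delirium", "control"),
                c("dementia", "control"))
  summaries <- list(); omnibus <- list(); pairwise <- list()
  for (v in variables) {
    by_group <- lapply(GROUPS, function(g)
      stats::na.omit(scores[[v]][scores$group == g]))
    names(by_group) <- GROUPS
    if (any(lengths(by_group) < 2L)) {
      warning("variable '", v, "' skipped: fewer than 2 non-missing values ",
              "in some group", call. = FALSE)
      next
    }
    for (g in GROUPS) {
      gs <- group_summary(by_group[[g]], g)
      summaries[[length(summaries) + 1L]] <-
        data.frame(variable = v, group = g, n = gs$n, median = gs$median,
                   iqr_low = gs$iqr_low, iqr_high = gs$iqr_high)
    }
    kw <- kruskal_wallis(by_group)
    omnibus[[length(omnibus) + 1L]] <-
      data.frame(variable = v, H = kw$statistic, df = kw$df,
                 p = kw$p_two_sided, significant = kw$p_two_sided < alpha)
    for (pr in pairs) {
      mw <- mann_whitney_u(by_group[[pr[1]]], by_group[[pr[2]]])
      pairwise[[length(pairwise) + 1L]] <-
        data.frame(variable = v, group1 = pr[1], group2 = pr[2],
                   n1 = mw$n_per_group[1], n2 = mw$n_per_group[2],
                   U = mw$statistic, Z = mw$z, p = mw$p_two_sided,
                   r = mw$effect_r, significant = mw$p_two_sided < alpha)
    }
  }
  structure(list(summaries = do.call(rbind, summaries),
                 omnibus = do.call(rbind, omnibus),
                 pairwise = do.call(rbind, pairwise),
                 alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Group comparison report (alpha =", x$alpha, ", two-sided)\n\n")
  for (v in unique(x$omnibus$variable)) {
    om <- x$omnibus[x$omnibus$variable == v, ]
    cat(sprintf("%s: H(%d) = %.2f, p = %.4g%s\n", v, om$df, om$H, om$p,
                if (om$significant) " *" else ""))
    sm <- x$summaries[x$summaries$variable == v, ]
    for (i in seq_len(nrow(sm)))
      cat(sprintf("  %-9s n = %2d  median = %.4g (IQR %.4g-%.4g)\n",
                  sm$group[i], sm$n[i], sm$median[i], sm$iqr_low[i],
                  sm$iqr_high[i]))
    pw <- x$pairwise[x$pairwise$variable == v, ]
    for (i in seq_len(nrow(pw)))
      cat(sprintf("  %s vs %s: U = %.2f, p = %.4g, r = %.2f%s\n",
                  pw$group1[i], pw$group2[i], pw$U[i], pw$p[i], pw$r[i],
                  if (pw$significant[i]) " *" else ""))
    cat("\n")
  }
  invisible(x)
}

#' Correlate attention/arousal covariates with the language variables
#'
#' Kendall tau-b with seeded percentile-bootstrap confidence intervals for
#' each (predictor, language score) pair, over the whole sample.  RASS
#' (agitation-sedation, negative = sedated) enters as its absolute value by
#' default, so that the correlate is the magnitude of arousal abnormality in
#' either direction; set `rass_absolute = FALSE` for the signed scale.
#'
#' @param scores Score-table data frame.
#' @param predictors Covariate columns (default BAT, OSLA, RASS).
#' @param variables Language score columns.
#' @param rass_absolute Use |RASS|?
#' @param n_boot,seed,conf Bootstrap settings (see [kendall_tau_b()]).
#' @param alpha Significance threshold for the `significant` flag.
#' @return A data frame: predictor, variable, n, tau_b, p, ci_low, ci_high,
#'   significant.  Pairs skipped for zero variance are absent, with a
#'   warning.
#' @export
correlate_scores <- function(scores, predictors = c("bat", "osla", "rass"),
                             variables = LANGUAGE_VARS,
                             rass_absolute = TRUE,
                             n_boot = 2000, seed = 20181126, conf = 0.95,
                             alpha = 0.01) {
  predictors <- intersect(predictors, names(scores))
  rows <- list()
  for (p in predictors) {
    pv <- scores[[p]]
    if (p == "rass" && rass_absolute) pv <- abs(pv)
    for (v in variables) {
      ok <- !is.na(pv) & !is.na(scores[[v]])
      if (sum(ok) < 3L || stats::var(pv[ok]) == 0 ||
          stats::var(scores[[v]][ok]) == 0) {
        warning("pair (", p, ", ", v, ") skipped: too few pairs or zero ",
                "variance", call. = FALSE)
        next
      }
      tb <- kendall_tau_b(pv[ok], scores[[v]][ok], n_boot = n_boot,
                          seed = seed, conf = conf)
      rows[[length(rows) + 1L]] <-
        data.frame(predictor = if (p == "rass" && rass_absolute) "abs_rass"
                   else p,
                   variable = v, n = tb$n, tau_b = tb$tau_b,
                   p = tb$p_two_sided, ci_low = tb$ci_low,
                   ci_high = tb$ci_high,
                   significant = tb$p_two_sided < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Age-regression screen over the language variables
#'
#' Fits `score ~ age` for each language variable and tabulates slope, p and
#' R^2 -- the screen for whether age, rather than clinical group, predicts
#' language performance.
#'
#' @param scores Score-table data frame with an `age` column.
#' @param variables Language score columns.
#' @return Data frame: variable, n, slope, intercept, slope_p, r_squared.
#' @export
age_regression_table <- function(scores, variables = LANGUAGE_VARS) {
  rows <- lapply(variables, function(v) {
    fit <- age_regression(scores$age, scores[[v]])
    data.frame(variable = v, n = fit$n, slope = fit$slope,
               intercept = fit$intercept, slope_p = fit$slope_p,
               r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}
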