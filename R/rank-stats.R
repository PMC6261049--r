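# Tie-corrected rank statistics for ordinal, tie-heavy clinical scores.
#
# The analysis is nonparametric throughout: Kruskal-Wallis omnibus tests,
# pairwise Mann-Whitney U with Cohen's effect size r = |Z|/sqrt(N), Kendall
# tau-b with percentile-bootstrap confidence intervals, ICC(2,1) for
# inter-rater agreement, and simple linear regression on age.  Two-sided
# significance is assessed at alpha = 0.01 by default, with no further
# multiple-testing correction.

#' Median and interquartile range for one group
#'
#' Quartiles use inclusive linear interpolation ([stats::quantile()] type 7);
#' the convention is configurable because printed IQRs rarely state theirs.
#'
#' @param values Numeric vector; `NA`s (undefined scores) are dropped.
#' @param group Group label carried into the result.
#' @param type Quantile type passed to [stats::quantile()].
#' @return A `group_summary` list: `group`, `n`, `median`, `iqr_low`,
#'   `iqr_high`.
#' @export
group_summary <- function(values, group = NA_character_, type = 7) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop("group_summary: no non-missing values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  structure(list(group = group, n = length(values),
                 median = q[2], iqr_low = q[1], iqr_high = q[3]),
            class = "group_summary")
}

# midranks and the tie term sum(t^3 - t) over tie groups
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Reports `U = min(U_x, U_y)` (the convention used by SPSS-style outputs),
#' a Z statistic from the tie-corrected normal approximation without
#' continuity correction, the two-sided p, and Cohen's effect size
#' `r = |Z| / sqrt(n_x + n_y)`.  With `exact = TRUE` (only valid without
#' ties) the two-sided p comes from the exact null distribution of U.
#'
#' @param x,y Numeric samples, each of size >= 2; `NA`s dropped.
#' @param exact Use the exact p (no ties, via [stats::pwilcox()])?
#' @return A `rank_test` list: `method`, `statistic` (U), `z`,
#'   `p_two_sided`, `effect_r`, `n_per_group`, `tie_correction`.
#' @export
mann_whitney_u <- function(x, y, exact = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each sample must have at least 2 non-missing values", call. = FALSE)
  n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- tie_term(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  if (sigma2 <= 0) {              # all values identical across both samples
    z <- 0; p <- 1
  } else {
    z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  if (exact) {
    if (ties > 0)
      stop("exact p is not available in the presence of ties", call. = FALSE)
    # two-sided: double the smaller tail of the null distribution of U
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
  }
  structure(list(method = if (exact) "Mann-Whitney U (exact)" else
                   "Mann-Whitney U (tie-corrected normal approximation)",
                 statistic = u, z = z, p_two_sided = p,
                 effect_r = abs(z) / sqrt(n),
                 n_per_group = c(n1, n2),
                 tie_correction = ties),
            class = "rank_test")
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Omnibus test across k groups.  H is divided by the tie correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)`; the p value comes from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   non-missing values).
#' @return A `rank_test` list: `method`, `statistic` (H), `df`,
#'   `p_two_sided`, `n_per_group`, `tie_correction`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs a list of >= 2 groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("each group must have at least 2 non-missing values", call. = FALSE)
  all_v <- unlist(groups, use.names = FALSE)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  ties <- tie_term(all_v)
  corr <- 1 - ties / (n^3 - n)
  if (corr <= 0) {                # all N values identical
    h <- 0; p <- 1
  } else {
    h <- h / corr
    p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  }
  structure(list(method = "Kruskal-Wallis (tie-corrected)",
                 statistic = h, df = length(groups) - 1,
                 p_two_sided = p, n_per_group = as.integer(sizes),
                 tie_correction = ties),
            class = "rank_test")
}

#' Kendall's tau-b with bootstrap confidence interval
#'
#' Tau-b adjusts the denominator for ties, which are pervasive in ordinal
#' clinical scores.  The two-sided p uses the tie-corrected normal
#' approximation (via [stats::cor.test()]); the confidence interval is a
#' seeded percentile bootstrap over paired case resampling.
#'
#' @param x,y Paired numeric vectors, n >= 3 complete pairs.
#' @param n_boot Bootstrap resamples (>= 200).
#' @param seed Integer seed making the CI reproducible.
#' @param conf Confidence level.
#' @return A `tau_result` list: `tau_b`, `p_two_sided`, `ci_low`, `ci_high`,
#'   `n`, `n_boot`, `seed`.
#' @export
kendall_tau_b <- function(x, y, n_boot = 2000, seed = 20181126,
                          conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("tau-b undefined: zero variance in one of the vectors",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  ci <- bootstrap_ci(function(d) {
    if (stats::var(d[, 1]) == 0 || stats::var(d[, 2]) == 0) return(NA_real_)
    stats::cor(d[, 1], d[, 2], method = "kendall")
  }, cbind(x, y), n_boot = n_boot, seed = seed, conf = conf)
  structure(list(tau_b = unname(ct$estimate),
                 p_two_sided = ct$p.value,
                 ci_low = ci[1], ci_high = ci[2],
                 n = n, n_boot = n_boot, seed = seed),
            class = "tau_result")
}

#' Percentile bootstrap confidence interval
#'
#' Case-resampling percentile bootstrap: rows of `data` are resampled with
#' replacement `n_boot` times and `statistic_fn` applied to each resample.
#' Resamples on which the statistic is undefined (`NA`) are tolerated up to
#' 10% and dropped; beyond that the interval is refused.  The caller's RNG
#' state is left untouched.
#'
#' @param statistic_fn Function of a matrix/data.frame returning a scalar
#'   (or `NA` when undefined on a degenerate resample).
#' @param data Matrix or data frame; rows are resampled.
#' @param n_boot Number of resamples (>= 200).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95: percentile 2.5/97.5 bounds).
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(statistic_fn, data, n_boot = 2000,
                         seed = 20181126, conf = 0.95) {
  if (n_boot < 200) stop("n_boot must be >= 200", call. = FALSE)
  data <- as.matrix(data)
  n <- nrow(data)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    as.numeric(statistic_fn(data[idx, , drop = FALSE]))
  }, numeric(1))
  n_bad <- sum(is.na(stat))
  if (n_bad > 0.1 * n_boot)
    stop("statistic undefined on ", n_bad, "/", n_boot,
         " bootstrap resamples", call. = FALSE)
  alpha <- (1 - conf) / 2
  unname(stats::quantile(stat[!is.na(stat)], c(alpha, 1 - alpha),
                         type = 7))
}

#' Intraclass correlation for inter-rater agreement
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC -- ICC(2,1)
#' in the Shrout-Fleiss taxonomy -- the conventional model when each of a
#' random panel of raters scores every subject and raters are treated as
#' interchangeable.  Mean squares come from the two-way ANOVA
#' `score ~ subject + rater` without replication.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns; no missing cells, >= 3 subjects, >= 2 raters.
#' @return An `icc_result` list: `icc`, `model`, `raters`, `subjects`.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("icc: missing cells are not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L)
    stop("icc needs >= 3 subjects and >= 2 raters", call. = FALSE)
  d <- data.frame(score = as.vector(m),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (isTRUE(all.equal(msr, mse)) && denom <= .Machine$double.eps)
    stop("icc undefined: no between-subject variance", call. = FALSE)
  val <- (msr - mse) / denom
  if (is.nan(val)) {
    # identical rater columns on varying subjects: mse = msc = 0 -> ICC 1
    val <- if (msr > 0) 1 else stop("icc undefined: zero variance",
                                    call. = FALSE)
  }
  structure(list(icc = val, model = "two-way random, absolute agreement, single rater (ICC(2,1))",
                 raters = k, subjects = n),
            class = "icc_result")
}

#' Linear regression of a language score on age
#'
#' Ordinary least squares with age as the predictor; used to screen for age
#' effects on the language variables.
#'
#' @param age Numeric predictor (non-constant, n >= 3 complete pairs).
#' @param score Numeric response.
#' @return A `regression_result` list: `slope`, `intercept`, `slope_p`,
#'   `r_squared`, `n`.
#' @export
age_regression <- function(age, score) {
  ok <- !is.na(age) & !is.na(score)
  age <- age[ok]; score <- score[ok]
  if (length(age) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(age) == 0)
    stop("age is constant: slope undefined", call. = FALSE)
  fit <- stats::lm(score ~ age)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(slope = co["age", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 slope_p = co["age", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = length(age)),
            class = "regression_result")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n")
  lab <- if (grepl("Kruskal", x$method)) "H" else "U"
  cat(sprintf("  %s = %.2f", lab, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  if (!is.null(x$z) && !grepl("Kruskal", x$method))
    cat(sprintf(", Z = %.2f", x$z))
  cat(sprintf(", p = %.4g", x$p_two_sided))
  if (!is.null(x$effect_r)) cat(sprintf(", r = %.2f", x$effect_r))
  cat("\n  n =", paste(x$n_per_group, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.2f, p = %.4g, %d%% CI = %.2f, %.2f (n = %d, %d bootstrap resamples)\n",
              x$tau_b, x$p_two_sided, 95L, x$ci_low, x$ci_high, x$n,
              x$n_boot))
  invisible(x)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.2f [%s; %d subjects x %d raters]\n",
              x$icc, x$model, x$subjects, x$raters))
  invisible(x)
}
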