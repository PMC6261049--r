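test_that("group summaries use inclusive linear interpolation quartiles", {
  gs <- group_summary(c(1, 2, 3, 4, 5), "g")
  expect_equal(gs$median, 3)
  expect_equal(gs$iqr_low, 2)
  expect_equal(gs$iqr_high, 4)

  const <- group_summary(rep(4, 15))
  expect_equal(const$median, 4)
  expect_equal(const$iqr_low, 4)
  expect_equal(const$iqr_high, 4)

  expect_equal(group_summary(c(NA, 1, NA, 3))$n, 2)
  expect_error(group_summary(c(NA, NA)), "no non-missing")
})

test_that("Mann-Whitney U matches exact enumeration and handles ties", {
  res <- mann_whitney_u(1:3, 4:6, exact = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 0.1)   # enumeration of C(6,3) = 20 splits

  # identical multisets: U = n^2/2, r = 0
  sym <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(sym$statistic, 8)
  expect_equal(sym$effect_r, 0)
  expect_equal(sym$z, 0)

  # degenerate: every value identical
  flat <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(flat$z, 0)
  expect_equal(flat$p_two_sided, 1)

  # r is symmetric under swapping the samples and always in [0, 1]
  set.seed(17)
  for (rep in 1:30) {
    x <- sample(0:5, sample(2:8, 1), replace = TRUE)
    y <- sample(0:5, sample(2:8, 1), replace = TRUE)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$effect_r, b$effect_r)
    expect_equal(a$statistic, b$statistic)
    expect_gte(a$effect_r, 0); expect_lte(a$effect_r, 1)
  }

  # asymptotic p agrees with wilcox.test's tie-corrected approximation
  set.seed(18)
  for (rep in 1:20) {
    x <- sample(0:4, 12, replace = TRUE)
    y <- sample(1:5, 14, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = FALSE))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is tie-corrected and collapses to Z^2 for 2 groups", {
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$p_two_sided, 1)

  # hand-computed rank-sum oracle: ranks 1..6, rank sums 3, 7, 11
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 21)
  expect_equal(kw$df, 2)

  set.seed(23)
  for (rep in 1:25) {
    g <- lapply(1:3, function(i) sample(0:6, sample(3:10, 1), replace = TRUE))
    ours <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)

    # two-group KW equals the squared MWU Z, ties included
    x <- sample(0:4, 9, replace = TRUE); y <- sample(0:4, 7, replace = TRUE)
    expect_equal(kruskal_wallis(list(x, y))$statistic,
                 mann_whitney_u(x, y)$z^2, tolerance = 1e-9)
  }
})

test_that("Kendall tau-b matches the pair-counting oracle", {
  conc <- kendall_tau_b(1:6, 2 * (1:6), n_boot = 200)
  expect_equal(conc$tau_b, 1.0)

  tb <- kendall_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3), n_boot = 200)
  expect_equal(tb$tau_b, (4 - 2) / 6, tolerance = 1e-12)

  expect_error(kendall_tau_b(rep(1, 5), 1:5, n_boot = 200), "zero variance")
  expect_error(kendall_tau_b(1:2, 2:1), "at least 3")

  set.seed(41)
  for (rep in 1:15) {
    n <- sample(8:50, 1)
    x <- sample(0:7, n, replace = TRUE)
    y <- x + sample(-3:3, n, replace = TRUE)
    tb <- kendall_tau_b(x, y, n_boot = 200)
    expect_equal(tb$tau_b, tau_b_oracle(x, y), tolerance = 1e-12)
    expect_gte(tb$tau_b, tb$ci_low - 1e-9)
    expect_lte(tb$tau_b, tb$ci_high + 1e-9)
  }
})

test_that("bootstrap CIs are percentile-based, seeded and leave the RNG alone", {
  const <- bootstrap_ci(function(d) mean(d), rep(3.5, 10), n_boot = 200,
                        seed = 1)
  expect_equal(const, c(3.5, 3.5))

  x <- matrix(c(1:20, (1:20) + rnorm(20)), ncol = 2)
  a <- bootstrap_ci(function(d) cor(d[, 1], d[, 2]), x, n_boot = 300,
                    seed = 99)
  b <- bootstrap_ci(function(d) cor(d[, 1], d[, 2]), x, n_boot = 300,
                    seed = 99)
  expect_identical(a, b)
  expect_lt(a[1], a[2])

  set.seed(1234); before <- .Random.seed
  bootstrap_ci(function(d) mean(d), 1:10, n_boot = 200, seed = 7)
  expect_identical(.Random.seed, before)

  expect_error(bootstrap_ci(function(d) NA_real_, 1:10, n_boot = 200,
                            seed = 1),
               "undefined")
  expect_error(bootstrap_ci(mean, 1:10, n_boot = 50, seed = 1), ">= 200")
})

test_that("ICC(2,1) matches the variance-component oracle", {
  m <- matrix(c(9, 6, 8, 7, 10,
                9, 6, 8, 7, 10), ncol = 2)
  expect_equal(icc(m)$icc, 1.0)

  # constructed 5x2 table against explicit ANOVA sums computed here
  r <- matrix(c(9, 6, 8, 7, 10,
                8, 5, 9, 6, 9), ncol = 2)
  n <- 5; k <- 2
  row_m <- rowMeans(r); col_m <- colMeans(r); grand <- mean(r)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((r - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc(r)$icc, expected, tolerance = 1e-12)

  # rater = subject score + huge independent noise: agreement washes out
  set.seed(77)
  subj <- rnorm(40)
  noisy <- cbind(subj + rnorm(40, sd = 50), subj + rnorm(40, sd = 50))
  expect_lt(abs(icc(noisy)$icc), 0.2)

  expect_error(icc(matrix(1, 5, 2)), "variance")
  expect_error(icc(matrix(c(1, 2, NA, 4, 5, 6), ncol = 2)), "missing")
  expect_error(icc(matrix(1:4, 2, 2)), ">= 3 subjects")
})

test_that("age regression recovers exact fits and its type-I rate", {
  age <- c(70, 75, 80, 85, 90)
  fit <- suppressWarnings(age_regression(age, 2 * age))  # perfect fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_error(age_regression(rep(80, 5), rnorm(5)), "constant")

  # score independent of age: slope_p < 0.01 in about 1% of simulations
  set.seed(55)
  rejections <- sum(replicate(500, {
    a <- sample(65:97, 45, replace = TRUE)
    age_regression(a, rnorm(45))$slope_p < 0.01
  }))
  expect_lte(rejections / 500, 0.03)
})

test_that("compare_groups flags nothing on identical groups and skips sparse variables", {
  set.seed(61)
  base <- sample(0:9, 15, replace = TRUE)
  df <- data.frame(group = rep(c("delirium", "dementia", "control"),
                               each = 15),
                   wab_score = rep(base, 3),
                   ct_mean_utt_len = rep(base + 0.5, 3))
  rep_id <- compare_groups(df, c("wab_score", "ct_mean_utt_len"))
  expect_false(any(rep_id$omnibus$significant))
  expect_false(any(rep_id$pairwise$significant))

  df$sparse <- NA_real_
  df$sparse[1] <- 1
  expect_warning(compare_groups(df, c("wab_score", "sparse")), "skipped")

  expect_error(compare_groups(data.frame(group = "delirium", wab_score = 1)),
               "three groups")
})

test_that("correlate_scores reports null taus near zero and skips constants", {
  set.seed(83)
  df <- data.frame(bat = sample(0:7, 45, replace = TRUE),
                   osla = rep(2, 45),
                   wab_score = sample(0:9, 45, replace = TRUE))
  expect_warning(
    tab <- correlate_scores(df, predictors = c("bat", "osla"),
                            variables = "wab_score", n_boot = 200),
    "skipped")
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$tau_b), 0.3)
  expect_lte(tab$ci_low, 0.05)
  expect_gte(tab$ci_high, -0.05)
})
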