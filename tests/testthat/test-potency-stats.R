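test_that("distribution summaries use linear interpolation", {
  expect_equal(summarize_distribution(c(5, 6, 7))$median, 6.0)
  s <- summarize_distribution(c(5, 5, 5, 5))
  expect_equal(s$median, 5.0)
  expect_equal(s$q3 - s$q1, 0)
  expect_equal(summarize_distribution(c(5, 6, 7, 8))$median, 6.5)
  expect_error(summarize_distribution(numeric()), "empty")
})

test_that("one-way ANOVA matches a brute-force sum-of-squares oracle", {
  # textbook three-group fixture
  g <- list(a = c(6.2, 5.9, 6.5, 6.1), b = c(7.0, 7.3, 6.8),
            c = c(5.1, 5.4, 5.0, 5.3, 5.2))
  res <- one_way_anova(g)
  x <- unlist(g)
  k <- length(g); N <- length(x)
  ss_between <- sum(vapply(g, function(v) {
    length(v) * (mean(v) - mean(x))^2
  }, 1.0))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1.0))
  f_oracle <- (ss_between / (k - 1)) / (ss_within / (N - k))
  expect_equal(res$F_statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pf(f_oracle, k - 1, N - k,
                                      lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups: no between-group variance
  same <- one_way_anova(list(c(5, 6, 7), c(5, 6, 7)))
  expect_equal(same$F_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2), 3)), "degenerate_group")
})

test_that("F equals t squared for two groups", {
  x <- c(5.1, 6.0, 5.7, 6.3, 5.2, 5.9)
  y <- c(6.8, 7.1, 6.5, 7.4, 6.9)
  f <- one_way_anova(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(f$F_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(f$p_value, tt$p.value, tolerance = 1e-9)
  # at k = 2 the Tukey adjusted p reduces to the ANOVA p
  tk <- tukey_hsd(list(x, y))
  expect_identical(nrow(tk), 1L)
  expect_equal(tk$adjusted_p, f$p_value, tolerance = 1e-4)
})

test_that("Tukey-Kramer flags a planted three-log-unit shift", {
  groups <- covkin:::with_seed(31, list(
    base = rnorm(50, 6, 0.5), same = rnorm(50, 6, 0.5),
    shifted = rnorm(50, 9, 0.5)))
  tk <- tukey_hsd(groups)
  expect_identical(nrow(tk), 3L)  # one row per unordered pair
  hit <- tk[tk$group_i == "base" & tk$group_j == "shifted" |
              tk$group_i == "shifted" & tk$group_j == "base", ]
  expect_true(hit$significant)
  expect_equal(abs(hit$mean_diff), 3, tolerance = 0.3)
  ns <- tk[(tk$group_i == "base" & tk$group_j == "same") |
             (tk$group_i == "same" & tk$group_j == "base"), ]
  expect_false(ns$significant)
  # identical groups: zero mean difference, not significant
  tk0 <- tukey_hsd(list(c(5, 6, 7), c(5, 6, 7)))
  expect_equal(tk0$mean_diff, 0)
  expect_false(tk0$significant)
})

test_that("paired t-test matches the hand formula", {
  d <- c(2.1, 2.4, 2.0, 2.3)
  res <- paired_t_test(d)
  expect_equal(res$t_statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
  expect_equal(res$mean_delta, 2.2)
  expect_error(paired_t_test(2.0), "at least 2")
  expect_error(paired_t_test(c(1, 1, 1)), "zero_variance")
})

test_that("null ANOVA rejects at the nominal five percent rate", {
  n_rep <- 1000L
  rejections <- covkin:::with_seed(2024, {
    vapply(seq_len(n_rep), function(i) {
      g <- list(rnorm(20, 6, 1), rnorm(20, 6, 1))
      one_way_anova(g)$p_value < 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  ci <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - ci)
  expect_lt(rate, 0.05 + ci)
})

test_that("shifting one equal group raises F, within-group SS unchanged", {
  g0 <- list(a = c(5.5, 6.1, 6.4, 5.8), b = c(5.5, 6.1, 6.4, 5.8))
  g1 <- list(a = g0$a, b = g0$b + 1)
  f0 <- one_way_anova(g0); f1 <- one_way_anova(g1)
  expect_gt(f1$F_statistic, f0$F_statistic)
  ssw <- function(g) sum(vapply(g, function(v) sum((v - mean(v))^2), 1.0))
  expect_equal(ssw(g0), ssw(g1))
})

test_that("per-warhead pair tests summarize deltas", {
  pairs <- data.frame(
    cpki_smiles = "a", pki_smiles = "b", target_id = "t",
    warhead = rep(c("aldehyde", "acrylate"), c(4L, 1L)),
    delta_p = c(2.1, 2.4, 2.0, 2.3, 2.2), series_id = "s",
    stringsAsFactors = FALSE)
  pt <- pair_tests(pairs)
  expect_identical(pt$n_pairs[pt$warhead == "aldehyde"], 4L)
  expect_false(is.na(pt$t_statistic[pt$warhead == "aldehyde"]))
  # a single pair has no defined test but keeps its mean
  expect_true(is.na(pt$t_statistic[pt$warhead == "acrylate"]))
  expect_equal(pt$mean_delta[pt$warhead == "acrylate"], 2.2)
})
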