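test_that("build_paired_table tallies joint outcomes", {
  t <- build_paired_table(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(unlist(unclass(t)), c(n00 = 1L, n01 = 1L, n10 = 1L, n11 = 1L))
  t0 <- build_paired_table(integer(), integer())
  expect_equal(t0$n00 + t0$n01 + t0$n10 + t0$n11, 0L)
  expect_error(build_paired_table(c(0, 2), c(0, 1)), "binary",
               class = "stewardpair_validation_error")
  expect_error(build_paired_table(c(0, 1), c(1)), "equal length",
               class = "stewardpair_validation_error")
  expect_error(paired_table(1, -1, 0, 0),
               class = "stewardpair_validation_error")
})

test_that("matched OR applies the 0.5 continuity correction and Wald CI", {
  r <- matched_odds_ratio(paired_table(393, 16, 76, 8))
  expect_equal(r$or_hat, 16.5 / 76.5)
  se <- sqrt(1 / 16.5 + 1 / 76.5)
  expect_equal(r$ci_low, exp(log(16.5 / 76.5) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(16.5 / 76.5) + 1.96 * se))
  expect_equal(r$rd, (16 - 76) / 493)
  # symmetric discordance gives OR exactly 1
  expect_equal(matched_odds_ratio(paired_table(0, 5, 5, 0))$or_hat, 1)
  # zero discordants stay finite thanks to the correction
  rz <- matched_odds_ratio(paired_table(10, 0, 0, 2))
  expect_true(is.finite(rz$or_hat) && rz$or_hat == 1)
  expect_error(matched_odds_ratio(paired_table(0, 0, 0, 0)),
               class = "stewardpair_validation_error")
})

test_that("matched OR transposition antisymmetry holds exactly", {
  set.seed(3)
  for (i in 1:50) {
    n01 <- sample(0:40, 1); n10 <- sample(0:40, 1)
    a <- matched_odds_ratio(paired_table(5, n01, n10, 3))
    b <- matched_odds_ratio(paired_table(5, n10, n01, 3))
    expect_equal(a$or_hat, 1 / b$or_hat)
    expect_equal(a$ci_low, 1 / b$ci_high)
  }
})

test_that("exact McNemar follows the doubled-smaller-tail convention", {
  expect_equal(mcnemar_exact(paired_table(0, 1, 30, 0)), 64 / 2^31)
  expect_equal(mcnemar_exact(paired_table(9, 0, 0, 4)), 1)
  expect_equal(mcnemar_exact(paired_table(0, 1, 2, 0)), 1)
  # swap invariance, and p in (0, 1]
  set.seed(4)
  for (i in 1:40) {
    n01 <- sample(0:30, 1); n10 <- sample(0:30, 1)
    p1 <- mcnemar_exact(paired_table(2, n01, n10, 1))
    p2 <- mcnemar_exact(paired_table(2, n10, n01, 1))
    expect_equal(p1, p2)
    expect_true(p1 > 0 && p1 <= 1)
  }
})

test_that("exact McNemar matches binomial-coefficient enumeration (d <= 12)", {
  for (d in 0:12) {
    for (n01 in 0:d) {
      n10 <- d - n01
      expect_equal(mcnemar_exact(paired_table(3, n01, n10, 2)),
                   binom_two_sided_oracle(min(n01, n10), d),
                   info = sprintf("n01=%d n10=%d", n01, n10))
    }
  }
})

test_that("sign test excludes zeros and matches the exact binomial", {
  r <- sign_test(c(rep(-1, 5), 1, rep(0, 3)))
  expect_equal(r$p, 0.21875)  # 2 * (7/64)
  expect_equal(r$n_neg, 5); expect_equal(r$n_pos, 1); expect_equal(r$n_zero, 3)
  expect_warning(rz <- sign_test(rep(0, 4)), "zero")
  expect_equal(rz$p, 1)
  # oracle equivalence over non-tied counts
  for (m in 1:12) {
    for (k in 0:m) {
      deltas <- c(rep(-1, k), rep(1, m - k))
      expect_equal(suppressWarnings(sign_test(deltas)$p),
                   binom_two_sided_oracle(min(k, m - k), m))
    }
  }
})

test_that("sign test equals McNemar when all magnitudes are 1", {
  set.seed(5)
  for (i in 1:25) {
    n01 <- sample(0:15, 1); n10 <- sample(0:15, 1); nz <- sample(0:20, 1)
    deltas <- c(rep(1, n01), rep(-1, n10), rep(0, nz))
    p_sign <- suppressWarnings(sign_test(deltas)$p)
    p_mcn <- mcnemar_exact(paired_table(nz, n01, n10, 0))
    expect_equal(p_sign, p_mcn)
  }
})

test_that("Wilcoxon signed-rank: exact small-n path", {
  expect_equal(wilcoxon_signed_rank(c(1, -1)), 1)
  expect_equal(wilcoxon_signed_rank(c(-1, -2, -3)), 0.25)
  # zeros dropped
  expect_equal(wilcoxon_signed_rank(c(-1, -2, -3, 0, 0)), 0.25)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate",
               class = "stewardpair_degenerate_input")
  # permutation invariance
  d <- c(-3, 1, -2, 5, -4, 2, 2, -1)
  expect_equal(wilcoxon_signed_rank(d), wilcoxon_signed_rank(rev(d)))
  expect_equal(wilcoxon_signed_rank(d), wilcoxon_signed_rank(sample(d)))
})

test_that("Wilcoxon matches brute-force sign-flip enumeration with ties", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d), wilcoxon_oracle(d),
                 info = paste(d, collapse = ","))
  }
})

test_that("Wilcoxon matches stats::wilcox.test exact p on untied data", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    # distinct magnitudes (wilcox.test abandons the exact path on ties)
    d <- (sample(1:50, n) + 0.5) * sample(c(-1, 1), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d),
                 suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value))
  }
})

test_that("Wilcoxon large-n approximation tracks wilcox.test with correction", {
  set.seed(9)
  d <- sample(c(-2, -1, 1, 2, 3), 60, replace = TRUE)
  p_pkg <- wilcoxon_signed_rank(d)
  p_ref <- suppressWarnings(
    stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
})

test_that("bootstrap median CI is deterministic and leaves RNG alone", {
  expect_equal(bootstrap_median_ci(rep(0, 20)), c(0, 0))
  x <- rnorm(30)
  ci1 <- bootstrap_median_ci(x, n_boot = 400, seed = 7)
  ci2 <- bootstrap_median_ci(x, n_boot = 400, seed = 7)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_median_ci(x, n_boot = 400, seed = 8)
  expect_false(identical(ci1, ci3))
  expect_error(bootstrap_median_ci(numeric()),
               class = "stewardpair_validation_error")
  # caller's RNG stream unaffected
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(bootstrap_median_ci(x, n_boot = 50))
  expect_identical(rnorm(1), before)
})

test_that("Holm step-down: worked example, properties, p.adjust oracle", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_error(holm_adjust(c(0.5, 1.2)),
               class = "stewardpair_validation_error")
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "holm"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
    perm <- sample(seq_along(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
  }
  # NA entries pass through but still count towards m
  adj <- holm_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(adj[2]))
  expect_equal(adj[1], 0.03)
})

test_that("delta_summary aggregates moments, signs and tests", {
  s0 <- suppressWarnings(delta_summary(c(0, 0, 0, 0)))
  expect_equal(s0$median, 0)
  expect_equal(s0$n_zero, 4)
  expect_equal(s0$p_sign, 1)
  expect_true(is.na(s0$p_wilcoxon))

  s <- delta_summary(c(-2, -1, 0, 1))
  expect_equal(s$median, -0.5)
  expect_equal(s$q1, unname(quantile(c(-2, -1, 0, 1), 0.25)))
  expect_equal(s$n_neg, 2); expect_equal(s$n_pos, 1); expect_equal(s$n_zero, 1)
  expect_equal(s$mean, -0.5)
  expect_equal(s$sd, sd(c(-2, -1, 0, 1)))
  expect_error(delta_summary(numeric()),
               class = "stewardpair_validation_error")

  sb <- delta_summary(c(rep(0, 30), -1, 1), with_bootstrap = TRUE,
                      n_boot = 200)
  expect_equal(c(sb$ci_median_low, sb$ci_median_high), c(0, 0))
})
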