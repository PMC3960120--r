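test_that("binomial tails reproduce the study's reporting conventions", {
  # one-tailed (smaller tail) at the rounded chance level 0.33
  expect_lt(abs(binom_pvalue(12, 24, 0.33, "smaller")$p_value - 0.063), 5e-4)
  # the same count at 1/3 gives a visibly different value
  expect_lt(abs(binom_pvalue(12, 24, 1 / 3, "smaller")$p_value - 0.068), 5e-4)
  # doubled-tail two-sided values at chance 0.5
  expect_lt(abs(binom_pvalue(7, 24, 0.5, "two_sided_double")$p_value - 0.064), 5e-4)
  expect_equal(binom_pvalue(6, 12, 0.5, "two_sided_double")$p_value, 1.0)
  expect_equal(binom_pvalue(0, 10, 0.5, "lower")$p_value, 2^-10)
})

test_that("binomial tails match direct enumeration of outcome sequences", {
  cases <- withr::with_seed(71, tibble::tibble(
    n = sample(1:12, 10, replace = TRUE),
    p0 = runif(10, 0.1, 0.9)
  ))
  cases$k <- withr::with_seed(72,
    vapply(cases$n, function(n) sample(0:n, 1), 1L))
  for (i in seq_len(nrow(cases))) {
    o <- oracle_binom_tails(cases$k[i], cases$n[i], cases$p0[i])
    expect_equal(binom_pvalue(cases$k[i], cases$n[i], cases$p0[i],
                              "lower")$p_value, o$lower, tolerance = 1e-12)
    expect_equal(binom_pvalue(cases$k[i], cases$n[i], cases$p0[i],
                              "upper")$p_value, o$upper, tolerance = 1e-12)
  }
})

test_that("upper and lower tails are complementary and ordered", {
  for (n in c(5, 24)) {
    for (k in 1:n) {
      up <- binom_pvalue(k, n, 0.33, "upper")$p_value
      lo_prev <- binom_pvalue(k - 1, n, 0.33, "lower")$p_value
      expect_lt(abs(up - (1 - lo_prev)), 1e-12)
    }
  }
  ks <- c(0, 3, 7, 12, 20, 24)
  for (k in ks) {
    sm <- binom_pvalue(k, 24, 0.4, "smaller")$p_value
    dbl <- binom_pvalue(k, 24, 0.4, "two_sided_double")$p_value
    up <- binom_pvalue(k, 24, 0.4, "upper")$p_value
    lo <- binom_pvalue(k, 24, 0.4, "lower")$p_value
    expect_gte(dbl, sm)
    expect_gte(sm, min(up, lo) - 1e-12)
    expect_true(all(c(sm, dbl, up, lo) >= 0 & c(sm, dbl, up, lo) <= 1))
  }
})

test_that("one-tailed values agree with the standard exact test", {
  # independent cross-check: stats::binom.test computes the same exact tails
  expect_equal(binom_pvalue(12, 24, 0.33, "upper")$p_value,
               binom.test(12, 24, 0.33, alternative = "greater")$p.value)
  expect_equal(binom_pvalue(4, 17, 0.5, "lower")$p_value,
               binom.test(4, 17, 0.5, alternative = "less")$p.value)
  expect_equal(binom_pvalue(9, 24, 1 / 3, "two_sided_minlik")$p_value,
               binom.test(9, 24, 1 / 3)$p.value)
})

test_that("binomial input validation rejects impossible counts", {
  expect_error(binom_pvalue(5, 4, 0.5), "k")
  expect_error(binom_pvalue(-1, 4, 0.5), "k")
  expect_error(binom_pvalue(2, 4, 0), "p0")
})

test_that("the 2x2 chi-square matches hand computation and the stats oracle", {
  t1 <- chisq2x2(6, 6, 1, 11)
  expect_lt(abs(t1$statistic - 5.042), 5e-4)
  expect_equal(t1$df, 1L)
  expect_lt(abs(t1$p_value - 0.025), 5e-4)
  expect_equal(chisq2x2(5, 5, 5, 5)$statistic, 0)
  expect_equal(chisq2x2(10, 0, 0, 10)$statistic, 20)
  ref <- suppressWarnings(
    chisq.test(matrix(c(6, 6, 1, 11), 2, byrow = TRUE), correct = FALSE))
  expect_equal(t1$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(t1$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("the chi-square is invariant to transposition and swaps", {
  s0 <- chisq2x2(6, 6, 1, 11)$statistic
  expect_equal(chisq2x2(6, 1, 6, 11)$statistic, s0) # transpose
  expect_equal(chisq2x2(1, 11, 6, 6)$statistic, s0) # row swap
  expect_equal(chisq2x2(6, 6, 11, 1)$statistic, s0) # column swap
})

test_that("degenerate 2x2 margins are rejected", {
  expect_error(chisq2x2(0, 0, 3, 4), "margin")
  expect_error(chisq2x2(0, 3, 0, 4), "margin")
  expect_error(chisq2x2(-1, 3, 2, 4), "nonnegative")
})

test_that("test results tidy into one-row tables", {
  td <- tidy(binom_pvalue(12, 24, 0.33, "smaller"))
  expect_equal(nrow(td), 1L)
  expect_named(td, c("test", "k", "n", "chance_level", "tail", "statistic",
                     "df", "p_value", "note"))
  expect_equal(td$tail, "smaller")
  expect_equal(glance(chisq2x2(6, 6, 1, 11))$df, 1L)
})
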