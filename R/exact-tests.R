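new_fetch_test <- function(test, p_value, tail = NA_character_,
                           k = NA_integer_, n = NA_integer_,
                           chance_level = NA_real_,
                           statistic = NA_real_, df = NA_integer_,
                           counts = NULL, note = NA_character_) {
  structure(
    list(test = test, k = k, n = n, chance_level = chance_level, tail = tail,
         statistic = statistic, df = df, p_value = p_value, counts = counts,
         note = note),
    class = "fetch_test"
  )
}

#' Exact binomial test with explicit tail conventions
#'
#' Computes exact binomial tail probabilities for `k` successes in `n` trials
#' at chance level `p0`, under one of several tail conventions used in
#' forced-choice retrieval analyses:
#'
#' \describe{
#'   \item{`upper`}{`P(X >= k)`.}
#'   \item{`lower`}{`P(X <= k)`.}
#'   \item{`smaller`}{the smaller of the two exact tails containing `k` — the
#'     convention behind one-tailed values reported for asymmetric chance
#'     levels such as 0.33.}
#'   \item{`two_sided_double`}{twice the smaller tail, capped at 1. This
#'     tail-doubling convention reproduces reported "2-tailed" values such as
#'     p = 1.0 for 6 of 12 at chance 0.5.}
#'   \item{`two_sided_minlik`}{the minimum-likelihood two-sided definition
#'     (sum of all outcome probabilities no larger than that of `k`), as used
#'     by [stats::binom.test()]; provided for comparison, not the default
#'     reporting convention.}
#' }
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Chance success probability, strictly between 0 and 1. Note that a
#'   rounded chance level (0.33) and its exact counterpart (1/3) give
#'   different p-values; the package's 3-object analyses default to 0.33.
#' @param tail Tail convention, see above.
#' @return A `fetch_test` object; use [tidy()] for a one-row tibble.
#' @examples
#' binom_pvalue(12, 24, 0.33, "smaller")          # 0.063
#' binom_pvalue(7, 24, 0.5, "two_sided_double")   # 0.064
#' @export
binom_pvalue <- function(k, n, p0,
                         tail = c("smaller", "upper", "lower",
                                  "two_sided_double", "two_sided_minlik")) {
  tail <- match.arg(tail)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n) {
    abort("`k` must satisfy 0 <= k <= n with n >= 1.")
  }
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be strictly between 0 and 1.")
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- switch(tail,
    upper = upper,
    lower = lower,
    smaller = min(lower, upper),
    two_sided_double = min(1, 2 * min(lower, upper)),
    two_sided_minlik = {
      d <- dbinom(0:n, n, p0)
      sum(d[d <= d[k + 1] * (1 + 1e-7)])
    }
  )
  new_fetch_test("binomial", p_value = min(1, p), tail = tail,
                 k = as.integer(k), n = as.integer(n), chance_level = p0)
}

#' Pearson chi-square for a 2x2 table, without continuity correction
#'
#' The association test used to compare success counts between two object
#' pairs: the uncorrected Pearson statistic on the 2x2 table
#' `rbind(c(a, b), c(c, d))` (rows = groups, columns = correct/incorrect),
#' referred to the chi-square distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Nonnegative cell counts; every row and column margin must be
#'   positive.
#' @return A `fetch_test` with fields `statistic`, `df = 1` and `p_value`.
#' @examples
#' chisq2x2(6, 6, 1, 11) # statistic 5.042, p = 0.025
#' @export
chisq2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("Cell counts must be nonnegative.")
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Every row and column margin must be positive.")
  }
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - expected)^2 / expected)
  new_fetch_test("chisq2x2",
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 tail = "two_sided_double", statistic = stat, df = 1L,
                 counts = m)
}

#' @export
print.fetch_test <- function(x, ...) {
  if (x$test == "binomial") {
    cat(sprintf("Exact binomial test: k = %d, n = %d, chance = %s, tail = %s\n",
                x$k, x$n, format(x$chance_level), x$tail))
  } else {
    cat(sprintf("Pearson chi-square (2x2, no continuity correction): X^2 = %s, df = %d\n",
                format(x$statistic, digits = 4), x$df))
  }
  cat(sprintf("p-value = %.4f\n", x$p_value))
  if (!is.na(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @method tidy fetch_test
#' @export
tidy.fetch_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    k = x$k, n = x$n,
    chance_level = x$chance_level,
    tail = x$tail,
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    note = x$note
  )
}

#' @method glance fetch_test
#' @export
glance.fetch_test <- function(x, ...) tidy(x)
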