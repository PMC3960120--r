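#' Simulate the attempt index of a sequential random search
#'
#' An indifferent searcher draws objects from a set of `set_size` one after the
#' other, without replacement, until it hits the single target. The returned
#' value is the draw number at which the target turns up. The draw order of a
#' no-replacement search is a uniform random permutation, so the function
#' simulates one permutation per trial via random keys and reports the
#' target's rank; the resulting index is uniform on `1..set_size`.
#'
#' @param set_size Number of objects in the array (>= 1).
#' @param n Number of independent trials to simulate.
#' @return An integer vector of length `n` with values in `1..set_size`.
#' @examples
#' table(sample_attempt_index(3, 1000))
#' @export
sample_attempt_index <- function(set_size, n = 1L) {
  if (length(set_size) != 1L || is.na(set_size) || set_size < 1) {
    abort("`set_size` must be a single integer >= 1.")
  }
  set_size <- as.integer(set_size)
  if (set_size == 1L) return(rep(1L, n))
  keys <- matrix(runif(n * set_size), nrow = n)
  # target is object 1; its draw position is the rank of its key
  as.integer(rowSums(keys <= keys[, 1L]))
}

#' Monte-Carlo chance null for the mean-attempts statistic
#'
#' Builds the null distribution of a subject's average attempt index under
#' pure chance: each simulated run performs `n_trials` sequential
#' no-replacement searches through `set_size` objects and records the mean of
#' the per-trial attempt indices; the run means over `n_sims` repetitions form
#' the null sample. A subject who has learned the labels should need fewer
#' attempts on average than this distribution.
#'
#' @param n_trials Trials per simulated run.
#' @param set_size Objects available per trial.
#' @param n_sims Number of simulated runs (default 10,000).
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A `fetch_null` object with fields `samples`, `n_trials`,
#'   `set_size`, `n_sims`, `seed` and `kind = "monte_carlo"`.
#' @seealso [exact_null()] for the enumeration twin, [mc_p()] for p-values.
#' @examples
#' null <- build_null(24, 3, n_sims = 1000, seed = 1)
#' mean(null$samples) # close to 2, the mean of a uniform draw on 1..3
#' @export
build_null <- function(n_trials, set_size, n_sims = 10000L, seed = 101L) {
  if (n_trials < 1 || set_size < 1 || n_sims < 1) {
    abort("`n_trials`, `set_size` and `n_sims` must all be positive.")
  }
  samples <- withr::with_seed(seed, {
    idx <- sample_attempt_index(set_size, n = n_sims * n_trials)
    rowMeans(matrix(idx, nrow = n_sims))
  })
  structure(
    list(samples = samples, n_trials = as.integer(n_trials),
         set_size = as.integer(set_size), n_sims = as.integer(n_sims),
         seed = as.integer(seed), kind = "monte_carlo"),
    class = "fetch_null"
  )
}

#' Exact chance null for the mean-attempts statistic
#'
#' The enumeration twin of [build_null()]: since the attempt index of a
#' no-replacement search is uniform on `1..set_size`, the sum of attempt
#' indices over `n_trials` trials has an exactly computable distribution, and
#' the mean is the sum divided by `n_trials`.
#'
#' @inheritParams build_null
#' @return A `fetch_null` object with fields `pmf` (tibble from
#'   [exact_sum_pmf()]), `n_trials`, `set_size` and `kind = "exact"`.
#' @export
exact_null <- function(n_trials, set_size) {
  structure(
    list(pmf = exact_sum_pmf(n_trials, set_size),
         n_trials = as.integer(n_trials), set_size = as.integer(set_size),
         kind = "exact"),
    class = "fetch_null"
  )
}

#' @export
print.fetch_null <- function(x, ...) {
  cat("<fetch_null> ", x$kind, ": ", x$n_trials, " trials, set size ",
      x$set_size, "\n", sep = "")
  if (x$kind == "monte_carlo") {
    cat("  ", x$n_sims, " simulated runs (seed ", x$seed, "); mean of means ",
        format(mean(x$samples), digits = 4), "\n", sep = "")
  } else {
    m <- sum(x$pmf$sum * x$pmf$prob) / x$n_trials
    cat("  exact pmf over sums ", min(x$pmf$sum), "..", max(x$pmf$sum),
        "; mean of means ", format(m, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Exact distribution of the summed attempt indices
#'
#' Probability mass function of the sum of `n_trials` independent attempt
#' indices, each uniform on `1..set_size`, computed by iterated convolution.
#' The support is `n_trials .. n_trials * set_size`.
#'
#' @inheritParams build_null
#' @return A tibble with columns `sum` and `prob`; `prob` sums to 1.
#' @examples
#' exact_sum_pmf(2, 2) # 0.25, 0.5, 0.25 on sums 2, 3, 4
#' @export
exact_sum_pmf <- function(n_trials, set_size) {
  if (n_trials < 1 || set_size < 1) {
    abort("`n_trials` and `set_size` must be positive.")
  }
  if (n_trials * set_size > 1e6) {
    abort("Support too large for dense convolution (> 1e6 points).")
  }
  step <- rep(1 / set_size, set_size) # pmf of one attempt index on 1..set_size
  pmf <- 1
  for (i in seq_len(n_trials)) {
    m <- length(pmf)
    out <- numeric(m + set_size - 1L)
    for (j in seq_len(set_size)) {
      idx <- j:(j + m - 1L)
      out[idx] <- out[idx] + pmf * step[j]
    }
    pmf <- out
  }
  tibble::tibble(
    sum = seq.int(n_trials, n_trials * set_size),
    prob = pmf
  )
}

#' Observed mean attempt index of a subject
#'
#' The test statistic of the Monte-Carlo analysis: the average attempt index
#' at which the subject retrieved the target. Real experiments cap the number
#' of attempts (e.g. at 2), while the simulated chance agent searches until it
#' finds the target, so trials where the subject never retrieved the target
#' need a policy to place both on the same scale:
#'
#' \describe{
#'   \item{`assign_set_size` (default)}{a failed trial counts as attempt index
#'     `set_size`, as if the target would have been found on the forced final
#'     draw. This is the only policy under which the capped subject and the
#'     uncapped chance agent are directly comparable.}
#'   \item{`exclude`}{failed trials are dropped from numerator and
#'     denominator.}
#'   \item{`assign_max_attempts`}{a failed trial counts as `max_attempts`.}
#' }
#'
#' @param trials Trial records for one subject and experiment.
#' @param policy Failure policy, see above.
#' @param set_size,max_attempts Overrides; by default taken from the records.
#' @return The mean attempt index, a single number.
#' @examples
#' observed_mean_attempts(study_trials("Paddy", "exp1")) # 38/24
#' @export
observed_mean_attempts <- function(trials,
                                   policy = c("assign_set_size", "exclude",
                                              "assign_max_attempts"),
                                   set_size = NULL, max_attempts = NULL) {
  policy <- match.arg(policy)
  trials <- validate_trials(trials)
  if (nrow(trials) == 0) abort("No trials.")
  sa <- trials$success_attempt
  failed <- is.na(sa)
  x <- as.numeric(sa)
  if (policy == "assign_set_size") {
    s <- rep(set_size %||% trials$set_size, length.out = nrow(trials))
    x[failed] <- s[failed]
  } else if (policy == "assign_max_attempts") {
    m <- max_attempts %||% max(lengths(split_attempts(trials$attempts)))
    x[failed] <- m
  } else {
    x <- x[!failed]
  }
  if (length(x) == 0) abort("No trials left after excluding failures.")
  mean(x)
}

#' Monte-Carlo p-value for the mean-attempts statistic
#'
#' The proportion of null runs whose mean attempt index is as small as or
#' smaller than the observed value (ties count as extreme). For an exact null
#' the same tail is computed from the enumerated sum distribution,
#' `P(sum <= observed * n_trials)`.
#'
#' @param observed Observed mean attempt index (see
#'   [observed_mean_attempts()]).
#' @param null A `fetch_null` from [build_null()] or [exact_null()].
#' @return A p-value in `[0, 1]`.
#' @examples
#' null <- build_null(24, 3, n_sims = 2000, seed = 1)
#' mc_p(38 / 24, null)
#' @export
mc_p <- function(observed, null) {
  stopifnot(inherits(null, "fetch_null"))
  p <- if (null$kind == "monte_carlo") {
    # tolerance keeps k/n-valued observations tied with equal simulated means
    mean(null$samples <= observed + 1e-9)
  } else {
    sum(null$pmf$prob[null$pmf$sum <= observed * null$n_trials + 1e-9])
  }
  min(1, max(0, p)) # guard accumulated floating error in the exact tail
}

#' Exact p-value for the mean-attempts statistic
#'
#' Closed-form twin of [mc_p()]: the lower tail of the exact sum distribution
#' from [exact_sum_pmf()], ties included.
#'
#' @inheritParams build_null
#' @param observed Observed mean attempt index.
#' @return A p-value in `[0, 1]`.
#' @examples
#' exact_p(38 / 24, 24, 3)
#' @export
exact_p <- function(observed, n_trials, set_size) {
  mc_p(observed, exact_null(n_trials, set_size))
}

#' @method tidy fetch_null
#' @export
tidy.fetch_null <- function(x, ...) {
  if (x$kind == "monte_carlo") {
    tibble::tibble(mean_attempts = x$samples)
  } else {
    tibble::tibble(mean_attempts = x$pmf$sum / x$n_trials, prob = x$pmf$prob)
  }
}

#' @method glance fetch_null
#' @export
glance.fetch_null <- function(x, ...) {
  if (x$kind == "monte_carlo") {
    tibble::tibble(kind = x$kind, n_trials = x$n_trials,
                   set_size = x$set_size, n_sims = x$n_sims, seed = x$seed,
                   mean = mean(x$samples), sd = stats::sd(x$samples))
  } else {
    m <- sum(x$pmf$sum * x$pmf$prob) / x$n_trials
    v <- sum((x$pmf$sum / x$n_trials - m)^2 * x$pmf$prob)
    tibble::tibble(kind = x$kind, n_trials = x$n_trials,
                   set_size = x$set_size, n_sims = NA_integer_,
                   seed = NA_integer_, mean = m, sd = sqrt(v))
  }
}
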