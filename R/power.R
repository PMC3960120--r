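power_tests <- c("exp1_mc", "exp1_first_binomial", "exp2_overall_binomial",
                 "exp3_overall_binomial")

# p-value of one simulated run under the named pipeline test; `null` is the
# prebuilt chance null for exp1_mc (it does not depend on the data, so one
# null serves every replicate)
replicate_pvalue <- function(test, trials, design, null = NULL,
                             policy = "assign_set_size") {
  correct <- !is.na(trials$success_attempt)
  switch(test,
    exp1_mc = mc_p(observed_mean_attempts(trials, policy = policy), null),
    exp1_first_binomial = binom_pvalue(
      sum(correct & trials$success_attempt == 1L), nrow(trials),
      design$chance_level, "smaller")$p_value,
    exp2_overall_binomial = ,
    exp3_overall_binomial = binom_pvalue(
      sum(correct), nrow(trials), design$chance_level,
      "two_sided_double")$p_value
  )
}

test_design <- function(test) {
  switch(test,
    exp1_mc = ,
    exp1_first_binomial = experiment_design("exp1"),
    exp2_overall_binomial = experiment_design("exp2"),
    exp3_overall_binomial = experiment_design("exp3")
  )
}

power_run <- function(test, design, agent, alpha, n_reps, seed,
                      n_sims = 10000L) {
  p <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_reps), function(i) {
      tr <- sim_trials_impl(agent, design, "sim")
      # each replicate runs the complete procedure, including its own
      # freshly simulated chance null, exactly as the pipeline test does
      null <- if (test == "exp1_mc") {
        build_null(design$n_trials, design$set_size, n_sims = n_sims,
                   seed = seed + i)
      }
      replicate_pvalue(test, tr, design, null = null)
    }, numeric(1))
  })
  r <- mean(p <= alpha) # ties reject, matching the tie handling of mc_p
  agent_kind <- agent$kind
  agent_theta <- agent$theta %||% NA_real_
  tibble::new_tibble(
    tibble::tibble(
      test = test, experiment = design$experiment,
      n_trials = design$n_trials, agent = agent_kind,
      theta = agent_theta, alpha = alpha,
      n_reps = as.integer(n_reps), seed = as.integer(seed),
      rejection_rate = r, mc_se = sqrt(r * (1 - r) / n_reps)
    ),
    class = "fetch_power"
  )
}

#' Type-I error of a pipeline test under the chance agent
#'
#' Simulates `n_reps` full sessions of a random (chance) agent under the
#' design, applies the named test to each at level `alpha`, and reports the
#' rejection rate with its binomial Monte-Carlo standard error. Because the
#' tests are discrete, rates at or below the nominal level are expected
#' (exact binomial tests are conservative).
#'
#' @param test One of `"exp1_mc"` (Monte-Carlo mean-attempts test),
#'   `"exp1_first_binomial"`, `"exp2_overall_binomial"`,
#'   `"exp3_overall_binomial"`.
#' @param design Design to simulate under; defaults to the test's paradigm.
#' @param alpha Nominal level; a replicate rejects when `p <= alpha`.
#' @param n_reps Number of simulated sessions (at least 100).
#' @param seed Integer seed.
#' @param n_sims Simulations for the Monte-Carlo null (`exp1_mc` only).
#' @return A one-row `fetch_power` tibble with `rejection_rate` and `mc_se`.
#' @examples
#' estimate_type1("exp3_overall_binomial", n_reps = 200, seed = 1)
#' @export
estimate_type1 <- function(test = power_tests, design = NULL, alpha = 0.05,
                           n_reps = 2000L, seed = 101L, n_sims = 10000L) {
  test <- match.arg(test)
  if (n_reps < 100) abort("`n_reps` below 100 gives a meaningless estimate.")
  design <- design %||% test_design(test)
  power_run(test, design, agent_spec("random"), alpha, n_reps, seed, n_sims)
}

#' Power curve of a pipeline test over knower accuracies
#'
#' Estimates the rejection rate of a test against knower agents of increasing
#' accuracy `theta`: the probability of detecting a genuine word-learner at
#' each accuracy level. At `theta` equal to the design's chance level the
#' knower coincides with the chance agent and the curve returns to the type-I
#' error.
#'
#' @inheritParams estimate_type1
#' @param thetas Knower accuracies to scan.
#' @return A `fetch_power` tibble, one row per `theta`.
#' @examples
#' power_curve("exp1_first_binomial", thetas = c(0.4, 0.8),
#'             n_reps = 200, seed = 1)
#' @export
power_curve <- function(test = power_tests, design = NULL,
                        thetas = c(0.4, 0.6, 0.8), alpha = 0.05,
                        n_reps = 2000L, seed = 101L, n_sims = 10000L) {
  test <- match.arg(test)
  if (n_reps < 100) abort("`n_reps` below 100 gives a meaningless estimate.")
  design <- design %||% test_design(test)
  rows <- purrr::imap(thetas, function(th, i) {
    power_run(test, design, agent_spec("knower", theta = th), alpha, n_reps,
              seed + i - 1L, n_sims)
  })
  out <- purrr::list_rbind(rows)
  tibble::new_tibble(out, class = "fetch_power")
}
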