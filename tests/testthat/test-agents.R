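test_that("choice probabilities implement each strategy", {
  expect_equal(unname(choice_probs(agent_spec("random"), "exp1")),
               rep(1 / 3, 3))
  p_know <- choice_probs(agent_spec("knower", theta = 1), "exp2")
  expect_equal(unname(p_know), c(1, 0, 0, 0))
  p_know2 <- choice_probs(agent_spec("knower", theta = 0.7), "exp1")
  expect_equal(unname(p_know2), c(0.7, 0.15, 0.15))
  # associative agents follow the object visible during naming
  p_occ <- choice_probs(agent_spec("associative", theta = 0.9), "exp3",
                        condition = "target_occluded")
  expect_equal(unname(p_occ), c(0.1, 0.9))
  p_open <- choice_probs(agent_spec("associative", theta = 0.9), "exp3",
                         condition = "target_open")
  expect_equal(unname(p_open), c(0.9, 0.1))
  # enhancement weights the attended location
  p_enh <- choice_probs(agent_spec("enhancement", w = 2), "exp1")
  expect_equal(unname(p_enh), c(3, 1, 1) / 5)
  # in the two-pair paradigm both labelled objects were attended
  p_lab <- choice_probs(agent_spec("enhancement", w = Inf), "exp2")
  expect_equal(unname(p_lab), c(0.5, 0.5, 0, 0))
  expect_equal(sum(choice_probs(agent_spec("learner", theta_start = 0.4,
                                           theta_end = 0.9),
                                "exp1", trial_index = 3, n_trials = 24)), 1)
})

test_that("learner accuracy ramps monotonically between its endpoints", {
  ag <- agent_spec("learner", theta_start = 0.5, theta_end = 0.95,
                   rate = 0.5)
  th <- vapply(1:28, function(i) {
    choice_probs(ag, "exp3", trial_index = i, n_trials = 28)[["target"]]
  }, 1)
  expect_true(all(diff(th) >= 0))
  expect_true(all(th >= 0.5 & th <= 0.95))
})

test_that("agent specifications are validated", {
  expect_error(agent_spec("knower"), "theta")
  expect_error(agent_spec("enhancement", w = -1), "w")
  expect_error(agent_spec("learner", theta_start = 0.5), "theta_start")
  expect_error(agent_spec("random", theta_by_pair = c(A = 1, B = 0)),
               "knower")
  expect_error(choice_probs(agent_spec("random"), "exp3", set_size = 1),
               "2 objects")
})

test_that("simulators emit valid, design-conforming records", {
  for (sim in list(
    simulate_exp1(agent_spec("random"), seed = 1),
    simulate_exp2(agent_spec("associative", theta = 0.5), seed = 2),
    simulate_exp3(agent_spec("enhancement", w = 1), seed = 3)
  )) {
    d <- experiment_design(sim$experiment[1])
    expect_silent(validate_trials(sim, d))
    expect_equal(nrow(sim), d$n_trials)
  }
  expect_identical(simulate_exp1(agent_spec("random"), seed = 5),
                   simulate_exp1(agent_spec("random"), seed = 5))
  expect_error(simulate_exp1(agent_spec("random"),
                             experiment_design("exp2"), seed = 1), "exp1")
})

test_that("a perfect knower always fetches first time", {
  s1 <- summarize_subject(simulate_exp1(agent_spec("knower", theta = 1),
                                        seed = 7))
  expect_equal(s1$first_attempt_correct, 24L)
  s3 <- summarize_subject(simulate_exp3(agent_spec("knower", theta = 1),
                                        seed = 8))
  expect_equal(s3$overall_correct, 28L)
})

test_that("random agents hit the analytic success rates in the 3-object task", {
  sums <- purrr::map(1:300, function(i) {
    summarize_subject(simulate_exp1(agent_spec("random"), seed = 1000 + i))
  }) |> purrr::list_rbind()
  # first attempt: 24/3 = 8; within two attempts: 24 * 2/3 = 16
  expect_equal(mean(sums$first_attempt_correct), 8, tolerance = 0.05)
  expect_equal(mean(sums$overall_correct), 16, tolerance = 0.04)
})

test_that("the two-pair simulator produces the analytic labelled rates", {
  labelled_rate <- function(trials) {
    first <- vapply(strsplit(trials$attempts, ";"), `[[`, "", 1L)
    mean(first %in% c("target", "labelled_nontarget"))
  }
  runs <- purrr::map(1:200, function(i) {
    tr <- simulate_exp2(agent_spec("random"), seed = 2000 + i)
    c(correct = mean(!is.na(tr$success_attempt)), lab = labelled_rate(tr))
  })
  m <- colMeans(do.call(rbind, runs))
  expect_equal(unname(m["correct"]), 1 / 4, tolerance = 0.08)
  expect_equal(unname(m["lab"]), 1 / 2, tolerance = 0.05)
  # an agent with all mass on the labelled pair: half correct, all labelled
  runs2 <- purrr::map(1:200, function(i) {
    tr <- simulate_exp2(agent_spec("enhancement", w = Inf), seed = 3000 + i)
    c(correct = mean(!is.na(tr$success_attempt)), lab = labelled_rate(tr))
  })
  m2 <- colMeans(do.call(rbind, runs2))
  expect_equal(unname(m2["correct"]), 1 / 2, tolerance = 0.05)
  expect_equal(unname(m2["lab"]), 1)
})

test_that("per-pair knower accuracy drives the pair asymmetry", {
  ag <- agent_spec("knower", theta = 0.5, theta_by_pair = c(A = 1, B = 0))
  tr <- simulate_exp2(ag, seed = 11)
  correct <- !is.na(tr$success_attempt)
  expect_equal(sum(correct & tr$pair == "A"), 12L)
  expect_equal(sum(correct & tr$pair == "B"), 0L)
})

test_that("a ramping learner improves from the first to the last window", {
  ag <- agent_spec("learner", theta_start = 0.5, theta_end = 0.95,
                   rate = 0.5)
  diffs <- vapply(1:300, function(i) {
    s <- summarize_subject(simulate_exp3(ag, seed = 4000 + i), window = 12)
    s$last_window_correct - s$first_window_correct
  }, 1L)
  expect_gt(mean(diffs), 1) # late-window counts dominate early-window ones
})

test_that("knower accuracy is recovered by the first-attempt moment estimator", {
  d <- experiment_design("exp1", n_trials = 240L)
  for (theta in c(0.4, 0.8)) {
    est <- vapply(1:60, function(i) {
      tr <- simulate_exp1(agent_spec("knower", theta = theta), d,
                          seed = 5000 + i)
      mean(!is.na(tr$success_attempt) & tr$success_attempt == 1L)
    }, 1)
    expect_true(mean(abs(est - theta) <= 0.1) >= 0.95)
  }
})
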