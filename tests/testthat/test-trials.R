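test_that("a CSV row maps to a trial record with the right success attempt", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,experiment,trial_index,set_size,condition,requested_label,attempts,success_attempt",
    "Paddy,exp1,1,3,default,Gysi,distracter;target,2"
  ), f)
  tr <- read_trials(f)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$success_attempt, 2L)
  expect_equal(tr$requested_label, "Gysi")
  expect_equal(strsplit(tr$attempts, ";")[[1]], c("distracter", "target"))
})

test_that("a header-only file reads as an empty table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("subject_id", "experiment", "trial_index", "set_size",
                     "condition", "requested_label", "attempts",
                     "success_attempt"), collapse = ","), f)
  expect_equal(nrow(read_trials(f)), 0L)
})

test_that("write then read round-trips records exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  for (trials in list(
    study_trials("Paddy", "exp1"),
    study_trials("Betsy", "exp3"),
    simulate_exp2(agent_spec("knower", theta = 0.7), seed = 4)
  )) {
    write_trials(trials, f)
    back <- read_trials(f)
    expect_equal(as.data.frame(back), as.data.frame(trials))
  }
})

test_that("many simulated records survive a round trip", {
  design <- experiment_design("exp3", n_trials = 1000L)
  trials <- simulate_exp3(agent_spec("random"), design, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, f)
  expect_equal(as.data.frame(read_trials(f)), as.data.frame(trials))
})

test_that("validation names the violated rule", {
  tr <- random_trials(5)
  bad <- tr
  bad$attempts[2] <- "wizard"
  expect_error(validate_trials(bad), "known roles.*row 2")
  bad <- tr
  bad$success_attempt[1] <- 2L # attempts say first-attempt success
  expect_error(validate_trials(bad), "first target retrieval")
  bad <- tr
  bad$attempts[3] <- "target;target"
  expect_error(validate_trials(bad), "at most once")
  bad <- tr
  bad$success_attempt[1] <- NA_integer_
  expect_error(validate_trials(bad), "implies success_attempt")
  expect_error(validate_trials(tr[, -3]), "missing column")
})

test_that("design-aware validation catches cap and balance violations", {
  tr <- random_trials(24)
  expect_silent(validate_trials(tr, experiment_design("exp1")))
  d1 <- experiment_design("exp1", max_attempts = 1)
  expect_error(validate_trials(tr, d1), "max_attempts")
  tr3 <- simulate_exp3(agent_spec("random"), seed = 2)
  expect_silent(validate_trials(tr3, experiment_design("exp3")))
  tr3$condition <- "target_open"
  expect_error(validate_trials(tr3, experiment_design("exp3")), "balanced")
})

test_that("subject summaries count overall, first-attempt and windows", {
  s <- summarize_subject(study_trials("Paddy", "exp1"))
  expect_equal(s$overall_correct, 22L)
  expect_equal(s$first_attempt_correct, 12L)
  expect_true(s$first_attempt_correct <= s$overall_correct)
  expect_true(s$overall_correct <= s$n_trials)

  s3 <- summarize_subject(study_trials("Paddy", "exp3"), window = 12)
  expect_equal(s3$last_window_correct, 10L)
  expect_equal(s3$first_window_correct, 6L)
  # 28 trials, two 12-trial windows: the middle 4 belong to neither
  expect_equal(s3$overall_correct -
                 (s3$first_window_correct + s3$last_window_correct), 2L)
})

test_that("all-first-attempt records give overall = first = n", {
  tr <- random_trials(10)
  tr$attempts <- "target"
  tr$success_attempt <- 1L
  s <- summarize_subject(tr)
  expect_equal(s$overall_correct, 10L)
  expect_equal(s$first_attempt_correct, 10L)
})

test_that("summaries are invariant under record order permutation", {
  tr <- study_trials("Betsy", "exp3")
  shuffled <- tr[withr::with_seed(5, sample(nrow(tr))), ]
  expect_equal(summarize_subject(tr), summarize_subject(shuffled))
})

test_that("summarize rejects mixed subjects, experiments and duplicates", {
  a <- random_trials(6, subject = "a")
  b <- random_trials(6, subject = "b")
  expect_error(summarize_subject(dplyr::bind_rows(a, b)), "multiple subjects")
  b2 <- random_trials(6, subject = "a")
  b2$experiment <- "exp3"
  b2$condition <- rep(c("target_open", "target_occluded"), 3)
  expect_error(summarize_subject(dplyr::bind_rows(a, b2)),
               "multiple experiments")
  dup <- a
  dup$trial_index[2] <- 1L
  expect_error(summarize_subject(dup), "Duplicate")
  expect_error(summarize_subject(a, window = 7L), "window")
})

test_that("designs validate their structural parameters", {
  expect_error(experiment_design("exp1", n_trials = 0), "positive")
  expect_error(experiment_design("exp1", chance_level = 1.2), "between")
  expect_error(experiment_design("exp3", n_trials = 27), "even")
  d <- experiment_design("exp3")
  expect_equal(unname(d$conditions), c(14L, 14L))
})

test_that("designs round-trip through a key:value config file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("experiment: exp1", "n_trials: 240", "chance_level: 0.33"), f)
  d <- read_design(f)
  expect_equal(d$n_trials, 240L)
  expect_equal(d$chance_level, 0.33)
  expect_error(read_design(textConnection("n_trials: 3")), "experiment")
})
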