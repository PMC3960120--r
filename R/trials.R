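#' @keywords internal
trial_roles <- c("target", "labelled_nontarget", "distracter", "none")

#' @keywords internal
trial_columns <- c("subject_id", "experiment", "trial_index", "set_size",
                   "condition", "requested_label", "attempts",
                   "success_attempt")

split_attempts <- function(attempts) {
  x <- as.character(attempts)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

#' Validate a tibble of fetch-task trials
#'
#' Checks the structural invariants of trial records: known experiment and
#' condition labels, 1-based positive trial indices, attempt lists made of the
#' roles `target`, `labelled_nontarget`, `distracter` or `none`, no repeated
#' retrieval of the same object within a trial (`none` excepted, since
#' returning empty-handed removes nothing from the array), and consistency of
#' `success_attempt` with the attempt list: when present it must point at the
#' first (and only) `target` entry.
#'
#' When a design is supplied, per-design rules are also enforced: attempt lists
#' no longer than `max_attempts`, `set_size` matching the design, and for the
#' two-condition paradigm exactly half the trials in each condition per
#' subject.
#'
#' @param trials A data frame with columns `subject_id`, `experiment`,
#'   `trial_index`, `set_size`, `condition`, `requested_label`, `attempts`
#'   (roles separated by `";"`), `success_attempt` (`NA` when the target was
#'   never retrieved). Extra columns (e.g. `run`, `pair`) are allowed and kept.
#' @param design Optional [experiment_design()] to validate against.
#'
#' @return The input as a tibble, invisibly. Errors name the violated rule and
#'   the first offending row.
#' @export
validate_trials <- function(trials, design = NULL) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    abort(sprintf("Trial table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  fail <- function(rule, rows) {
    abort(sprintf("Trial validation failed [%s] at row %d.", rule, rows[1]))
  }
  chk <- function(ok, rule) if (!all(ok)) fail(rule, which(!ok))

  chk(trials$experiment %in% c("exp1", "exp2", "exp3"), "known experiment")
  chk(trials$condition %in% c("default", "target_open", "target_occluded"),
      "known condition")
  chk(!is.na(trials$trial_index) & trials$trial_index >= 1, "trial_index >= 1")
  chk(!is.na(trials$set_size) & trials$set_size >= 2, "set_size >= 2")

  att <- split_attempts(trials$attempts)
  chk(vapply(att, function(a) all(a %in% trial_roles), TRUE), "known roles")
  # no role-instance repeats: objects are drawn without replacement, so a
  # role can recur only as often as instances of it exist; `none` is exempt.
  # Without object identities the checkable part is that `target` never
  # repeats (there is exactly one target).
  chk(vapply(att, function(a) sum(a == "target") <= 1L, TRUE),
      "target retrieved at most once")
  sa <- trials$success_attempt
  first_target <- vapply(att, function(a) {
    i <- match("target", a)
    if (is.na(i)) NA_integer_ else as.integer(i)
  }, 1L)
  chk(is.na(sa) | (!is.na(first_target) & sa == first_target),
      "success_attempt marks the first target retrieval")
  chk(!is.na(sa) | is.na(first_target),
      "target retrieval implies success_attempt")

  if (!is.null(design)) {
    chk(trials$experiment == design$experiment, "experiment matches design")
    chk(trials$set_size == design$set_size, "set_size matches design")
    chk(lengths(att) <= design$max_attempts, "attempts within max_attempts")
    if (design$experiment == "exp3") {
      counts <- trials |>
        dplyr::count(.data$subject_id, .data$condition)
      bal <- tidyr::pivot_wider(counts, names_from = "condition",
                                values_from = "n", values_fill = 0L)
      half <- design$n_trials %/% 2L
      ok <- all(c("target_open", "target_occluded") %in% names(bal)) &&
        all(bal$target_open == half) && all(bal$target_occluded == half)
      if (!ok) fail("balanced exp3 conditions", 1L)
    }
  }
  invisible(trials)
}

#' Read fetch-task trials from a CSV file
#'
#' The on-disk format is comma-separated UTF-8 with a header row. Attempt
#' lists are stored in a single column with roles separated by semicolons,
#' e.g. `"distracter;target"` for a trial where the target was retrieved on
#' the second attempt. Records are validated on read.
#'
#' @param file Path to a CSV file.
#' @param design Optional [experiment_design()] to validate against.
#' @return A tibble of trial records in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trials(study_trials("Paddy", "exp1"), f)
#' read_trials(f)
#' @export
read_trials <- function(file, design = NULL) {
  trials <- readr::read_csv(
    file,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      experiment = readr::col_character(),
      trial_index = readr::col_integer(),
      set_size = readr::col_integer(),
      condition = readr::col_character(),
      requested_label = readr::col_character(),
      attempts = readr::col_character(),
      success_attempt = readr::col_integer(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  prob <- readr::problems(trials)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed trial file: parse error at row %d (%s).",
                  prob$row[1], prob$expected[1]))
  }
  trials$attempts[is.na(trials$attempts)] <- ""
  # an all-NA pair column has no type on disk; it is character by convention
  if ("pair" %in% names(trials) && is.logical(trials$pair)) {
    trials$pair <- as.character(trials$pair)
  }
  if ("run" %in% names(trials)) trials$run <- as.integer(trials$run)
  validate_trials(trials, design)
  trials
}

#' Write fetch-task trials to a CSV file
#'
#' The inverse of [read_trials()]: `read_trials(write_trials(x, f))` returns
#' records equal to `x`. An empty table produces a header-only file.
#'
#' @param trials A validated trial tibble.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_trials <- function(trials, file) {
  validate_trials(trials)
  readr::write_csv(tibble::as_tibble(trials), file, progress = FALSE)
  invisible(file)
}

#' Summarize one subject's trials
#'
#' Collapses a subject's trial records into the counts the standard analyses
#' consume: trials with the target retrieved at all (`overall_correct`),
#' trials with the target retrieved on the first attempt
#' (`first_attempt_correct`), per-condition counts for the two-condition
#' paradigm, learning-window counts (the first `window` and last `window`
#' trials by `trial_index`; with 28 trials and `window = 12` the middle 4
#' trials belong to neither window), the number of trials on which the
#' subject chose the object that was in the open during naming
#' (`open_choices`, two-condition paradigm only), and the observed mean
#' attempt index under the `assign_set_size` failure policy (see
#' [observed_mean_attempts()]).
#'
#' @param trials Trial records for a single subject and experiment.
#' @param design Optional design; defaults are inferred from the records.
#' @param window Window length for first/last trial-window counts; defaults
#'   to 12 or the full run if shorter.
#' @return A one-row tibble.
#' @examples
#' summarize_subject(study_trials("Paddy", "exp1"))
#' summarize_subject(study_trials("Betsy", "exp3"), window = 12)
#' @export
summarize_subject <- function(trials, design = NULL, window = NULL) {
  trials <- validate_trials(trials, design)
  if (nrow(trials) == 0) abort("No trials to summarize.")
  if (dplyr::n_distinct(trials$subject_id) != 1L) {
    abort("Trials mix multiple subjects; summarize one subject at a time.")
  }
  if (dplyr::n_distinct(trials$experiment) != 1L) {
    abort("Trials mix multiple experiments.")
  }
  if (anyDuplicated(trials$trial_index) > 0L) {
    abort("Duplicate trial_index values.")
  }
  n <- nrow(trials)
  window <- as.integer(window %||% min(12L, n))
  if (window > n) abort("`window` exceeds the number of trials.")
  correct <- !is.na(trials$success_attempt)
  first <- !is.na(trials$success_attempt) & trials$success_attempt == 1L
  in_first <- trials$trial_index <= window
  in_last <- trials$trial_index > n - window
  open <- trials$condition == "target_open"
  occl <- trials$condition == "target_occluded"
  # In the barrier paradigm the chooser faces the open object and the occluded
  # one: a correct open-condition choice and an incorrect occluded-condition
  # choice are both choices of the open object.
  open_choices <- if (any(open) || any(occl)) {
    sum(correct & open) + sum(!correct & occl)
  } else {
    NA_integer_
  }
  tibble::tibble(
    subject_id = trials$subject_id[1],
    experiment = trials$experiment[1],
    n_trials = n,
    overall_correct = sum(correct),
    first_attempt_correct = sum(first),
    n_open = sum(open),
    n_occluded = sum(occl),
    correct_open = if (any(open)) sum(correct & open) else NA_integer_,
    correct_occluded = if (any(occl)) sum(correct & occl) else NA_integer_,
    window = as.integer(window),
    first_window_correct = sum(correct & in_first),
    last_window_correct = sum(correct & in_last),
    open_choices = open_choices,
    observed_mean_attempts = observed_mean_attempts(trials,
                                                    policy = "assign_set_size")
  )
}
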