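new_fetch_report <- function(subject_id, experiment, run, summary, tests,
                             conventions) {
  structure(
    list(subject_id = subject_id, experiment = experiment, run = run,
         summary = summary, tests = tests, conventions = conventions),
    class = "fetch_report"
  )
}

label_test <- function(label, test) {
  dplyr::bind_cols(tibble::tibble(label = label), tidy(test))
}

#' Analyse one subject's 3-object retrieval run
#'
#' Runs the two standard analyses of the 3-object paradigm on one subject's
#' records: the Monte-Carlo test of the mean attempt index against the chance
#' null of sequential search without replacement ([build_null()], [mc_p()]),
#' and the exact binomial test of first-attempt successes at chance 0.33
#' (smaller tail).
#'
#' @param trials One subject's trial records (one run).
#' @param design The design; defaults to the built-in 24-trial, 3-object one.
#' @param n_sims Monte-Carlo simulations for the null.
#' @param seed Seed for the null.
#' @param policy Failure policy for the observed statistic, see
#'   [observed_mean_attempts()].
#' @param exact Use the exact enumeration null instead of simulation.
#' @return A `fetch_report`; `tidy()` gives the test table, `glance()` the
#'   subject summary.
#' @examples
#' analyze_exp1(study_trials("Paddy", "exp1"), n_sims = 2000, seed = 1)
#' @export
analyze_exp1 <- function(trials, design = experiment_design("exp1"),
                         n_sims = 10000L, seed = 101L,
                         policy = "assign_set_size", exact = FALSE) {
  s <- summarize_subject(trials, design, window = min(12L, design$n_trials))
  observed <- observed_mean_attempts(trials, policy = policy)
  null <- if (exact) {
    exact_null(s$n_trials, design$set_size)
  } else {
    build_null(s$n_trials, design$set_size, n_sims = n_sims, seed = seed)
  }
  mc <- new_fetch_test("monte_carlo", p_value = mc_p(observed, null),
                       tail = "lower", k = s$overall_correct, n = s$n_trials,
                       statistic = observed,
                       note = paste0("observed mean attempts; failure policy ",
                                     policy))
  fb <- binom_pvalue(s$first_attempt_correct, s$n_trials,
                     design$chance_level, tail = "smaller")
  tests <- dplyr::bind_rows(
    label_test("mean_attempts_mc", mc),
    label_test("first_attempt_binomial", fb)
  )
  new_fetch_report(
    s$subject_id, "exp1", if ("run" %in% names(trials)) trials$run[1] else 1L,
    s, tests,
    conventions = list(chance_level = design$chance_level,
                       binomial_tail = "smaller", failure_policy = policy,
                       null_kind = null$kind,
                       n_sims = if (!exact) n_sims else NA_integer_,
                       seed = if (!exact) seed else NA_integer_)
  )
}

#' Analyse one subject's two-pair retrieval run
#'
#' Standard analyses of the two-pair paradigm (two labelled targets plus two
#' distracters at request time, chance 0.5 between the labelled objects):
#' the overall binomial, the any-labelled-object binomial (did the subject at
#' least pick a labelled object?), the pair-A vs pair-B 2x2 chi-square, and
#' the binomial on how often an incorrect retrieval was the labelled
#' non-target. The last analysis has no canonical chance level; by default
#' one labelled object among three non-targets gives `p0 = 1/3`, and the
#' result carries a caveat note.
#'
#' @param trials One subject's records, with a `pair` column for the
#'   chi-square (skipped with a note if absent).
#' @param design The design; defaults to the built-in 24-trial one.
#' @param p0_incorrect Chance level for the incorrect-retrieval analysis.
#' @return A `fetch_report`.
#' @examples
#' analyze_exp2(study_trials("Paddy", "exp2"))
#' @export
analyze_exp2 <- function(trials, design = experiment_design("exp2"),
                         p0_incorrect = 1 / 3) {
  s <- summarize_subject(trials, design, window = min(12L, design$n_trials))
  first_role <- vapply(split_attempts(trials$attempts),
                       function(a) if (length(a)) a[[1]] else "none", "")
  labelled <- first_role %in% c("target", "labelled_nontarget")
  tests <- dplyr::bind_rows(
    label_test("overall_binomial",
               binom_pvalue(s$overall_correct, s$n_trials,
                            design$chance_level, "two_sided_double")),
    label_test("labelled_binomial",
               binom_pvalue(sum(labelled), s$n_trials, design$chance_level,
                            "two_sided_double"))
  )
  if ("pair" %in% names(trials) && !anyNA(trials$pair)) {
    correct <- !is.na(trials$success_attempt)
    a <- sum(correct & trials$pair == "A")
    b <- sum(!correct & trials$pair == "A")
    cc <- sum(correct & trials$pair == "B")
    d <- sum(!correct & trials$pair == "B")
    m <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      tests <- dplyr::bind_rows(tests, label_test("pair_chisq",
                                                  chisq2x2(a, b, cc, d)))
    }
  }
  # incorrect retrievals of an object: the subject came back with something
  # other than the target (empty-handed returns are not retrievals)
  n_inc <- sum(first_role %in% c("labelled_nontarget", "distracter"))
  k_inc <- sum(first_role == "labelled_nontarget")
  if (n_inc > 0) {
    it <- binom_pvalue(k_inc, n_inc, p0_incorrect, "two_sided_double")
    it$note <- paste("chance level for incorrect retrievals is a convention",
                     "(no canonical value exists for this analysis)")
    tests <- dplyr::bind_rows(tests, label_test("incorrect_labelled_binomial",
                                                it))
  }
  new_fetch_report(
    s$subject_id, "exp2", if ("run" %in% names(trials)) trials$run[1] else 1L,
    s, tests,
    conventions = list(chance_level = design$chance_level,
                       binomial_tail = "two_sided_double",
                       p0_incorrect = p0_incorrect)
  )
}

#' Analyse one subject's barrier (visible vs occluded target) run
#'
#' Standard analyses of the two-object barrier paradigm at chance 0.5 with
#' tail-doubled two-sided binomials: overall successes; successes in the
#' target-open and target-occluded naming conditions separately; successes in
#' the first and last `window` trials (a learning contrast — with 28 trials
#' and `window = 12` the middle 4 trials belong to neither window); and the
#' preference for the object that was in the open during naming, counted over
#' all trials regardless of correctness (a diagnostic for associative
#' word-object mapping).
#'
#' @param trials One subject's records.
#' @param design The design; defaults to the built-in 28-trial one.
#' @param window Window length for the learning contrast.
#' @return A `fetch_report`.
#' @examples
#' analyze_exp3(study_trials("Betsy", "exp3"))
#' @export
analyze_exp3 <- function(trials, design = experiment_design("exp3"),
                         window = 12L) {
  s <- summarize_subject(trials, design, window = window)
  bt <- function(k, n) binom_pvalue(k, n, design$chance_level,
                                    "two_sided_double")
  tests <- dplyr::bind_rows(
    label_test("overall_binomial", bt(s$overall_correct, s$n_trials)),
    label_test("open_condition_binomial", bt(s$correct_open, s$n_open)),
    label_test("occluded_condition_binomial",
               bt(s$correct_occluded, s$n_occluded)),
    label_test("first_window_binomial", bt(s$first_window_correct, s$window)),
    label_test("last_window_binomial", bt(s$last_window_correct, s$window)),
    label_test("open_preference_binomial", bt(s$open_choices, s$n_trials))
  )
  new_fetch_report(
    s$subject_id, "exp3", if ("run" %in% names(trials)) trials$run[1] else 1L,
    s, tests,
    conventions = list(chance_level = design$chance_level,
                       binomial_tail = "two_sided_double", window = window)
  )
}

#' @export
print.fetch_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

#' @method tidy fetch_report
#' @export
tidy.fetch_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_id, experiment = x$experiment,
                   run = x$run),
    x$tests
  )
}

#' @method glance fetch_report
#' @export
glance.fetch_report <- function(x, ...) x$summary

#' Serialize an analysis report
#'
#' @param report A `fetch_report`.
#' @param format `"text"` (human-readable, p-values to 4 decimals, with the
#'   conventions that produced them), `"json"` (round-trippable via
#'   [jsonlite::fromJSON()]), or `"csv"` (one row per test).
#' @return A single character string.
#' @export
render_report <- function(report, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  conv <- report$conventions
  if (format == "json") {
    return(jsonlite::toJSON(
      list(subject_id = report$subject_id, experiment = report$experiment,
           run = report$run, summary = report$summary, tests = report$tests,
           conventions = conv),
      auto_unbox = TRUE, digits = NA, na = "null"
    ))
  }
  if (format == "csv") {
    return(readr::format_csv(tidy(report)))
  }
  lines <- c(
    sprintf("Subject %s, %s (run %s)", report$subject_id, report$experiment,
            report$run),
    sprintf("  %-28s p = %.4f%s%s",
            report$tests$label, report$tests$p_value,
            ifelse(is.na(report$tests$tail), "",
                   paste0("  [", report$tests$tail, "]")),
            ifelse(is.na(report$tests$note), "",
                   paste0("  (", report$tests$note, ")"))),
    "  conventions:",
    sprintf("    %s = %s", names(conv),
            vapply(conv, function(v) paste(format(v), collapse = ","), ""))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Analyse a full study: every subject, experiment and run
#'
#' Maps the per-paradigm analyses over all subject x experiment x run groups
#' in a trial table and binds the tidied results. With no arguments this
#' reproduces the package's built-in study table (see [study_trials()]).
#'
#' @param trials A trial tibble covering one or more subjects/experiments;
#'   a `run` column distinguishes repeated runs of the same paradigm.
#' @param n_sims,seed Monte-Carlo settings passed to [analyze_exp1()].
#' @param exact Use the exact null for the mean-attempts test.
#' @return A tibble with one row per test: subject, experiment, run, test
#'   label, inputs, tail convention and p-value.
#' @examples
#' analyze_study(study_trials("Betsy"), n_sims = 2000, seed = 1)
#' @export
analyze_study <- function(trials = study_trials(), n_sims = 10000L,
                          seed = 101L, exact = FALSE) {
  if (!"run" %in% names(trials)) trials$run <- 1L
  groups <- dplyr::distinct(trials, .data$subject_id, .data$experiment,
                            .data$run)
  purrr::pmap(groups, function(subject_id, experiment, run) {
    tr <- trials[trials$subject_id == subject_id &
                   trials$experiment == experiment & trials$run == run, ]
    rep <- switch(experiment,
      exp1 = analyze_exp1(tr, n_sims = n_sims, seed = seed, exact = exact),
      exp2 = analyze_exp2(tr),
      exp3 = analyze_exp3(tr)
    )
    tidy(rep)
  }) |>
    purrr::list_rbind()
}
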