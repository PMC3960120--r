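# Published per-subject counts from a three-experiment word-learning study
# with four label-trained Border Collies. Only aggregate counts were printed;
# the trial-level tables below are deterministic reconstructions whose
# aggregates equal every printed count.

exp1_counts <- function() {
  tibble::tribble(
    ~subject_id, ~run, ~overall, ~first_attempt,
    "Paddy", 1L, 22L, 12L,
    "Arco",  1L, 15L, 11L,
    "Arco",  2L, 19L,  6L,
    "Joey",  1L, 17L, 10L,
    "Joey",  2L, 19L, 11L,
    "Betsy", 1L, 17L, 11L,
    "Betsy", 2L, 16L,  9L
  )
}

exp3_counts <- function() {
  # preference for the open object is implied: open-correct + occluded-incorrect
  tibble::tribble(
    ~subject_id, ~overall, ~correct_open, ~correct_occluded,
    ~first_window, ~last_window,
    "Paddy", 18L,  9L, 9L,  6L, 10L,
    "Betsy", 17L, 11L, 6L,  7L,  7L,
    "Joey",  11L,  4L, 7L,  4L,  4L,
    "Arco",  15L,  9L, 6L,  7L,  7L
  )
}

fixture_labels <- function(n, offset = 0L) {
  vocab <- c("Gysi", "Hot Dog", "Gluehbirne", "Bruno", "Lumpi",
             "Regenbogenhantel", "Beetle", "Quadratschaedel", "Spirale",
             "Muente", "Heini", "Spektrum", "Snutig", "Boomer", "Harlikin",
             "Moby Dick", "Kilogramm", "Petzi", "Topolino", "Neopren",
             "Niederoesterreich", "Stechapfel", "Alfons", "Schrubka",
             "Titifax", "Columbus", "Aristotoles", "Klecksi", "Propeller",
             "Tantalus")
  sprintf("%s_%02d", vocab[((seq_len(n) - 1L + offset) %% length(vocab)) + 1L],
          seq_len(n))
}

fixture_exp1_one <- function(subject_id, run, overall, first_attempt,
                             n = 24L, set_size = 3L) {
  n_second <- overall - first_attempt
  n_fail <- n - overall
  attempts <- c(rep("target", first_attempt),
                rep("distracter;target", n_second),
                rep("distracter;distracter", n_fail))
  tibble::tibble(
    subject_id = subject_id, experiment = "exp1", run = run,
    trial_index = seq_len(n), set_size = set_size, condition = "default",
    requested_label = fixture_labels(n, offset = run * 7L),
    pair = NA_character_,
    attempts = attempts,
    success_attempt = c(rep(1L, first_attempt), rep(2L, n_second),
                        rep(NA_integer_, n_fail))
  )
}

fixture_exp2 <- function() {
  # Paddy, 24 trials among 4 objects: 7 correct (6 on pair A, 1 on pair B),
  # 11 retrievals of a labelled object overall (so 4 of the 17 incorrect
  # retrievals were the labelled non-target), pairs alternating A, B, ...
  n <- 24L
  pair <- rep(c("A", "B"), length.out = n)
  outcome <- character(n)
  assign_pair <- function(p, n_correct, n_lab) {
    idx <- which(pair == p)
    c(rep("target", n_correct), rep("labelled_nontarget", n_lab),
      rep("distracter", length(idx) - n_correct - n_lab))
  }
  outcome[pair == "A"] <- assign_pair("A", 6L, 2L)
  outcome[pair == "B"] <- assign_pair("B", 1L, 2L)
  tibble::tibble(
    subject_id = "Paddy", experiment = "exp2", run = 1L,
    trial_index = seq_len(n), set_size = 4L, condition = "default",
    requested_label = fixture_labels(n, offset = 10L),
    pair = pair,
    attempts = outcome,
    success_attempt = ifelse(outcome == "target", 1L, NA_integer_)
  )
}

# allocate `a_total` open-condition successes over windows with open-slot
# capacities `open_cap` and per-window success targets `target_w` whose
# occluded complement must fit `occ_cap`; lexicographically maximal feasible
# allocation, deterministic
allocate_open <- function(a_total, target_w, open_cap, occ_cap) {
  for (a1 in min(open_cap[1], target_w[1], a_total):0) {
    for (a2 in min(open_cap[2], target_w[2], a_total - a1):0) {
      a3 <- a_total - a1 - a2
      a <- c(a1, a2, a3)
      b <- target_w - a
      if (a3 >= 0 && a3 <= min(open_cap[3], target_w[3]) &&
          all(b >= 0) && all(b <= occ_cap)) {
        return(a)
      }
    }
  }
  abort("Infeasible windowed success allocation.")
}

fixture_exp3_one <- function(subject_id, overall, correct_open,
                             correct_occluded, first_window, last_window,
                             n = 28L, window = 12L) {
  # conditions alternate open, occluded, so every window is balanced
  condition <- rep(c("target_open", "target_occluded"), length.out = n)
  windows <- list(seq_len(window),
                  seq.int(window + 1L, n - window),
                  seq.int(n - window + 1L, n))
  target_w <- c(first_window, overall - first_window - last_window,
                last_window)
  open_cap <- vapply(windows, function(w) sum(condition[w] == "target_open"),
                     1)
  occ_cap <- vapply(windows,
                    function(w) sum(condition[w] == "target_occluded"), 1)
  a <- allocate_open(correct_open, target_w, open_cap, occ_cap)
  b <- target_w - a
  correct <- logical(n)
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    # successes fill the earliest trials of each condition within the window
    correct[head(w[condition[w] == "target_open"], a[wi])] <- TRUE
    correct[head(w[condition[w] == "target_occluded"], b[wi])] <- TRUE
  }
  stopifnot(sum(correct) == overall,
            sum(correct & condition == "target_open") == correct_open,
            sum(correct & condition == "target_occluded") == correct_occluded)
  tibble::tibble(
    subject_id = subject_id, experiment = "exp3", run = 1L,
    trial_index = seq_len(n), set_size = 2L, condition = condition,
    requested_label = fixture_labels(n, offset = 20L),
    pair = NA_character_,
    attempts = ifelse(correct, "target", "distracter"),
    success_attempt = ifelse(correct, 1L, NA_integer_)
  )
}

#' Packaged trial records reproducing the published study counts
#'
#' Trial-level records for the four subjects (Paddy, Betsy, Joey, Arco) of a
#' published three-experiment word-learning study, reconstructed from the
#' printed aggregate counts: per run of the 3-object paradigm, the number of
#' trials with the target retrieved at all and on the first attempt; for the
#' two-pair paradigm, the overall, per-pair and labelled-object counts; for
#' the barrier paradigm, the overall, per-condition and first/last-12-trial
#' window counts. Where a printed table does not constrain trial order, the
#' reconstruction is deterministic (successes earliest first, windowed counts
#' respected); analyses in this package are invariant to that ordering.
#'
#' `success_attempt` placements within exp1 runs and the assignment of
#' labelled-non-target retrievals to particular exp2 trials are synthetic in
#' exactly this sense: only their aggregates are data.
#'
#' @param subject Optional subject name to filter to.
#' @param experiment Optional experiment (`"exp1"`, `"exp2"`, `"exp3"`).
#' @param run Optional run number within `exp1` (Paddy has only run 1).
#' @return A trial tibble (see [validate_trials()]).
#' @examples
#' study_trials("Paddy", "exp1")
#' dplyr::count(study_trials(), experiment, subject_id)
#' @export
study_trials <- function(subject = NULL, experiment = NULL, run = NULL) {
  e1 <- exp1_counts() |>
    purrr::pmap(function(subject_id, run, overall, first_attempt) {
      fixture_exp1_one(subject_id, run, overall, first_attempt)
    }) |>
    purrr::list_rbind()
  e3 <- exp3_counts() |>
    purrr::pmap(function(subject_id, overall, correct_open, correct_occluded,
                         first_window, last_window) {
      fixture_exp3_one(subject_id, overall, correct_open, correct_occluded,
                       first_window, last_window)
    }) |>
    purrr::list_rbind()
  out <- dplyr::bind_rows(e1, fixture_exp2(), e3)
  if (!is.null(subject)) out <- dplyr::filter(out, .data$subject_id %in% subject)
  if (!is.null(experiment)) {
    exp <- experiment
    out <- dplyr::filter(out, .data$experiment %in% exp)
  }
  if (!is.null(run)) out <- dplyr::filter(out, .data$run %in% !!run)
  out
}
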