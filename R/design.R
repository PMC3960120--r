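#' Experiment designs for the three fetch-task paradigms
#'
#' A design bundles the structural parameters of a forced-choice retrieval
#' experiment: how many trials a subject receives, how many objects are on the
#' floor when the subject is sent to fetch, how many retrieval attempts a trial
#' allows, the chance success level of an indifferent chooser, and the
#' counterbalancing constraints the trial schedule must satisfy.
#'
#' The three built-in designs are:
#' \describe{
#'   \item{`exp1`}{24 trials, 3 objects, up to 2 retrieval attempts per trial,
#'     chance level 0.33. Target position counterbalanced over the 3 positions.}
#'   \item{`exp2`}{24 trials, 4 objects at request time (two labelled targets,
#'     two distracters), a single scored attempt, chance level 0.5 (between the
#'     two labelled objects). Trials alternate between object pair A and pair B
#'     under the constraint that the same pair never appears in more than 2
#'     consecutive trials.}
#'   \item{`exp3`}{28 trials, 2 objects, a single attempt, chance level 0.5.
#'     In exactly half of the trials the target is in the open during naming
#'     (`target_open`), in the other half it is occluded (`target_occluded`).}
#' }
#'
#' The chance level for `exp1` is 0.33 exactly, not 1/3: the first-attempt
#' binomial analyses for the 3-object design are conventionally computed at the
#' rounded value, and the two give visibly different p-values at n = 24
#' (e.g. 0.063 vs 0.068 for k = 12). Pass `chance_level = 1/3` to override.
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param n_trials,set_size,max_attempts,chance_level Optional overrides of the
#'   built-in values, e.g. a longer run of the same paradigm for simulation
#'   studies. `set_size` is the number of objects available at request time.
#' @param n_positions Number of distinct target positions to counterbalance
#'   over; defaults to `set_size`.
#'
#' @return An object of class `fetch_design`: a list with elements
#'   `experiment`, `n_trials`, `set_size`, `max_attempts`, `chance_level`,
#'   `n_positions`, `conditions` (per-condition trial counts, `exp3` only) and
#'   `pair_balance` (`exp2` only).
#'
#' @examples
#' experiment_design("exp1")
#' experiment_design("exp1", n_trials = 240) # extended run for power studies
#' @export
experiment_design <- function(experiment = c("exp1", "exp2", "exp3"),
                              n_trials = NULL, set_size = NULL,
                              max_attempts = NULL, chance_level = NULL,
                              n_positions = NULL) {
  experiment <- match.arg(experiment)
  base <- switch(experiment,
    exp1 = list(n_trials = 24L, set_size = 3L, max_attempts = 2L,
                chance_level = 0.33),
    exp2 = list(n_trials = 24L, set_size = 4L, max_attempts = 1L,
                chance_level = 0.5),
    exp3 = list(n_trials = 28L, set_size = 2L, max_attempts = 1L,
                chance_level = 0.5)
  )
  d <- list(
    experiment = experiment,
    n_trials = as.integer(n_trials %||% base$n_trials),
    set_size = as.integer(set_size %||% base$set_size),
    max_attempts = as.integer(max_attempts %||% base$max_attempts),
    chance_level = chance_level %||% base$chance_level
  )
  d$n_positions <- as.integer(n_positions %||% d$set_size)
  if (d$n_trials < 1L) abort("`n_trials` must be positive.")
  if (d$set_size < 2L) abort("`set_size` must be at least 2.")
  if (d$max_attempts < 1L) abort("`max_attempts` must be at least 1.")
  if (d$chance_level <= 0 || d$chance_level >= 1) {
    abort("`chance_level` must be strictly between 0 and 1.")
  }
  if (experiment == "exp3") {
    if (d$n_trials %% 2L != 0L) {
      abort("exp3 requires an even `n_trials` so conditions can be balanced.")
    }
    d$conditions <- c(target_open = d$n_trials %/% 2L,
                      target_occluded = d$n_trials %/% 2L)
  }
  if (experiment == "exp2") {
    if (d$n_trials %% 2L != 0L) {
      abort("exp2 requires an even `n_trials` so pairs can be balanced.")
    }
    d$pair_balance <- c(A = d$n_trials %/% 2L, B = d$n_trials %/% 2L)
  }
  structure(d, class = "fetch_design")
}

#' @export
print.fetch_design <- function(x, ...) {
  cat("<fetch_design> ", x$experiment, "\n", sep = "")
  cat("  trials: ", x$n_trials, ", set size: ", x$set_size,
      ", max attempts: ", x$max_attempts,
      ", chance level: ", format(x$chance_level), "\n", sep = "")
  if (!is.null(x$conditions)) {
    cat("  conditions: ",
        paste(names(x$conditions), x$conditions, sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$pair_balance)) {
    cat("  pairs: ",
        paste(names(x$pair_balance), x$pair_balance, sep = " = ",
              collapse = ", "),
        " (same pair in at most 2 consecutive trials)\n", sep = "")
  }
  invisible(x)
}

#' Read an experiment design from a YAML-like key:value file
#'
#' Reads a plain-text configuration with one `key: value` per line (a subset of
#' YAML sufficient for designs) and builds the corresponding design via
#' [experiment_design()]. Recognised keys are `experiment`, `n_trials`,
#' `set_size`, `max_attempts`, `chance_level` and `n_positions`; `experiment`
#' is required.
#'
#' @param file Path to the configuration file.
#' @return A `fetch_design`.
#' @export
read_design <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed design line: '%s'.", lines[which(bad)[1]]))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  cfg <- as.list(setNames(vals, keys))
  if (is.null(cfg$experiment)) abort("Design file must set `experiment`.")
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  experiment_design(
    experiment = cfg$experiment,
    n_trials = num(cfg$n_trials),
    set_size = num(cfg$set_size),
    max_attempts = num(cfg$max_attempts),
    chance_level = num(cfg$chance_level),
    n_positions = num(cfg$n_positions)
  )
}
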