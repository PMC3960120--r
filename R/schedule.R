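#' Generate a counterbalanced trial schedule
#'
#' Produces per-trial settings — target position, naming condition and object
#' pair — satisfying the design's counterbalancing constraints:
#'
#' * the target position is balanced over the `n_positions` positions
#'   (requires `n_trials` divisible by `n_positions`);
#' * for the two-pair paradigm, pairs A and B each occupy half the trials and
#'   the same pair never appears in more than 2 consecutive trials;
#' * for the two-condition paradigm, `target_open` and `target_occluded` each
#'   occupy exactly half the trials.
#'
#' Schedules are drawn by rejection sampling from random balanced
#' permutations; generation is deterministic for a fixed seed and errors after
#' a bounded retry budget if the constraints cannot be met.
#'
#' @param design A [experiment_design()].
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param max_tries Retry budget for the rejection sampler.
#' @return A tibble with columns `trial_index`, `target_position`,
#'   `condition` and `pair` (`NA` where a dimension does not apply).
#' @examples
#' generate_schedule(experiment_design("exp3"), seed = 1)
#' @export
generate_schedule <- function(design, seed, max_tries = 1000L) {
  stopifnot(inherits(design, "fetch_design"))
  withr::with_seed(seed, schedule_draw(design, max_tries))
}

# draws one schedule from the current RNG stream (simulators embed this in
# their own seeded block so schedule and choices share one stream)
schedule_draw <- function(design, max_tries = 1000L) {
  n <- design$n_trials
  if (n %% design$n_positions != 0L) {
    abort("`n_trials` must be divisible by `n_positions` to counterbalance.")
  }
  position <- sample(rep(seq_len(design$n_positions),
                         n %/% design$n_positions))
  condition <- if (design$experiment == "exp3") {
    sample(rep(c("target_open", "target_occluded"), each = n %/% 2L))
  } else {
    rep("default", n)
  }
  pair <- rep(NA_character_, n)
  if (design$experiment == "exp2") {
    pair <- sample_run_constrained(c("A", "B"), n %/% 2L,
                                   max_run = 2L, max_tries = max_tries)
  }
  tibble::tibble(
    trial_index = seq_len(n),
    target_position = as.integer(position),
    condition = condition,
    pair = pair
  )
}

# Balanced sequence over `values` (each n_each times) with no run longer than
# max_run, by rejection sampling.
sample_run_constrained <- function(values, n_each, max_run, max_tries) {
  for (i in seq_len(max_tries)) {
    s <- sample(rep(values, each = n_each))
    if (max(rle(s)$lengths) <= max_run) return(s)
  }
  abort(sprintf(
    "Could not satisfy the run-length constraint within %d tries.", max_tries))
}

#' Check a schedule against its design's counterbalancing constraints
#'
#' @param schedule A tibble from [generate_schedule()].
#' @param design The design the schedule was generated for.
#' @return `TRUE` if every constraint holds, otherwise `FALSE`.
#' @export
check_schedule <- function(schedule, design) {
  n <- design$n_trials
  if (nrow(schedule) != n) return(FALSE)
  pos_counts <- table(factor(schedule$target_position,
                             levels = seq_len(design$n_positions)))
  if (any(pos_counts != n %/% design$n_positions)) return(FALSE)
  if (design$experiment == "exp3") {
    cc <- table(factor(schedule$condition,
                       levels = c("target_open", "target_occluded")))
    if (any(cc != n %/% 2L)) return(FALSE)
  }
  if (design$experiment == "exp2") {
    pc <- table(factor(schedule$pair, levels = c("A", "B")))
    if (any(pc != n %/% 2L)) return(FALSE)
    if (max(rle(schedule$pair)$lengths) > 2L) return(FALSE)
  }
  TRUE
}
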