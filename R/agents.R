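#' Specify a generative learner agent
#'
#' Agents formalise the competing strategies a subject could bring to a
#' fetch task, and drive the synthetic-data simulators:
#'
#' \describe{
#'   \item{`random`}{chooses uniformly among the available objects — the
#'     chance model.}
#'   \item{`knower`}{a referential learner: puts probability `theta` on the
#'     true referent of the requested label, the remainder uniform on the
#'     other objects, regardless of what was visible during naming.}
#'   \item{`associative`}{maps the label to whatever object was visible
#'     during naming: puts `theta` on the visible object. In the barrier
#'     paradigm this is the target when the target was in the open but the
#'     non-target when the target was occluded, so a strong associative agent
#'     is right in one condition and wrong in the other.}
#'   \item{`enhancement`}{local enhancement: mixes a uniform choice with
#'     extra weight `w` on the object(s) at the location(s) the human
#'     attended during naming (the target's location; in the two-pair
#'     paradigm, both labelled objects). Weights are `1 + w` on attended
#'     objects and 1 elsewhere, normalised; `w = Inf` concentrates all mass
#'     uniformly on the attended set.}
#'   \item{`learner`}{a knower whose accuracy ramps logistically over the
#'     session from `theta_start` to `theta_end` with steepness `rate`
#'     (per-trial logistic slope, centred mid-session) — a subject that needs
#'     experience with the paradigm before the referential cue is used.}
#' }
#'
#' @param kind Agent kind, see above.
#' @param theta Accuracy parameter in `[0, 1]` (`knower`, `associative`).
#' @param w Enhancement weight, `>= 0` or `Inf` (`enhancement`).
#' @param theta_start,theta_end Start and end accuracies of the `learner`
#'   ramp, in `[0, 1]`.
#' @param rate Logistic steepness of the `learner` ramp (per trial);
#'   nonnegative so that accuracy is monotone from `theta_start` to
#'   `theta_end`.
#' @param theta_by_pair Optional named vector `c(A = ..., B = ...)` giving a
#'   per-pair accuracy for the two-pair paradigm (`knower` only); models an
#'   imbalance between the pair learned first and the pair learned later.
#' @return A `fetch_agent` object.
#' @examples
#' agent_spec("knower", theta = 0.8)
#' agent_spec("learner", theta_start = 0.5, theta_end = 0.95, rate = 0.5)
#' @export
agent_spec <- function(kind = c("random", "knower", "associative",
                                "enhancement", "learner"),
                       theta = NULL, w = NULL,
                       theta_start = NULL, theta_end = NULL, rate = 0.5,
                       theta_by_pair = NULL) {
  kind <- match.arg(kind)
  in01 <- function(x) !is.null(x) && !is.na(x) && x >= 0 && x <= 1
  if (kind %in% c("knower", "associative")) {
    if (!in01(theta)) abort(sprintf("`%s` agents need `theta` in [0, 1].", kind))
  }
  if (kind == "enhancement") {
    if (is.null(w) || is.na(w) || w < 0) {
      abort("`enhancement` agents need `w` >= 0 (Inf allowed).")
    }
  }
  if (kind == "learner") {
    if (!in01(theta_start) || !in01(theta_end)) {
      abort("`learner` agents need `theta_start` and `theta_end` in [0, 1].")
    }
    if (is.na(rate) || rate < 0) abort("`rate` must be nonnegative.")
  }
  if (!is.null(theta_by_pair)) {
    if (kind != "knower") abort("`theta_by_pair` applies to `knower` agents.")
    if (!all(c("A", "B") %in% names(theta_by_pair))) {
      abort("`theta_by_pair` must name pairs A and B.")
    }
  }
  structure(
    list(kind = kind, theta = theta, w = w, theta_start = theta_start,
         theta_end = theta_end, rate = rate, theta_by_pair = theta_by_pair),
    class = "fetch_agent"
  )
}

#' @export
print.fetch_agent <- function(x, ...) {
  pars <- switch(x$kind,
    random = "",
    knower = paste0("theta = ", format(x$theta)),
    associative = paste0("theta = ", format(x$theta)),
    enhancement = paste0("w = ", format(x$w)),
    learner = sprintf("theta %s -> %s, rate %s", format(x$theta_start),
                      format(x$theta_end), format(x$rate))
  )
  cat("<fetch_agent> ", x$kind, if (nzchar(pars)) paste0(" (", pars, ")"),
      "\n", sep = "")
  invisible(x)
}

agent_theta_at <- function(agent, trial_index, n_trials) {
  mid <- (n_trials + 1) / 2
  agent$theta_start + (agent$theta_end - agent$theta_start) *
    stats::plogis(agent$rate * (trial_index - mid))
}

roles_for <- function(experiment, set_size) {
  switch(experiment,
    exp1 = c("target", rep("distracter", set_size - 1L)),
    exp2 = c("target", "labelled_nontarget",
             rep("distracter", set_size - 2L)),
    exp3 = c("target", rep("distracter", set_size - 1L))
  )
}

mass_on <- function(k, idx, p) {
  out <- rep((1 - p) / (k - length(idx)), k)
  out[idx] <- p / length(idx)
  out
}

#' Choice probabilities of an agent in a trial context
#'
#' The probability with which an agent picks each available object on its
#' first retrieval attempt, given the trial context: the roles on offer, the
#' naming condition, and (for ramping learners) the position of the trial in
#' the session.
#'
#' @param agent A [agent_spec()].
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"` — determines the role
#'   layout of the object array.
#' @param set_size Number of objects available.
#' @param condition Naming condition (`"default"`, `"target_open"`,
#'   `"target_occluded"`).
#' @param trial_index,n_trials Trial position, used by `learner` agents.
#' @param pair Requested pair (`"A"`/`"B"`), used with `theta_by_pair`.
#' @return A named probability vector over the available roles, summing to 1.
#' @examples
#' choice_probs(agent_spec("random"), "exp1")
#' choice_probs(agent_spec("associative", theta = 0.9), "exp3",
#'              condition = "target_occluded")
#' @export
choice_probs <- function(agent, experiment, set_size = NULL,
                         condition = "default", trial_index = 1L,
                         n_trials = 1L, pair = NULL) {
  stopifnot(inherits(agent, "fetch_agent"))
  set_size <- set_size %||% switch(experiment, exp1 = 3L, exp2 = 4L, exp3 = 2L)
  if (set_size < 2) abort("A choice context needs at least 2 objects.")
  roles <- roles_for(experiment, set_size)
  k <- length(roles)
  target_idx <- 1L
  # object visible during naming: the target, unless it was occluded while a
  # non-target was in the open
  visible_idx <- if (identical(condition, "target_occluded")) 2L else 1L
  # location(s) the human attended during naming: the target's; in the
  # two-pair paradigm both labelled objects were attended over the session
  attended_idx <- if (experiment == "exp2") c(1L, 2L) else 1L
  p <- switch(agent$kind,
    random = rep(1 / k, k),
    knower = {
      th <- agent$theta
      if (!is.null(agent$theta_by_pair) && !is.null(pair)) {
        th <- unname(agent$theta_by_pair[[pair]])
      }
      mass_on(k, target_idx, th)
    },
    associative = mass_on(k, visible_idx, agent$theta),
    enhancement = {
      if (is.infinite(agent$w)) {
        mass_on(k, attended_idx, 1)
      } else {
        wts <- rep(1, k)
        wts[attended_idx] <- 1 + agent$w
        wts / sum(wts)
      }
    },
    learner = mass_on(k, target_idx,
                      agent_theta_at(agent, trial_index, n_trials))
  )
  setNames(p, roles)
}

# sample one index per row of a probability matrix
sample_rows <- function(p) {
  cp <- t(apply(p, 1L, cumsum))
  u <- runif(nrow(p))
  as.integer(rowSums(u > cp) + 1L)
}

sim_labels <- function(n) {
  vocab <- c("Gysi", "Bruno", "Lumpi", "Beetle", "Spirale", "Muente",
             "Boomer", "Petzi", "Topolino", "Alfons", "Klecksi", "Propeller",
             "Columbus", "Torpedo", "Rabe", "Arabella", "Miranda", "Knautschli")
  sprintf("%s_%02d", rep_len(vocab, n), seq_len(n))
}

sim_trials_impl <- function(agent, design, subject_id) {
  sch <- schedule_draw(design)
  n <- design$n_trials
  roles <- roles_for(design$experiment, design$set_size)
  k <- length(roles)
  # first-attempt choice probabilities, one row per trial; only learner
  # agents vary with trial_index, so other agents need one row per distinct
  # (condition, pair) context
  if (agent$kind == "learner") {
    p <- t(vapply(seq_len(n), function(i) {
      choice_probs(agent, design$experiment, design$set_size,
                   condition = sch$condition[i], trial_index = i,
                   n_trials = n, pair = sch$pair[i])
    }, numeric(k)))
  } else {
    key <- paste(sch$condition, sch$pair)
    uk <- unique(key)
    lut <- vapply(uk, function(kk) {
      i <- match(kk, key)
      choice_probs(agent, design$experiment, design$set_size,
                   condition = sch$condition[i], trial_index = i,
                   n_trials = n, pair = sch$pair[i])
    }, numeric(k))
    p <- t(lut)[match(key, uk), , drop = FALSE]
  }
  first <- sample_rows(p)
  attempts <- roles[first]
  success <- ifelse(first == 1L, 1L, NA_integer_)
  if (design$max_attempts >= 2L) {
    # a refused first object is set aside; the agent re-chooses among the
    # remaining objects with the same preferences, renormalised
    retry <- which(first != 1L)
    if (length(retry) > 0) {
      p2 <- p[retry, , drop = FALSE]
      p2[cbind(seq_along(retry), first[retry])] <- 0
      p2 <- p2 / rowSums(p2)
      second <- sample_rows(p2)
      attempts[retry] <- paste(attempts[retry], roles[second], sep = ";")
      success[retry][second == 1L] <- 2L
    }
  }
  tibble::tibble(
    subject_id = subject_id,
    experiment = design$experiment,
    run = 1L,
    trial_index = seq_len(n),
    set_size = design$set_size,
    condition = sch$condition,
    requested_label = sim_labels(n),
    pair = sch$pair,
    attempts = attempts,
    success_attempt = success
  )
}

#' Simulate fetch-task trials under an agent model
#'
#' Generates a full session of synthetic trial records for a given design and
#' agent: a counterbalanced schedule is drawn, the agent's first choice on
#' each trial follows [choice_probs()], and where the design allows a second
#' attempt a refused object is set aside and the agent re-chooses among the
#' remaining objects with renormalised preferences. Output passes
#' [validate_trials()] and [check_schedule()]'s constraints.
#'
#' `simulate_exp1()`, `simulate_exp2()` and `simulate_exp3()` are
#' design-checked shorthands for the three built-in paradigms.
#'
#' @param agent A [agent_spec()].
#' @param design A [experiment_design()].
#' @param seed Integer seed; simulation is deterministic per seed.
#' @param subject_id Subject identifier written into the records.
#' @return A trial tibble (see [validate_trials()] for the schema).
#' @examples
#' simulate_exp1(agent_spec("knower", theta = 0.8),
#'               experiment_design("exp1"), seed = 1)
#' @export
simulate_trials <- function(agent, design, seed, subject_id = "sim") {
  stopifnot(inherits(agent, "fetch_agent"), inherits(design, "fetch_design"))
  withr::with_seed(seed, sim_trials_impl(agent, design, subject_id))
}

#' @rdname simulate_trials
#' @export
simulate_exp1 <- function(agent, design = experiment_design("exp1"), seed,
                          subject_id = "sim") {
  if (design$experiment != "exp1") abort("`design` must be an exp1 design.")
  simulate_trials(agent, design, seed, subject_id)
}

#' @rdname simulate_trials
#' @export
simulate_exp2 <- function(agent, design = experiment_design("exp2"), seed,
                          subject_id = "sim") {
  if (design$experiment != "exp2") abort("`design` must be an exp2 design.")
  simulate_trials(agent, design, seed, subject_id)
}

#' @rdname simulate_trials
#' @export
simulate_exp3 <- function(agent, design = experiment_design("exp3"), seed,
                          subject_id = "sim") {
  if (design$experiment != "exp3") abort("`design` must be an exp3 design.")
  simulate_trials(agent, design, seed, subject_id)
}
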