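#' Plot a Monte-Carlo or exact chance null
#'
#' Histogram (Monte-Carlo) or needle plot (exact) of the null distribution of
#' the mean attempt index, with an optional observed value marked; the
#' p-value of the mean-attempts test is the mass at or left of the mark.
#'
#' @param object A `fetch_null`.
#' @param observed Optional observed mean attempt index to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(build_null(24, 3, n_sims = 1000, seed = 1), observed = 38 / 24)
#' @method autoplot fetch_null
#' @export
autoplot.fetch_null <- function(object, observed = NULL, ...) {
  d <- tidy(object)
  p <- if (object$kind == "monte_carlo") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_attempts)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_attempts,
                                    y = .data$prob)) +
      ggplot2::geom_col(width = 1 / (2 * object$n_trials), fill = "grey40")
  }
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red3",
                                 linetype = 2)
  }
  p +
    ggplot2::labs(
      x = "mean attempt index per run",
      y = if (object$kind == "monte_carlo") "simulated runs" else "probability",
      title = sprintf("Chance null: %d trials, %d objects (%s)",
                      object$n_trials, object$set_size, object$kind)
    ) +
    ggplot2::theme_minimal()
}

#' Plot power estimates over knower accuracy
#'
#' Rejection-rate curve from [power_curve()] with pointwise 2 Monte-Carlo
#' standard-error ribbons and the nominal level as a reference line.
#'
#' @param object A `fetch_power` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fetch_power
#' @export
autoplot.fetch_power <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$rejection_rate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$rejection_rate - 2 * .data$mc_se),
                   ymax = pmin(1, .data$rejection_rate + 2 * .data$mc_se)),
      fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = 3) +
    ggplot2::labs(x = "knower accuracy (theta)", y = "rejection rate",
                  title = unique(d$test)) +
    ggplot2::theme_minimal()
}

#' Plot a subject's per-window success counts
#'
#' Bar chart of first/last-window correct-retrieval counts from a subject
#' summary, a quick visual of the learning contrast.
#'
#' @param trials One subject's trial records.
#' @param window Window length.
#' @return A ggplot object.
#' @export
plot_windows <- function(trials, window = 12L) {
  s <- summarize_subject(trials, window = window)
  d <- tibble::tibble(
    window = factor(c("first", "last"), levels = c("first", "last")),
    correct = c(s$first_window_correct, s$last_window_correct),
    n = s$window
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$correct)) +
    ggplot2::geom_col(fill = "grey50") +
    ggplot2::geom_hline(yintercept = s$window / 2, linetype = 2) +
    ggplot2::labs(x = NULL, y = sprintf("correct of %d", s$window),
                  title = sprintf("%s (%s): first vs last %d trials",
                                  s$subject_id, s$experiment, window)) +
    ggplot2::theme_minimal()
}
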