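#' Tidy a simulation result
#'
#' @param x A `chaining_sim`.
#' @param type `"attempts"` (default, one row per attempt),
#'   `"transitions"` (per-step trace), `"snapshots"` (value-table
#'   snapshots), `"values"` (final `v` and `w` tables, long).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.chaining_sim <- function(x, type = c("attempts", "transitions",
                                          "snapshots", "values"), ...) {
  type <- match.arg(type)
  switch(type,
    attempts = x$attempts,
    transitions = x$transitions %||%
      abort("No transitions recorded; rerun with record = \"transitions\"."),
    snapshots = x$snapshots %||%
      abort("No snapshots recorded; rerun with snapshot_every set."),
    values = {
      v <- x$v
      v$table <- "v"
      w <- x$w[, c("observation", "value")]
      w$behaviour <- NA_character_
      w$table <- "w"
      dplyr::bind_rows(v, w)[, c("table", "observation", "behaviour",
                                 "value")]
    })
}

#' One-row summary of a simulation
#'
#' @param x A `chaining_sim`.
#' @param ... Unused.
#' @return Tibble with attempt/step counts, overall and final (trailing
#'   100 attempts) reward rates, total collected value and the seed.
#' @export
glance.chaining_sim <- function(x, ...) {
  att <- x$attempts
  tibble::tibble(
    n_attempts = nrow(att),
    n_steps = sum(att$steps),
    reward_rate = mean(att$reached_reward),
    final_reward_rate = mean(tail(att$reached_reward, 100)),
    total_u = sum(att$total_u),
    capped_attempts = sum(att$ended == "cap"),
    seed = x$seed %||% NA_integer_)
}

#' Tidy oracle values
#'
#' @param x An `oracle_values`.
#' @param type `"w"` for per-state expected future value, `"v"` for
#'   state-behaviour values.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oracle_values <- function(x, type = c("w", "v"), ...) {
  type <- match.arg(type)
  if (type == "w") {
    tibble::tibble(state = names(x$w_star), w_star = as.numeric(x$w_star))
  } else {
    x$v_star
  }
}

#' One-row summary of oracle values
#' @param x An `oracle_values`.
#' @param ... Unused.
#' @return Tibble with solver method, Bellman residual and state count.
#' @export
glance.oracle_values <- function(x, ...) {
  tibble::tibble(method = x$method, residual = x$residual,
                 n_states = length(x$w_star))
}

#' Plot a simulation's learning curve
#'
#' Trailing-window reward rate (and, where the task has more than two
#' states, the running highest state reached) against attempt number.
#'
#' @param object A `chaining_sim`.
#' @param window Trailing window (attempts).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chaining_sim <- function(object, window = 50, ...) {
  df <- dplyr::bind_rows(
    running_statistic(object, "reward_rate", window = window),
    running_statistic(object, "highest_state", window = window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attempt, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "attempt", y = NULL,
                  title = "Learning curve") +
    ggplot2::theme_minimal()
}

#' Plot a learning-time scaling study
#'
#' Mean attempts-to-criterion against sequence length on a logarithmic
#' vertical axis, one line per entry pattern, with replicate points.
#'
#' @param object A `learning_time_study` tibble (rows of replicates),
#'   possibly several patterns bound together.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_time_study <- function(object, ...) {
  summ <- summarise_learning_times(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$l, y = .data$mean,
                                     colour = .data$pattern)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object,
                        ggplot2::aes(y = .data$attempts), alpha = 0.3,
                        size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sequence length l", y = "attempts to criterion",
                  title = "Learning time by entry pattern") +
    ggplot2::theme_minimal()
}
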