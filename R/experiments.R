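#' Learning criterion
#'
#' Operationalises "having learned a task" as reaching the reward in at
#' least a proportion `threshold` of the trailing `window` attempts. The
#' default (75% of the trailing 20 attempts) sits between the 70–80%
#' criteria used in the animal sequence-learning studies the model is
#' compared against.
#'
#' @param window Trailing window length in attempts (>= 1).
#' @param threshold Required proportion of reward-reaching attempts in the
#'   window, in `(0, 1]`.
#' @return A `learning_criterion` list.
#' @export
learning_criterion <- function(window = 20, threshold = 0.75) {
  if (window < 1) abort("`window` must be >= 1.")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  structure(list(window = as.integer(window), threshold = threshold),
            class = "learning_criterion")
}

# first attempt index at which the trailing-window criterion holds, NA if
# never; `ok` is the per-attempt reward indicator
first_criterion_attempt <- function(ok, criterion) {
  w <- criterion$window
  if (length(ok) < w) return(NA_integer_)
  rm <- running_mean(as.numeric(ok), w)
  idx <- which(seq_along(ok) >= w & rm >= criterion$threshold)
  if (length(idx)) idx[1] else NA_integer_
}

#' Attempts needed to learn a task
#'
#' Simulates until the learning criterion is first met (the first attempt
#' whose trailing window satisfies it) or until `cap` attempts, whichever
#' comes first. When a training-protocol hook is supplied, the criterion
#' additionally requires the protocol to have run to completion (entry back
#' at the start for backward chaining; reward frontier at the true reward
#' for forward chaining).
#'
#' @param bundle A [preset_bundle][chain_task()] or [task_spec()].
#' @param criterion A [learning_criterion()].
#' @param seed Integer seed.
#' @param cap Attempt cap (>= 1). Capped runs are flagged, never silently
#'   reported as finite learning times.
#' @param hook Optional protocol hook ([backward_chaining_protocol()],
#'   [forward_chaining_protocol()]).
#' @param agent Optional [agent_config()] override.
#' @param chunk Attempts per engine call between criterion checks (with a
#'   hook the loop runs attempt by attempt).
#' @return One-row tibble: `attempts`, `capped`, `seed`.
#' @export
attempts_to_learn <- function(bundle, criterion = learning_criterion(),
                              seed = NULL, cap = 100000, hook = NULL,
                              agent = NULL, chunk = 1000) {
  if (cap < 1) abort("`cap` must be >= 1.")
  task <- as_task(bundle)
  if (inherits(bundle, "preset_bundle")) agent <- agent %||% bundle$agent
  agent <- agent %||% agent_config()
  if (!is.null(seed)) set.seed(seed)

  ct <- compile_task(task)
  ag <- compile_agent(ct, agent)
  proto_env <- if (!is.null(hook)) attr(hook, "env")
  reached <- logical(0)
  done <- 0L
  found <- NA_integer_
  complete_at <- if (is.null(proto_env)) 0L else NA_integer_

  while (done < cap && is.na(found)) {
    nb <- if (is.null(hook)) min(chunk, cap - done) else 1L
    if (!is.null(hook)) {
      hook(list(task = ct, agent = ag, attempt = done + 1L,
                reached = reached))
    }
    res <- run_engine(nb, ct, ag, max_steps = 10000, reset_on_start = TRUE,
                      record = FALSE, attempt_offset = done, use_cpp = TRUE)
    reached <- c(reached, res$reached == 1L)
    done <- done + nb
    if (!is.null(proto_env) && is.na(complete_at) &&
        isTRUE(proto_env$complete)) {
      complete_at <- done
    }
    if (!is.na(complete_at)) {
      # criterion may only be satisfied by windows ending after protocol
      # completion
      cand <- first_criterion_attempt(reached, criterion)
      if (!is.na(cand) && cand >= complete_at) {
        found <- cand
      } else if (!is.na(cand)) {
        # search later windows
        w <- criterion$window
        rm <- running_mean(as.numeric(reached), w)
        idx <- which(seq_along(reached) >= max(w, complete_at) &
                       rm >= criterion$threshold)
        if (length(idx)) found <- idx[1]
      }
    }
  }
  tibble::tibble(attempts = ifelse(is.na(found), as.integer(cap),
                                   as.integer(found)),
                 capped = is.na(found),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Attempts until the reward is first reached
#'
#' The number of attempts before the reward is found for the first time —
#' the quantity that makes start-entry chains exponentially hard: the
#' reward must initially be found by chance, which takes about `m^l`
#' attempts under uniform choice. Use `beta = 0` (the default agent) to
#' keep choice uniform throughout the search.
#'
#' @param bundle A [preset_bundle][chain_task()] or [task_spec()].
#' @param seed Integer seed.
#' @param cap Attempt cap.
#' @param agent Agent configuration; default a `beta = 0` (uniform-choice)
#'   agent.
#' @return One-row tibble: `attempts`, `capped`, `seed`.
#' @export
attempts_to_first_reward <- function(bundle, seed = NULL, cap = 100000,
                                     agent = agent_config(beta = 0)) {
  task <- as_task(bundle)
  if (!is.null(seed)) set.seed(seed)
  ct <- compile_task(task)
  ag <- compile_agent(ct, agent)
  done <- 0L
  found <- NA_integer_
  while (done < cap && is.na(found)) {
    nb <- min(1000L, cap - done)
    res <- run_engine(nb, ct, ag, max_steps = 10000, reset_on_start = TRUE,
                      record = FALSE, attempt_offset = done, use_cpp = TRUE)
    hit <- which(res$reached == 1L)
    if (length(hit)) found <- done + hit[1]
    done <- done + nb
  }
  tibble::tibble(attempts = ifelse(is.na(found), as.integer(cap),
                                   as.integer(found)),
                 capped = is.na(found),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Closed-form learning-time scaling laws
#'
#' The expected order of magnitude of the number of trials needed to learn
#' an `l`-step sequence with `m` behaviours per step, as a function of the
#' entry pattern, where `a` is the number of trials required to learn one
#' rewarded action:
#' \describe{
#'   \item{`start`}{always entering at the first state: exponential,
#'     `a * m^l`;}
#'   \item{`random`}{entering at a uniformly random state: quadratic,
#'     `a * (m/2) * l * (l+1)`;}
#'   \item{`highest_unlearned`}{backward chaining (entry at the highest
#'     state not yet learned): linear, `a * l * m`;}
#'   \item{`forward`}{forward chaining with an advancing reward frontier:
#'     linear, `a * l * m`;}
#'   \item{`favourable_exit`}{mistakes that never lose progress:
#'     `m * l * (l+1) / 2` time steps.}
#' }
#'
#' @param pattern Entry pattern name (see above).
#' @param a Trials to learn one rewarded action.
#' @param m Repertoire size.
#' @param l Sequence length.
#' @return Numeric expected learning time (vectorised over `l`).
#' @export
#' @examples
#' formula_learning_time("start", a = 1, m = 10, l = 4)  # 10000
formula_learning_time <- function(pattern = c("start", "random",
                                              "highest_unlearned", "forward",
                                              "favourable_exit"),
                                  a = 1, m, l) {
  pattern <- match.arg(pattern)
  if (any(c(a, m, l) <= 0)) abort("All arguments must be positive.")
  switch(pattern,
         start = a * m^l,
         random = a * (m / 2) * l * (l + 1),
         highest_unlearned = a * l * m,
         forward = a * l * m,
         favourable_exit = m * l * (l + 1) / 2)
}

#' Number of candidate behaviour sequences
#'
#' A repertoire of `m` behaviours yields `m^l` sequences of length `l`
#' among which a learner must locate the functional one (about 100 million
#' for the 40-behaviour, 5-step nut-cracking task).
#'
#' @param m Repertoire size.
#' @param l Sequence length.
#' @return `m^l`.
#' @export
sequence_count <- function(m, l) {
  if (any(c(m, l) <= 0)) abort("All arguments must be positive.")
  m^l
}

#' Sequence-space reduction from restricting the repertoire
#'
#' Cutting the behaviours tried in each state to a fraction `fraction` of
#' the repertoire reduces the number of candidate sequences of length `l`
#' to `fraction^l` of the original (halving: ~13% at `l = 3`, ~6% at
#' `l = 4`), which is how genetic predispositions make longer sequences
#' learnable.
#'
#' @param l Sequence length.
#' @param fraction Fraction of the repertoire retained (default one half).
#' @return The remaining fraction of candidate sequences, `fraction^l`.
#' @export
repertoire_reduction <- function(l, fraction = 0.5) {
  if (any(l <= 0) || fraction <= 0 || fraction > 1) {
    abort("Need l > 0 and fraction in (0, 1].")
  }
  fraction^l
}

#' Learning-time scaling study
#'
#' Measures attempts-to-criterion across sequence lengths for a given entry
#' pattern, with seeded replicates: `"start"` (always enter at state 0),
#' `"random"` (uniform random entry), `"backward"` and `"forward"`
#' (training protocols). Every replicate's seed is recorded.
#'
#' @param pattern One of `"start"`, `"random"`, `"backward"`, `"forward"`,
#'   or a numeric `p` in `(0, 1)` for the mixed entry family.
#' @param l_values Two or more sequence lengths.
#' @param m Repertoire size.
#' @param replicates Replicates per `l` (>= 1).
#' @param seed Master seed from which replicate seeds are derived.
#' @param cap Attempt cap per replicate.
#' @param criterion A [learning_criterion()].
#' @param agent Agent configuration (default `alpha_v = alpha_w = 0.1`,
#'   `beta = 5`, the chain-task recommendation).
#' @param b,c Chain reward and cost.
#' @return A tibble of class `learning_time_study`: one row per replicate
#'   with `pattern`, `l`, `m`, `replicate`, `seed`, `attempts`, `capped`.
#' @seealso [summarise_learning_times()], [formula_learning_time()]
#' @export
learning_time_study <- function(pattern, l_values, m, replicates = 10,
                                seed = 1, cap = 100000,
                                criterion = learning_criterion(),
                                agent = agent_config(alpha_v = 0.1,
                                                     alpha_w = 0.1,
                                                     beta = 5),
                                b = 5, c = 0.2) {
  if (length(l_values) < 2) abort("Provide at least two values of `l`.")
  p_num <- suppressWarnings(as.numeric(pattern))
  seeds <- derive_seeds(seed, length(l_values) * replicates)
  out <- list()
  i <- 0L
  for (l in l_values) {
    for (rep in seq_len(replicates)) {
      i <- i + 1L
      p_entry <- if (!is.na(p_num)) p_num else {
        if (pattern == "random") 1 else 0
      }
      bundle <- chain_task(l = l, m = m, b = b, c = c, p = p_entry,
                           agent = agent)
      hook <- switch(as.character(pattern),
                     backward = backward_chaining_protocol(bundle),
                     forward = forward_chaining_protocol(bundle, criterion),
                     NULL)
      res <- attempts_to_learn(bundle, criterion, seed = seeds[i], cap = cap,
                               hook = hook)
      out[[i]] <- tibble::tibble(pattern = as.character(pattern), l = l,
                                 m = m, replicate = rep, seed = seeds[i],
                                 attempts = res$attempts,
                                 capped = res$capped)
    }
  }
  structure(dplyr::bind_rows(out),
            class = c("learning_time_study", "tbl_df", "tbl", "data.frame"))
}

#' Summarise a learning-time study
#'
#' Per (pattern, l, m): replicate count, mean, median, normal-theory 95%
#' confidence bounds and the fraction of capped replicates. When any
#' replicate hit the cap the median (robust to capping) should be preferred
#' over the mean, which is then a lower bound.
#'
#' @param study Output of [learning_time_study()] (rows of replicates).
#' @return A tibble with one row per condition.
#' @export
summarise_learning_times <- function(study) {
  dplyr::summarise(
    dplyr::group_by(study, .data$pattern, .data$l, .data$m),
    n = dplyr::n(),
    mean = mean(.data$attempts),
    median = median(.data$attempts),
    lo = mean(.data$attempts) - qt(0.975, pmax(dplyr::n() - 1, 1)) *
      sd(.data$attempts) / sqrt(dplyr::n()),
    hi = mean(.data$attempts) + qt(0.975, pmax(dplyr::n() - 1, 1)) *
      sd(.data$attempts) / sqrt(dplyr::n()),
    cap_fraction = mean(.data$capped),
    .groups = "drop")
}

#' Running statistics over a simulation
#'
#' Trailing moving averages of per-attempt statistics: `"reward_rate"`
#' (proportion of attempts reaching the reward), `"highest_state"` (index
#' of the furthest state reached per attempt), or
#' `"choice_probability"` of one behaviour in one observation. Choice
#' probability is computed from the agent's softmax tables at snapshot
#' times when snapshots exist (lower variance), otherwise from the
#' empirical choice frequencies in the recorded transitions; the mode used
#' is recorded in the result.
#'
#' @param sim A `chaining_sim`.
#' @param statistic One of `"reward_rate"`, `"highest_state"`,
#'   `"choice_probability"`.
#' @param window Trailing window in attempts (>= 1); ignored for the
#'   softmax mode of `choice_probability`.
#' @param observation,behaviour Required for `"choice_probability"`.
#' @param mode `"auto"` (snapshots if available), `"softmax"`,
#'   `"empirical"`.
#' @return A tibble `(attempt, value, statistic, mode)`.
#' @export
running_statistic <- function(sim, statistic = c("reward_rate",
                                                 "highest_state",
                                                 "choice_probability"),
                              window = 50, observation = NULL,
                              behaviour = NULL,
                              mode = c("auto", "softmax", "empirical")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (window < 1) abort("`window` must be >= 1.")
  att <- sim$attempts

  if (statistic == "reward_rate") {
    return(tibble::tibble(attempt = att$attempt,
                          value = running_mean(as.numeric(att$reached_reward),
                                               window),
                          statistic = statistic, mode = "attempts"))
  }
  if (statistic == "highest_state") {
    return(tibble::tibble(attempt = att$attempt,
                          value = running_mean(as.numeric(att$highest_index),
                                               window),
                          statistic = statistic, mode = "attempts"))
  }

  if (is.null(observation) || is.null(behaviour)) {
    abort("`choice_probability` needs `observation` and `behaviour`.")
  }
  use_softmax <- switch(mode, softmax = TRUE, empirical = FALSE,
                        auto = !is.null(sim$snapshots))
  if (use_softmax) {
    if (is.null(sim$snapshots)) {
      abort("No snapshots recorded; use mode = \"empirical\".")
    }
    sn <- sim$snapshots
    v <- sn[sn$table == "v" & sn$observation == observation, ]
    beta <- beta_lookup(sim$params$agent, observation, unique(v$behaviour))
    out <- dplyr::group_by(v, .data$attempt)
    out <- dplyr::summarise(out, value = {
      p <- action_probabilities(.data$value, beta[.data$behaviour])
      sum(p[.data$behaviour == !!behaviour])
    }, .groups = "drop")
    return(tibble::tibble(attempt = out$attempt, value = out$value,
                          statistic = statistic, mode = "softmax"))
  }
  if (is.null(sim$transitions)) {
    abort("No transitions recorded; rerun with record = \"transitions\".")
  }
  tr <- sim$transitions[sim$transitions$observation == observation, ]
  per <- dplyr::summarise(
    dplyr::group_by(tr, .data$attempt),
    value = mean(.data$behaviour == !!behaviour), .groups = "drop")
  full <- tibble::tibble(attempt = att$attempt)
  full$value <- per$value[match(full$attempt, per$attempt)]
  tibble::tibble(attempt = full$attempt,
                 value = running_mean(full$value, window),
                 statistic = statistic, mode = "empirical")
}

# static beta values for one observation (modulation rules are resolved at
# their baseline, i.e. as if the last prediction error were 0)
beta_lookup <- function(agent, observation, behaviours) {
  vapply(setNames(behaviours, behaviours), function(b) {
    effective_beta(agent, observation, b, last_d_v = NULL)
  }, numeric(1))
}
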