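#' Simulate a chaining agent on a task
#'
#' Runs repeated attempts of the agent-environment loop. An attempt starts
#' at a state drawn from the entry distribution and ends when a terminal
#' state is entered, when a transition returns to the designated start state
#' (two successive visits to the initial state delimit an attempt), or at
#' `max_steps` (flagged, not an error). Within an attempt the agent chooses
#' behaviours by softmax on the current observation, the environment draws a
#' successor from the kernel, the primary value of the state entered is
#' collected, and both learning updates are applied. The automatic reset
#' after a terminal state is not a learning transition.
#'
#' @param task A [task_spec()] or [preset_bundle][build_preset()].
#' @param agent An [agent_config()]; defaults to the bundle's recommended
#'   configuration when `task` is a preset bundle.
#' @param n_attempts Number of attempts to run (>= 0).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param max_steps Step cap per attempt (default 10000, a guard against
#'   self-perpetuating loops).
#' @param record `"transitions"` keeps the full per-step trace,
#'   `"attempts"` only per-attempt summaries (cheaper for long runs).
#' @param snapshot_every Record copies of the value tables every so many
#'   attempts (and at attempt 0); `NULL` disables snapshots.
#' @param hooks Optional list of functions called before every attempt with
#'   a context list (`task` and `agent` compiled environments, `attempt`
#'   index, logical vector `reached` of per-attempt reward outcomes so far).
#'   Training protocols use hooks to move the entry state or edit primary
#'   values; see [backward_chaining_protocol()].
#' @param engine `"cpp"` (compiled, default), `"r"` (reference
#'   implementation), or `"auto"`.
#' @param reset_on_start Whether returning to the start state closes an
#'   attempt (default `TRUE`). Policy-rollout cross-checks disable this so
#'   an episode runs until a terminal state.
#' @param init Optional agent state (element `state` of a previous result)
#'   to continue learning from.
#'
#' @return A `chaining_sim` object: tibbles `attempts` (per-attempt
#'   summaries), `transitions` (if recorded), `snapshots`; final value
#'   tables `v` and `w`; `seed` and a full parameter echo. Use [tidy()],
#'   [glance()], [autoplot()], [running_statistic()].
#' @export
#' @examples
#' bundle <- chain_task(l = 2, m = 2, b = 1, c = 0.2)
#' sim <- run_simulation(bundle, n_attempts = 50, seed = 1)
#' glance(sim)
run_simulation <- function(task, agent = NULL, n_attempts = 1000,
                           seed = NULL, max_steps = 10000,
                           record = c("transitions", "attempts"),
                           snapshot_every = NULL, hooks = NULL,
                           engine = c("cpp", "r", "auto"),
                           reset_on_start = TRUE, init = NULL) {
  record <- match.arg(record)
  engine <- match.arg(engine)
  if (inherits(task, "preset_bundle")) {
    agent <- agent %||% task$agent
    task <- task$task
  }
  agent <- agent %||% agent_config()
  if (n_attempts < 0) abort("`n_attempts` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)

  ct <- compile_task(task)
  ag <- compile_agent(ct, agent)
  if (!is.null(init)) {
    stopifnot(identical(dim(init$V), dim(ag$V)), length(init$W) == length(ag$W))
    ag$V[] <- init$V
    ag$W[] <- init$W
  }
  use_cpp <- engine %in% c("cpp", "auto")

  echo <- list(task = task$name, n_attempts = n_attempts,
               max_steps = max_steps, engine = if (use_cpp) "cpp" else "r",
               reset_on_start = reset_on_start,
               snapshot_every = snapshot_every, agent = ag$config)

  chunks <- list()
  snaps <- list()
  reached_all <- logical(0)
  take_snap <- function(at) {
    snaps[[length(snaps) + 1L]] <<- list(attempt = at, V = ag$V + 0,
                                         W = ag$W + 0)
  }
  if (!is.null(snapshot_every)) take_snap(0L)

  done <- 0L
  while (done < n_attempts) {
    if (!is.null(hooks)) {
      ctx <- list(task = ct, agent = ag, attempt = done + 1L,
                  reached = reached_all)
      for (h in hooks) h(ctx)
    }
    step_to <- n_attempts
    if (!is.null(snapshot_every)) {
      step_to <- min(step_to, (done %/% snapshot_every + 1L) * snapshot_every)
    }
    nb <- if (!is.null(hooks)) 1L else step_to - done
    res <- run_engine(nb, ct, ag, max_steps, reset_on_start,
                      record == "transitions", done, use_cpp)
    chunks[[length(chunks) + 1L]] <- res
    reached_all <- c(reached_all, res$reached == 1L)
    done <- done + nb
    if (!is.null(snapshot_every) && done %% snapshot_every == 0L) {
      take_snap(done)
    }
  }

  assemble_sim(chunks, snaps, ct, ag, seed, echo)
}

run_engine <- function(nb, ct, ag, max_steps, reset_on_start, record,
                       attempt_offset, use_cpp) {
  if (nb == 0L) {
    return(list(entry = integer(), steps = integer(), total_u = numeric(),
                reached = integer(), ended = integer(), highest = integer()))
  }
  reset_mode <- if (isTRUE(reset_on_start)) ct$reset_mode else 0L
  if (use_cpp) {
    cpp_run_attempts(
      as.integer(nb), ct$obs_of, ct$u, ct$terminal, reward_state_vec(ct),
      as.integer(ct$start), ct$entry_states, ct$entry_cum, ct$rep_cols,
      ct$kern_ns, ct$kern_cp, ag$V, ag$W, ag$Beta, ag$Mod, ag$has_mod_row,
      terminal_obs_vec(ct), ag$alpha_v, ag$alpha_w, ag$chaining,
      as.integer(max_steps), reset_mode, record,
      as.integer(attempt_offset))
  } else {
    r_run_attempts(nb, ct, ag, max_steps, reset_mode, record,
                   attempt_offset)
  }
}

assemble_sim <- function(chunks, snaps, ct, ag, seed, echo) {
  cat1 <- function(field) {
    out <- do.call(c, lapply(chunks, `[[`, field))
    out %||% if (grepl("^tr_u|^tr_dv|total", field)) numeric() else integer()
  }
  ended_lab <- c("terminal", "reset", "cap")
  n <- length(cat1("steps"))
  attempts <- tibble::tibble(
    attempt = seq_len(n),
    entry_state = ct$state_names[cat1("entry")],
    steps = cat1("steps"),
    total_u = cat1("total_u"),
    reached_reward = cat1("reached") == 1L,
    highest_state = ct$state_names[cat1("highest")],
    highest_index = cat1("highest"),
    ended = ended_lab[pmax(cat1("ended"), 1L)])

  transitions <- NULL
  if (any(vapply(chunks, function(x) !is.null(x$tr_attempt), logical(1)))) {
    transitions <- tibble::tibble(
      attempt = cat1("tr_attempt"),
      step = cat1("tr_step"),
      state = ct$state_names[cat1("tr_state")],
      observation = ct$obs_names[ct$obs_of[cat1("tr_state")]],
      behaviour = ct$beh_names[cat1("tr_beh")],
      next_state = ct$state_names[cat1("tr_next")],
      next_observation = ct$obs_names[ct$obs_of[cat1("tr_next")]],
      u = cat1("tr_u"),
      d_v = cat1("tr_dv"),
      terminal = cat1("tr_term") == 1L)
  }

  snapshots <- NULL
  if (length(snaps)) {
    snapshots <- dplyr::bind_rows(lapply(snaps, function(sn) {
      v <- v_table_from_matrix(ct, sn$V)
      v$table <- "v"
      w <- w_table_from_vector(ct, sn$W)[, c("observation", "value")]
      w$behaviour <- NA_character_
      w$table <- "w"
      out <- dplyr::bind_rows(v, w)
      out$attempt <- sn$attempt
      out[, c("attempt", "table", "observation", "behaviour", "value")]
    }))
  }

  structure(
    list(attempts = attempts, transitions = transitions,
         snapshots = snapshots,
         v = v_table_from_matrix(ct, ag$V),
         w = w_table_from_vector(ct, ag$W),
         state = list(V = ag$V + 0, W = ag$W + 0),
         seed = seed, params = echo),
    class = "chaining_sim")
}

#' @export
print.chaining_sim <- function(x, ...) {
  n <- nrow(x$attempts)
  cat(sprintf("<chaining_sim> %s: %d attempts, %d steps, reward rate %.3f\n",
              x$params$task, n, sum(x$attempts$steps),
              mean(x$attempts$reached_reward)))
  invisible(x)
}

#' Run a single attempt and return its trace
#'
#' One attempt of the simulation loop with full per-step records: state,
#' observation, behaviour, successor, primary value collected and the
#' prediction error that drove learning.
#'
#' @inheritParams run_simulation
#' @return A tibble of transition records (one attempt), with the attempt
#'   summary row as attribute `"summary"`.
#' @export
run_attempt <- function(task, agent = NULL, seed = NULL, max_steps = 10000,
                        engine = c("cpp", "r", "auto")) {
  sim <- run_simulation(task, agent, n_attempts = 1, seed = seed,
                        max_steps = max_steps, record = "transitions",
                        engine = match.arg(engine))
  out <- sim$transitions
  attr(out, "summary") <- sim$attempts
  out
}
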