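#' Define a finite-state task environment
#'
#' A task is a finite set of environmental states with genetically fixed
#' primary reinforcement values `u`, a per-state behaviour repertoire with a
#' (possibly stochastic) transition kernel, an entry distribution, terminal
#' states that end an attempt, and an optional observation map modelling
#' perceptual aliasing (several true states perceived as one stimulus).
#'
#' @param states Data frame with columns `state` (label), `u` (primary
#'   reinforcement value, reward units) and `terminal` (logical).
#' @param transitions Data frame with columns `state`, `behaviour`,
#'   `next_state` and `prob`. Rows sharing `(state, behaviour)` describe a
#'   stochastic kernel and their probabilities must sum to 1. The ordered set
#'   of behaviours of a state is the order of first appearance.
#' @param entry Either a single state label (always enter there), or a data
#'   frame with columns `state` and `prob` summing to 1 over non-terminal
#'   states.
#' @param start State label marking the designated initial state. An attempt
#'   is the trajectory segment between two successive visits to this state
#'   (entering a terminal state also closes an attempt). Defaults to the
#'   highest-probability entry state.
#' @param observe Optional data frame with columns `state`, `observation`
#'   mapping true states to observation labels; states left out of the map
#'   are observed as themselves only when `observe` is `NULL` (a partial map
#'   is an error at lookup time). Aliased states must share an identical
#'   behaviour repertoire.
#' @param attempt_closure When does a transition into the start state close
#'   the current attempt (and end the learning episode)? `"return"`
#'   (default): every transition into the start state, including
#'   self-transitions — appropriate when mistakes are described as sending
#'   the animal back to the start to try again. `"arrival"`: only
#'   transitions from a different state — appropriate when a failed action
#'   leaves the animal in place, still engaged with the task, so that
#'   remaining at the start is one continuous visit.
#' @param name Task name used in printouts and manifests.
#'
#' @return An object of class `task_spec`.
#' @seealso [validate_task()], [chain_task()], [build_preset()]
#' @export
#' @examples
#' states <- tibble::tibble(
#'   state = c("0", "1"), u = c(-0.2, 1), terminal = c(FALSE, TRUE))
#' transitions <- tibble::tibble(
#'   state = "0", behaviour = c("go", "stay"),
#'   next_state = c("1", "0"), prob = 1)
#' task <- task_spec(states, transitions, entry = "0")
#' validate_task(task)
task_spec <- function(states, transitions, entry, start = NULL,
                      observe = NULL,
                      attempt_closure = c("return", "arrival"),
                      name = "task") {
  attempt_closure <- match.arg(attempt_closure)
  states <- tibble::as_tibble(states)
  transitions <- tibble::as_tibble(transitions)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("`%s` is missing column(s): %s.", what,
                    paste(miss, collapse = ", ")))
    }
  }
  need(states, c("state", "u", "terminal"), "states")
  need(transitions, c("state", "behaviour", "next_state", "prob"),
       "transitions")
  states$state <- as_chr(states$state)
  transitions$state <- as_chr(transitions$state)
  transitions$behaviour <- as_chr(transitions$behaviour)
  transitions$next_state <- as_chr(transitions$next_state)
  if (anyDuplicated(states$state)) abort("Duplicate state labels.")

  if (is.character(entry) && length(entry) == 1L) {
    entry <- tibble::tibble(state = entry, prob = 1)
  }
  entry <- tibble::as_tibble(entry)
  need(entry, c("state", "prob"), "entry")
  entry$state <- as_chr(entry$state)

  if (!is.null(observe)) {
    observe <- tibble::as_tibble(observe)
    need(observe, c("state", "observation"), "observe")
    observe$state <- as_chr(observe$state)
    observe$observation <- as_chr(observe$observation)
  }

  if (is.null(start)) start <- entry$state[which.max(entry$prob)]
  start <- as_chr(start)

  structure(
    list(states = states, transitions = transitions, entry = entry,
         start = start, observe = observe,
         attempt_closure = attempt_closure, name = name, meta = list()),
    class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s: %d states (%d terminal), %d transition rows\n",
              x$name, nrow(x$states), sum(x$states$terminal),
              nrow(x$transitions)))
  cat(sprintf("  start: %s; entry over {%s}\n", x$start,
              paste(x$entry$state, collapse = ", ")))
  if (!is.null(x$observe)) {
    merged <- x$observe$observation[duplicated(x$observe$observation)]
    if (length(merged)) {
      cat(sprintf("  aliased observations: %s\n",
                  paste(unique(merged), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Validate a task specification
#'
#' Checks all structural invariants of a [task_spec()]: kernel rows summing
#' to one, a proper entry distribution over existing non-terminal states,
#' primary values defined everywhere, terminals without outgoing behaviours,
#' non-terminals with at least one behaviour, consistent repertoires across
#' aliased states, and reachability of the reward (the highest-value
#' terminal) from every entry state. Violations are returned as data, not
#' raised as conditions.
#'
#' @param task A [task_spec()].
#' @return A tibble with columns `check` and `message`, one row per
#'   violation; zero rows when the task is well formed.
#' @export
validate_task <- function(task) {
  v <- list()
  add <- function(check, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(check = check, message = message)
  }
  st <- task$states
  tr <- task$transitions

  if (!is.numeric(st$u) || anyNA(st$u) || any(!is.finite(st$u))) {
    add("u_defined", "primary value `u` must be finite for every state")
  }

  unknown <- setdiff(unique(c(tr$state, tr$next_state)), st$state)
  if (length(unknown)) {
    add("states_exist", sprintf("transitions reference unknown state(s): %s",
                                paste(unknown, collapse = ", ")))
  }

  if (any(tr$prob < 0 | tr$prob > 1)) {
    bad <- tr[tr$prob < 0 | tr$prob > 1, ]
    add("prob_range", sprintf("probability out of [0, 1] on edge(s): %s",
        paste(sprintf("(%s, %s)", bad$state, bad$behaviour), collapse = "; ")))
  }

  sums <- dplyr::summarise(dplyr::group_by(tr, .data$state, .data$behaviour),
                           p = sum(.data$prob), .groups = "drop")
  bad <- sums[abs(sums$p - 1) > 1e-9, ]
  if (nrow(bad)) {
    add("kernel_sums", sprintf(
      "transition probabilities do not sum to 1 for: %s",
      paste(sprintf("(%s, %s) = %.6g", bad$state, bad$behaviour, bad$p),
            collapse = "; ")))
  }

  if (abs(sum(task$entry$prob) - 1) > 1e-9) {
    add("entry_sums", sprintf("entry distribution sums to %.6g, not 1",
                              sum(task$entry$prob)))
  }
  bad_entry <- setdiff(task$entry$state, st$state)
  if (length(bad_entry)) {
    add("entry_states", sprintf("entry references unknown state(s): %s",
                                paste(bad_entry, collapse = ", ")))
  }
  term_entry <- intersect(task$entry$state[task$entry$prob > 0],
                          st$state[st$terminal])
  if (length(term_entry)) {
    add("entry_terminal", sprintf("entry assigns mass to terminal state(s): %s",
                                  paste(term_entry, collapse = ", ")))
  }
  if (!task$start %in% st$state) {
    add("start_state", sprintf("start state '%s' does not exist", task$start))
  }

  with_beh <- unique(tr$state)
  no_beh <- setdiff(st$state[!st$terminal], with_beh)
  if (length(no_beh)) {
    add("repertoire", sprintf("non-terminal state(s) without behaviours: %s",
                              paste(no_beh, collapse = ", ")))
  }
  term_beh <- intersect(st$state[st$terminal], with_beh)
  if (length(term_beh)) {
    add("terminal_repertoire",
        sprintf("terminal state(s) with outgoing behaviours: %s",
                paste(term_beh, collapse = ", ")))
  }

  if (!is.null(task$observe)) {
    missing_obs <- setdiff(st$state, task$observe$state)
    if (length(missing_obs)) {
      add("observe_partial", sprintf("observation map omits state(s): %s",
                                     paste(missing_obs, collapse = ", ")))
    } else {
      # aliased states must be indistinguishable to the learner: identical
      # repertoires, and never a terminal merged with a non-terminal
      obs_of <- setNames(task$observe$observation, task$observe$state)
      reps <- split(tr$behaviour, tr$state)
      reps <- lapply(reps, unique)
      for (ob in unique(obs_of)) {
        members <- names(obs_of)[obs_of == ob]
        if (length(members) < 2L) next
        tflags <- st$terminal[match(members, st$state)]
        if (length(unique(tflags)) > 1L) {
          add("alias_terminal", sprintf(
            "observation '%s' merges terminal and non-terminal states", ob))
        }
        rr <- lapply(members, function(s) sort(reps[[s]] %||% character()))
        if (length(unique(rr)) > 1L) {
          add("alias_repertoire", sprintf(
            "observation '%s' merges states with different repertoires", ob))
        }
      }
    }
  }

  # reward reachability: the highest-u terminal must be reachable from every
  # positive-probability entry state through some behaviour sequence
  if (!length(v)) {
    terms <- st$state[st$terminal]
    if (!length(terms)) {
      add("reward_reachable", "task has no terminal state")
    } else {
      reward <- terms[which.max(st$u[match(terms, st$state)])]
      # backward reachability over the directed graph of positive-prob edges
      edges <- tr[tr$prob > 0, c("state", "next_state")]
      can <- reward
      repeat {
        new <- unique(edges$state[edges$next_state %in% can])
        new <- setdiff(new, can)
        if (!length(new)) break
        can <- c(can, new)
      }
      bad <- setdiff(task$entry$state[task$entry$prob > 0], can)
      if (length(bad)) {
        add("reward_reachable", sprintf(
          "reward state '%s' unreachable from entry state(s): %s",
          reward, paste(bad, collapse = ", ")))
      }
    }
  }

  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(check = character(), message = character())
  }
}

stop_if_invalid <- function(task) {
  bad <- validate_task(task)
  if (nrow(bad)) {
    abort(paste0("Invalid task specification:\n",
                 paste(sprintf("- [%s] %s", bad$check, bad$message),
                       collapse = "\n")))
  }
  invisible(task)
}

#' Draw entry states
#'
#' Samples task entry states from the entry distribution. For the structured
#' entry-pattern family of chain tasks (see [chain_task()]), the first state
#' has probability `(1 - p) + p/l` and every other non-terminal chain state
#' `p/l`: with probability `p` the animal enters the task at a random state,
#' otherwise at the first state.
#'
#' @param task A [task_spec()].
#' @param n Number of draws.
#' @return Character vector of state labels of length `n`.
#' @export
sample_entry <- function(task, n = 1) {
  p <- task$entry$prob
  if (length(p) == 1L) return(rep(task$entry$state, n))
  idx <- findInterval(runif(n), cumsum(p), left.open = TRUE) + 1L
  task$entry$state[idx]
}

#' Execute one environment transition
#'
#' Draws the successor of `state` under `behaviour` from the task kernel.
#' The primary value collected is always the value of the state entered.
#'
#' @param task A [task_spec()].
#' @param state Current state label.
#' @param behaviour Behaviour label; must be in the repertoire of `state`.
#' @return A list with `next_state`, `u` (value collected) and `terminal`.
#' @export
step_task <- function(task, state, behaviour) {
  state <- as_chr(state)
  if (!state %in% task$states$state) {
    abort(sprintf("Unknown state '%s'.", state))
  }
  rows <- task$transitions[task$transitions$state == state &
                             task$transitions$behaviour == behaviour, ]
  if (!nrow(rows)) {
    abort(sprintf("Behaviour '%s' is not in the repertoire of state '%s'.",
                  behaviour, state))
  }
  if (nrow(rows) == 1L) {
    nxt <- rows$next_state
  } else {
    idx <- findInterval(runif(1), cumsum(rows$prob), left.open = TRUE) + 1L
    idx <- min(idx, nrow(rows))
    nxt <- rows$next_state[idx]
  }
  i <- match(nxt, task$states$state)
  list(next_state = nxt, u = task$states$u[i],
       terminal = task$states$terminal[i])
}

#' Observation label of a state
#'
#' Maps a true environmental state to the observation perceived by the
#' learner. Without an observation map every state is observed as itself;
#' with one, aliased states share a label and are indistinguishable to the
#' agent, whose value tables are keyed by observation.
#'
#' @param task A [task_spec()].
#' @param state State label(s).
#' @return Character vector of observation labels.
#' @export
observe <- function(task, state) {
  state <- as_chr(state)
  bad <- setdiff(state, task$states$state)
  if (length(bad)) {
    abort(sprintf("Unknown state(s): %s.", paste(bad, collapse = ", ")))
  }
  if (is.null(task$observe)) return(state)
  i <- match(state, task$observe$state)
  if (anyNA(i)) {
    abort(sprintf("State(s) not covered by the observation map: %s.",
                  paste(state[is.na(i)], collapse = ", ")))
  }
  task$observe$observation[i]
}

# repertoire of a state, in order of first appearance
repertoire <- function(task, state) {
  unique(task$transitions$behaviour[task$transitions$state == state])
}
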