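#' Behavioural policies for the oracle
#'
#' A policy assigns each non-terminal observation a probability distribution
#' over its behaviours. Policies are evaluated on true states (aliased
#' states share the policy of their observation).
#'
#' @param task A [task_spec()] or preset bundle.
#' @param probs Data frame `(observation, behaviour, prob)`; distributions
#'   must be valid and cover every non-terminal observation.
#' @return A `policy_spec` tibble.
#' @export
policy_spec <- function(task, probs) {
  task <- as_task(task)
  ct <- compile_task(task)
  probs <- tibble::as_tibble(probs)
  probs$observation <- as_chr(probs$observation)
  probs$behaviour <- as_chr(probs$behaviour)
  oc <- obs_cols(ct)
  for (o in seq_len(ct$n_o)) {
    cols <- oc[[o]]
    if (is.null(cols) || !length(cols)) next
    rows <- probs[probs$observation == ct$obs_names[o], ]
    if (!nrow(rows)) {
      abort(sprintf("Policy missing observation '%s'.", ct$obs_names[o]))
    }
    if (abs(sum(rows$prob) - 1) > 1e-9 || any(rows$prob < 0)) {
      abort(sprintf("Policy for '%s' is not a distribution.",
                    ct$obs_names[o]))
    }
    bad <- setdiff(rows$behaviour, ct$beh_names[cols])
    if (length(bad)) {
      abort(sprintf("Policy for '%s' uses unavailable behaviour(s): %s.",
                    ct$obs_names[o], paste(bad, collapse = ", ")))
    }
  }
  structure(probs, class = c("policy_spec", class(probs)))
}

#' Uniform random policy
#' @param task A [task_spec()] or preset bundle.
#' @return A [policy_spec()] choosing uniformly in every observation.
#' @export
uniform_policy <- function(task) {
  task <- as_task(task)
  ct <- compile_task(task)
  oc <- obs_cols(ct)
  rows <- lapply(seq_len(ct$n_o), function(o) {
    cols <- oc[[o]]
    if (is.null(cols) || !length(cols)) return(NULL)
    tibble::tibble(observation = ct$obs_names[o],
                   behaviour = ct$beh_names[cols],
                   prob = 1 / length(cols))
  })
  policy_spec(task, dplyr::bind_rows(rows))
}

as_task <- function(task) {
  if (inherits(task, "preset_bundle")) task$task else task
}

# Is the transition s -> ns an episode boundary under the given horizon?
# Terminals always end the episode. Under the "attempt" horizon a reset to
# the start state does too, where "reset" follows the task's attempt
# closure: any transition into the start state ("return" tasks), or only
# arrivals from a different state ("arrival" tasks, where staying in place
# at the start is one continuous visit).
edge_boundary <- function(ct, horizon, s, ns) {
  if (ct$terminal[ns]) return(TRUE)
  if (horizon != "attempt" || ns != ct$start) return(FALSE)
  ct$reset_mode == 1L || s != ns
}

# States that can close an episode (used for properness diagnostics).
boundary_states <- function(ct, horizon) {
  b <- ct$terminal
  if (horizon == "attempt") b[ct$start] <- TRUE
  b
}

# Per-state transition matrix and expected one-step primary value under a
# policy defined on observations. Continuation through episode-boundary
# transitions is cut from `P`; their u still enters `r`.
policy_matrices <- function(ct, policy, horizon = "task") {
  n_s <- ct$n_s
  P <- matrix(0, n_s, n_s)
  P_full <- matrix(0, n_s, n_s)
  r <- numeric(n_s)
  for (s in seq_len(n_s)) {
    cols <- ct$rep_cols[[s]]
    if (!length(cols)) next
    o <- ct$obs_names[ct$obs_of[s]]
    rows <- policy[policy$observation == o, ]
    pb <- setNames(rep(0, length(cols)), ct$beh_names[cols])
    pb[rows$behaviour] <- rows$prob
    for (j in seq_along(cols)) {
      if (pb[j] == 0) next
      ns <- ct$kern_ns[[s]][[j]]
      cp <- ct$kern_cp[[s]][[j]]
      pr <- diff(c(0, cp))
      for (i in seq_along(ns)) {
        P_full[s, ns[i]] <- P_full[s, ns[i]] + pb[j] * pr[i]
        r[s] <- r[s] + pb[j] * pr[i] * ct$u[ns[i]]
        if (!edge_boundary(ct, horizon, s, ns[i])) {
          P[s, ns[i]] <- P[s, ns[i]] + pb[j] * pr[i]
        }
      }
    }
  }
  list(P = P, r = r, P_full = P_full)
}

# States from which no episode boundary is reachable through
# positive-probability policy edges (the recurrent non-terminal trap named
# in diagnostics). Uses the unmodified transition structure.
improper_states <- function(ct, P, boundary) {
  can <- which(boundary)
  repeat {
    new <- which(rowSums(P[, can, drop = FALSE]) > 0)
    new <- setdiff(new, can)
    if (!length(new)) break
    can <- c(can, new)
  }
  setdiff(which(!boundary), can)
}

#' Exact policy evaluation (Bellman consistency)
#'
#' Solves the self-consistency condition
#' \deqn{w^*_S = \sum_{S'} P_{S,S'} (u_{S'} + w^*_{S'})}
#' for the expected total primary value gained after each state under a
#' fixed behavioural strategy, by direct linear solve on the non-terminal
#' states (terminal `w*` is 0), with iterative sweeps as a fallback. The
#' state-behaviour values `v*` follow as
#' \eqn{v^*_{S \to B} = \sum_{S'} P(S'|S,B) (u_{S'} + w^*_{S'})}.
#'
#' The policy must be proper: a terminal state reached with probability 1
#' from everywhere, checked via the spectral radius of the sub-stochastic
#' non-terminal transition matrix.
#'
#' @param task A [task_spec()] or preset bundle.
#' @param policy A [policy_spec()]; default the uniform policy.
#' @param tol Residual tolerance for the direct solve (iterative fallback
#'   stops at `1e-8`).
#' @param horizon `"task"` (default) evaluates the kernel as given, the
#'   episode ending only at terminal states; `"attempt"` additionally ends
#'   the episode whenever the designated start state is entered (its `u` is
#'   still collected), matching the learning agent, whose attempts are
#'   delimited by visits to the start state and bootstrap from 0 there.
#' @return An `oracle_values` object: named vector `w_star`, tibble
#'   `v_star`, the achieved Bellman `residual`, and the evaluated policy.
#' @export
#' @examples
#' b <- chain_task(l = 2, m = 1, b = 1, c = 0.2)
#' policy_evaluation(b)$w_star   # 0.8, 1.0, 0
policy_evaluation <- function(task, policy = NULL, tol = 1e-10,
                              horizon = c("task", "attempt")) {
  task <- as_task(task)
  horizon <- match.arg(horizon)
  ct <- compile_task(task)
  policy <- policy %||% uniform_policy(task)
  pm <- policy_matrices(ct, policy, horizon)
  boundary <- boundary_states(ct, horizon)
  nt <- which(!ct$terminal)
  Pnn <- pm$P[nt, nt, drop = FALSE]

  rad <- if (length(nt)) max(Mod(eigen(Pnn, only.values = TRUE)$values)) else 0
  if (rad >= 1 - 1e-9) {
    trap <- improper_states(ct, pm$P_full, boundary)
    abort(sprintf(
      "Improper policy: non-terminal state(s) {%s} cannot reach a terminal (spectral radius %.6f).",
      paste(ct$state_names[trap], collapse = ", "), rad))
  }

  w <- numeric(ct$n_s)
  sol <- tryCatch(solve(diag(length(nt)) - Pnn, pm$r[nt]),
                  error = function(e) NULL)
  if (!is.null(sol)) {
    w[nt] <- sol
    method <- "direct"
  } else {
    ww <- numeric(length(nt))
    for (it in seq_len(100000)) {
      new <- pm$r[nt] + Pnn %*% ww
      if (max(abs(new - ww)) < 1e-8) { ww <- new; break }
      ww <- new
    }
    w[nt] <- ww
    method <- "iterative"
  }
  residual <- max(abs(w[nt] - (pm$r[nt] + Pnn %*% w[nt])), 0)

  new_oracle_values(ct, w, residual, method, policy, horizon)
}

new_oracle_values <- function(ct, w, residual, method, policy, horizon) {
  names(w) <- ct$state_names
  v <- v_star_from_w(ct, w, horizon)
  structure(list(w_star = w, v_star = v, residual = residual,
                 method = method, policy = policy, horizon = horizon,
                 state_obs = setNames(ct$obs_names[ct$obs_of],
                                      ct$state_names)),
            class = "oracle_values")
}

v_star_from_w <- function(ct, w, horizon) {
  rows <- lapply(seq_len(ct$n_s), function(s) {
    cols <- ct$rep_cols[[s]]
    if (!length(cols)) return(NULL)
    vv <- vapply(seq_along(cols), function(j) {
      ns <- ct$kern_ns[[s]][[j]]
      pr <- diff(c(0, ct$kern_cp[[s]][[j]]))
      wc <- vapply(ns, function(n2) {
        if (edge_boundary(ct, horizon, s, n2)) 0 else w[n2]
      }, numeric(1))
      sum(pr * (ct$u[ns] + wc))
    }, numeric(1))
    tibble::tibble(state = ct$state_names[s],
                   behaviour = ct$beh_names[cols], v_star = vv)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.oracle_values <- function(x, ...) {
  cat(sprintf("<oracle_values> (%s solve, residual %.2e)\n", x$method,
              x$residual))
  print(round(x$w_star, 6))
  invisible(x)
}

#' Optimal values and greedy policy by value iteration
#'
#' Computes the best attainable expected future value of every state,
#' \eqn{w^*_S = \max_B \sum_{S'} P(S'|S,B)(u_{S'} + w^*_{S'})}, together
#' with a deterministic greedy policy attaining it. The returned values
#' dominate the evaluation of any proper policy pointwise.
#'
#' @param task A [task_spec()] or preset bundle.
#' @param tol Convergence tolerance on the sup-norm update.
#' @param max_iter Iteration cap; exceeding it with a growing residual
#'   signals that no proper policy exists.
#' @param horizon Episode horizon as in [policy_evaluation()].
#' @return An `oracle_values` object whose `policy` is the greedy policy.
#' @export
optimal_values <- function(task, tol = 1e-12, max_iter = 100000,
                           horizon = c("task", "attempt")) {
  task <- as_task(task)
  horizon <- match.arg(horizon)
  ct <- compile_task(task)
  n_s <- ct$n_s
  w <- numeric(n_s)
  qvals <- function(s, w) {
    cols <- ct$rep_cols[[s]]
    vapply(seq_along(cols), function(j) {
      ns <- ct$kern_ns[[s]][[j]]
      pr <- diff(c(0, ct$kern_cp[[s]][[j]]))
      wc <- vapply(ns, function(n2) {
        if (edge_boundary(ct, horizon, s, n2)) 0 else w[n2]
      }, numeric(1))
      sum(pr * (ct$u[ns] + wc))
    }, numeric(1))
  }
  delta <- 0
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (s in which(!ct$terminal)) {
      best <- max(qvals(s, w))
      delta <- max(delta, abs(best - w[s]))
      w[s] <- best
    }
    if (delta < tol) break
  }
  if (delta >= max(tol, 1e-8)) {
    abort("Value iteration did not converge; the task admits no proper policy.")
  }

  # greedy policy on observations (aliased states share repertoires; the
  # greedy action is taken from the first member state)
  oc <- obs_cols(ct)
  rows <- lapply(seq_len(ct$n_o), function(o) {
    cols <- oc[[o]]
    if (is.null(cols) || !length(cols)) return(NULL)
    s <- which(ct$obs_of == o & !ct$terminal)[1]
    q <- qvals(s, w)
    tibble::tibble(observation = ct$obs_names[o],
                   behaviour = ct$beh_names[cols],
                   prob = as.numeric(seq_along(cols) == which.max(q)))
  })
  policy <- policy_spec(task, dplyr::bind_rows(rows))

  residual <- max(0, vapply(which(!ct$terminal), function(s) {
    abs(max(qvals(s, w)) - w[s])
  }, numeric(1)))
  new_oracle_values(ct, w, residual, "value-iteration", policy, horizon)
}

#' Softmax self-consistent values
#'
#' Predicts the asymptote of the learning agent by alternating exact policy
#' evaluation with the softmax decision rule: values give a softmax policy,
#' the policy is evaluated exactly, and so on to a fixed point. For aliased
#' observations the observation-level value fed to the softmax is the
#' visitation-weighted average of the member states' values (the learner's
#' table converges to a visitation mixture). Perceptual aliasing can break
#' the contraction, in which case the iteration trace is returned flagged
#' non-convergent rather than raising an error.
#'
#' @param task A [task_spec()] or preset bundle.
#' @param agent An [agent_config()] supplying `beta` (and overrides).
#' @param max_iter Iteration cap.
#' @param tol Fixed-point tolerance on policy probabilities.
#' @param horizon Episode horizon as in [policy_evaluation()]; defaults to
#'   `"attempt"`, the horizon the learning agent experiences.
#' @return A list: `values` (an `oracle_values`), `policy`, `converged`,
#'   `iterations`, and a `trace` tibble of per-iteration maximum policy
#'   change.
#' @export
softmax_equilibrium <- function(task, agent = NULL, max_iter = 500,
                                tol = 1e-9,
                                horizon = c("attempt", "task")) {
  if (inherits(task, "preset_bundle")) {
    agent <- agent %||% task$agent
    task <- task$task
  }
  horizon <- match.arg(horizon)
  agent <- agent %||% agent_config()
  ct <- compile_task(task)
  ag <- compile_agent(ct, agent)
  oc <- obs_cols(ct)

  policy <- uniform_policy(task)
  trace <- numeric(0)
  converged <- FALSE
  ev <- NULL
  for (it in seq_len(max_iter)) {
    ev <- policy_evaluation(task, policy, horizon = horizon)
    # observation-level v: visitation-weighted mixture over member states
    visits <- expected_visits(ct, policy, horizon)
    rows <- lapply(seq_len(ct$n_o), function(o) {
      cols <- oc[[o]]
      if (is.null(cols) || !length(cols)) return(NULL)
      members <- ct$state_names[ct$obs_of == o & !ct$terminal]
      wts <- visits[members]
      if (sum(wts) <= 0) wts <- rep(1, length(members))
      vs <- ev$v_star[ev$v_star$state %in% members, ]
      vo <- vapply(ct$beh_names[cols], function(b) {
        vv <- vs$v_star[vs$behaviour == b]
        sum(vv * (wts / sum(wts))[match(vs$state[vs$behaviour == b], members)])
      }, numeric(1))
      p <- action_probabilities(vo, ag$Beta[o, cols])
      tibble::tibble(observation = ct$obs_names[o],
                     behaviour = ct$beh_names[cols], prob = as.numeric(p))
    })
    new_policy <- policy_spec(task, dplyr::bind_rows(rows))
    dmax <- max(abs(new_policy$prob - policy$prob[match(
      paste(new_policy$observation, new_policy$behaviour),
      paste(policy$observation, policy$behaviour))]))
    trace <- c(trace, dmax)
    policy <- new_policy
    if (dmax < tol) { converged <- TRUE; break }
  }
  list(values = ev, policy = policy, converged = converged,
       iterations = length(trace),
       trace = tibble::tibble(iteration = seq_along(trace),
                              max_change = trace))
}

# Expected visits per episode to each state under a policy, starting from
# the entry distribution: N = entry' (I - Pnn)^{-1} over non-terminals.
expected_visits <- function(ct, policy, horizon = "task") {
  pm <- policy_matrices(ct, policy, horizon)
  nt <- which(!ct$terminal)
  entry <- numeric(ct$n_s)
  entry[ct$entry_states] <- diff(c(0, ct$entry_cum))
  N <- numeric(ct$n_s)
  if (length(nt)) {
    Pnn <- pm$P[nt, nt, drop = FALSE]
    N[nt] <- tryCatch(
      as.numeric(solve(t(diag(length(nt)) - Pnn), entry[nt])),
      error = function(e) rep(1, length(nt)))
  }
  setNames(N, ct$state_names)
}

#' Monte-Carlo episode returns under a fixed policy
#'
#' Simulates full task episodes (entry to terminal, never ending early at
#' the start state) under a frozen policy — learning rates zero, behaviour
#' probabilities fixed — and returns the collected primary value of each
#' episode. The mean return estimates the entry-weighted expected future
#' value, the quantity [policy_evaluation()] computes exactly with
#' `horizon = "task"`; the two must agree within Monte-Carlo error.
#'
#' @param task A [task_spec()] or preset bundle.
#' @param policy A [policy_spec()]; default uniform.
#' @param n Number of episodes.
#' @param seed Integer seed.
#' @param max_steps Step cap per episode.
#' @return Numeric vector of `n` episode returns.
#' @export
policy_rollouts <- function(task, policy = NULL, n = 1000, seed = NULL,
                            max_steps = 10000) {
  task <- as_task(task)
  policy <- policy %||% uniform_policy(task)
  # encode the policy in the softmax: beta = 1 and v = log(prob) reproduce
  # the target distribution exactly; zero learning rates freeze it
  v_init <- tibble::tibble(observation = policy$observation,
                           behaviour = policy$behaviour,
                           value = pmax(log(policy$prob), -700))
  agent <- agent_config(alpha_v = 0, alpha_w = 0, beta = 1, v_init = v_init)
  sim <- run_simulation(task, agent, n_attempts = n, seed = seed,
                        record = "attempts", reset_on_start = FALSE)
  sim$attempts$total_u
}

#' Maximum deviation of learned tables from oracle values
#'
#' Compares an agent's learned `v` and `w` tables against oracle values,
#' restricted to observations (and observation-behaviour pairs) visited at
#' least `min_visits` times. An aliased observation is compared against the
#' visitation-weighted average of its member states' oracle values, since
#' that mixture is what the learner's shared table entry estimates.
#'
#' @param sim A `chaining_sim` with recorded transitions, or a list with
#'   elements `v`, `w` (tibbles as in [value_tables()]) plus `visits`
#'   tibbles.
#' @param oracle An `oracle_values` object.
#' @param min_visits Minimum visit count for an entry to be compared.
#' @return The maximum absolute deviation (scalar), with a tibble of
#'   per-entry deviations as attribute `"details"`.
#' @export
compare_to_oracle <- function(sim, oracle, min_visits = 1) {
  if (inherits(sim, "chaining_sim")) {
    if (is.null(sim$transitions)) {
      abort("`sim` must be run with record = \"transitions\".")
    }
    tr <- sim$transitions
    w_vis <- dplyr::count(tr, .data$observation, .data$state)
    v_vis <- dplyr::count(tr, .data$observation, .data$state, .data$behaviour)
    v_tbl <- sim$v
    w_tbl <- sim$w
  } else {
    abort("`sim` must be a chaining_sim result.")
  }

  # oracle w per observation: visit-weighted over member true states
  w_obs <- dplyr::summarise(
    dplyr::group_by(w_vis, .data$observation),
    n = sum(.data$n),
    oracle = sum(oracle$w_star[.data$state] * .data$n) / sum(.data$n),
    .groups = "drop")
  w_cmp <- dplyr::inner_join(w_tbl[!w_tbl$terminal, ], w_obs,
                             by = "observation")
  w_cmp <- w_cmp[w_cmp$n >= min_visits, ]
  w_det <- tibble::tibble(table = "w", key = w_cmp$observation,
                          deviation = abs(w_cmp$value - w_cmp$oracle))

  vs <- oracle$v_star
  vs$key <- paste(vs$state, vs$behaviour)
  v_vis$key <- paste(v_vis$state, v_vis$behaviour)
  v_vis$oracle <- vs$v_star[match(v_vis$key, vs$key)]
  v_obs <- dplyr::summarise(
    dplyr::group_by(v_vis, .data$observation, .data$behaviour),
    n = sum(.data$n),
    oracle = sum(.data$oracle * .data$n) / sum(.data$n),
    .groups = "drop")
  v_cmp <- dplyr::inner_join(v_tbl, v_obs, by = c("observation", "behaviour"))
  v_cmp <- v_cmp[v_cmp$n >= min_visits, ]
  v_det <- tibble::tibble(table = "v",
                          key = paste(v_cmp$observation, v_cmp$behaviour),
                          deviation = abs(v_cmp$value - v_cmp$oracle))

  det <- dplyr::bind_rows(w_det, v_det)
  if (!nrow(det)) abort("No comparable entries with the given `min_visits`.")
  out <- max(det$deviation)
  attr(out, "details") <- det
  out
}
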