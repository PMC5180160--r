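#' Parameters for the random-task generator
#'
#' @param n_layers Number of non-terminal layers (>= 1).
#' @param states_per_layer States in each non-terminal layer (>= 1).
#' @param m Behaviours per state (>= 1).
#' @param branching Maximum distinct successors per behaviour (>= 1).
#' @param reward_range Range of terminal reward magnitudes (positive).
#' @param cost_range Range of per-state cost magnitudes (non-negative).
#' @param reset_prob Probability that a behaviour mixes in a reset edge to
#'   the entry layer, in `[0, 1)`.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(n_layers = 3, states_per_layer = 2, m = 2,
                           branching = 2, reward_range = c(1, 5),
                           cost_range = c(0.05, 0.4), reset_prob = 0.15) {
  if (n_layers < 1 || states_per_layer < 1 || m < 1 || branching < 1) {
    abort("Counts must be positive.")
  }
  if (reset_prob < 0 || reset_prob >= 1) abort("`reset_prob` must be in [0, 1).")
  structure(list(n_layers = n_layers, states_per_layer = states_per_layer,
                 m = m, branching = branching, reward_range = reward_range,
                 cost_range = cost_range, reset_prob = reset_prob),
            class = "fixture_params")
}

#' Generate a random terminating task
#'
#' Builds a random task environment that is guaranteed to end in finite
#' time by construction: states are arranged in layers, every behaviour
#' sends most of its probability mass to the next layer (the last layer is
#' terminal and rewarded), and an optional minority share of mass forms
#' reset edges back to the entry layer. Under any policy each step has
#' positive probability of progressing towards a terminal, so every policy
#' is proper. Used for property-based testing of the agent and oracle.
#'
#' @param params A [fixture_params()].
#' @param seed Integer seed (generator is deterministic given the seed).
#' @return A `preset_bundle` whose task passes [validate_task()].
#' @export
random_task <- function(params = fixture_params(), seed = 1) {
  set.seed(seed)
  L <- params$n_layers
  k <- params$states_per_layer
  layer_states <- lapply(seq_len(L), function(i) {
    sprintf("L%dS%d", i, seq_len(k))
  })
  terms <- sprintf("T%d", seq_len(max(1L, k %/% 2L + (k %% 2L))))
  all_states <- c(unlist(layer_states), terms)

  costs <- runif(length(all_states) - length(terms),
                 params$cost_range[1], params$cost_range[2])
  rewards <- runif(length(terms), params$reward_range[1],
                   params$reward_range[2])
  states <- tibble::tibble(
    state = all_states,
    u = c(-costs, rewards),
    terminal = c(rep(FALSE, length(all_states) - length(terms)),
                 rep(TRUE, length(terms))))

  rows <- list()
  for (i in seq_len(L)) {
    nxt <- if (i < L) layer_states[[i + 1]] else terms
    for (s in layer_states[[i]]) {
      for (bj in seq_len(params$m)) {
        nb <- min(params$branching, length(nxt))
        targets <- sample(nxt, nb)
        pr <- rexp(nb)
        pr <- pr / sum(pr)
        if (runif(1) < params$reset_prob) {
          # carve a minority share for a reset edge to the entry layer
          share <- runif(1, 0.05, 0.3)
          reset_to <- sample(layer_states[[1]], 1)
          targets <- c(targets, reset_to)
          pr <- c(pr * (1 - share), share)
        }
        # collapse duplicated targets
        agg <- tapply(pr, targets, sum)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          state = s, behaviour = paste0("B", bj),
          next_state = names(agg), prob = as.numeric(agg))
      }
    }
  }
  entry <- tibble::tibble(state = layer_states[[1]],
                          prob = 1 / length(layer_states[[1]]))
  task <- task_spec(states, dplyr::bind_rows(rows), entry,
                    start = layer_states[[1]][1],
                    name = sprintf("random_task_seed%d", seed))
  agent <- agent_config(alpha_v = 0.1, alpha_w = 0.1, beta = 1)
  new_preset_bundle(task, agent,
                    provenance = c("randomly generated layered task",
                                   sprintf("seed %d", seed)),
                    name = task$name)
}

#' Generate a random proper policy
#'
#' Draws a random behaviour distribution for every observation; single
#' behaviour states get a deterministic policy. Properness (terminal
#' reached with probability 1) is verified and the draw repeated a bounded
#' number of times if necessary.
#'
#' @param task A [task_spec()] or preset bundle.
#' @param seed Integer seed.
#' @param max_tries Resampling bound.
#' @return A [policy_spec()].
#' @export
random_policy <- function(task, seed = 1, max_tries = 20) {
  task <- as_task(task)
  ct <- compile_task(task)
  oc <- obs_cols(ct)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    rows <- lapply(seq_len(ct$n_o), function(o) {
      cols <- oc[[o]]
      if (is.null(cols) || !length(cols)) return(NULL)
      pr <- rexp(length(cols))
      pr <- pr / sum(pr)
      tibble::tibble(observation = ct$obs_names[o],
                     behaviour = ct$beh_names[cols], prob = pr)
    })
    policy <- policy_spec(task, dplyr::bind_rows(rows))
    ok <- tryCatch({
      policy_evaluation(task, policy)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(policy)
  }
  abort("Could not draw a proper policy within `max_tries`.")
}
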