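new_preset_bundle <- function(task, agent, provenance, name) {
  structure(list(task = task, agent = agent, provenance = provenance,
                 name = name),
            class = "preset_bundle")
}

#' @export
print.preset_bundle <- function(x, ...) {
  cat(sprintf("<preset_bundle> %s\n", x$name))
  print(x$task)
  print(x$agent)
  cat("provenance:\n")
  cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Behaviour-chain task
#'
#' The canonical sequence-learning environment: `l + 1` states numbered
#' `0..l`. In each state `0..l-1` the animal chooses among `m` behaviours;
#' exactly one ("correct") behaviour advances to the next state, all others
#' return it to state 0. State `l` is terminal with primary value `b > 0`;
#' every other state has the small negative value `-c` of neutral
#' conditions. The entry pattern is the structured family: with probability
#' `p` the task is entered at a random state `0..l-1`, with probability
#' `1 - p` at state 0, so state 0 has entry probability `(1-p) + p/l`.
#'
#' Under uniform initial choice the reward is first found after about `m^l`
#' attempts, which is why start-entry chains of even moderate length are
#' unlearnable without favourable entry or exit patterns.
#'
#' @param l Sequence length (>= 1).
#' @param m Repertoire size per state (>= 1).
#' @param b Reward value of the final state (> 0).
#' @param c Cost (positive magnitude) of non-rewarding states.
#' @param p Random-entry probability in `[0, 1]`.
#' @param agent Recommended agent; default `alpha_v = alpha_w = 0.1`,
#'   `beta = 5`.
#' @return A `preset_bundle`.
#' @export
#' @examples
#' chain_task(l = 4, m = 10)
chain_task <- function(l, m, b = 5, c = 0.2, p = 0,
                       agent = agent_config(alpha_v = 0.1, alpha_w = 0.1,
                                            beta = 5)) {
  if (l < 1 || m < 1) abort("`l` and `m` must be >= 1.")
  if (b <= 0 || c < 0) abort("Need `b` > 0 and `c` >= 0.")
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
  states <- tibble::tibble(
    state = as.character(0:l),
    u = c(rep(-c, l), b),
    terminal = c(rep(FALSE, l), TRUE))
  beh <- paste0("B", seq_len(m))
  correct <- "B1"
  rows <- lapply(0:(l - 1), function(k) {
    tibble::tibble(
      state = as.character(k),
      behaviour = beh,
      next_state = c(as.character(k + 1), rep("0", m - 1)),
      prob = 1)
  })
  entry <- tibble::tibble(
    state = as.character(0:(l - 1)),
    prob = c((1 - p) + p / l, rep(p / l, l - 1)))
  entry <- entry[entry$prob > 0, ]
  task <- task_spec(states, dplyr::bind_rows(rows), entry, start = "0",
                    name = sprintf("chain_l%d_m%d", l, m))
  task$meta <- list(kind = "chain", l = l, m = m, b = b, c = c, p = p,
                    correct = setNames(rep(correct, l),
                                       as.character(0:(l - 1))))
  new_preset_bundle(
    task, agent,
    provenance = c(
      sprintf("chain of l=%d steps, repertoire m=%d per state", l, m),
      sprintf("printed values: reward b=%g, cost c=%g; entry parameter p=%g",
              b, c, p),
      "mistakes reset to state 0; defaults alpha=0.1, beta=5"),
    name = sprintf("chain(l=%d, m=%d)", l, m))
}

#' Preset tasks from the chaining literature
#'
#' Constructors for the classic simulation scenarios, parameterised by the
#' values printed in the corresponding figure captions, with documented
#' defaults for unprinted ones (see each bundle's `provenance`).
#'
#' \describe{
#'   \item{`self_control`}{Take a small reward `b1 = 1` immediately, or
#'     wait (at cost `c = 0.2` per state) for a large reward `b2 = 5`. A
#'     third action, available in all states, leaves the task (a terminal
#'     outside-the-task state valued `-c`; the next attempt re-enters at the
#'     start). Recommended `alpha_v = alpha_w = 0.1`, `beta = 2`.}
#'   \item{`nut_cracking`}{Six-stage chain (start, nut, nut on anvil,
#'     hammer in hand, open nut, eaten) modelling stone-tool nut cracking:
#'     a repertoire of 40 behaviours per state (5 functional, 35 not), a
#'     direct start-to-open-nut "steal" entry with probability 0.01,
#'     mistakes that leave the animal in place with probability 0.75 (else
#'     back to start), and a strike that succeeds with probability 0.75.
#'     Primary values are not printed in the source; defaults are
#'     `u = +5` for the eaten state and `-0.2` elsewhere. Recommended
#'     `alpha_v = alpha_w = 0.05`, `beta = 5`, all initial `v` equal.}
#'   \item{`raccoon`}{Token-deposit misbehaviour: pick up a token, deposit
#'     it for food `b = 2`, with an innate response bias `beta = 3` for
#'     keeping the token (all other pairs `beta = 1`) and initially high
#'     values (5) for the do-nothing and drop actions. `alpha = 0.25`,
#'     `c = 0.2`. The task graph is a documented reconstruction.}
#'   \item{`generic_misbehaviour`}{Two states; behaviour B1 leads to the
#'     reward from either, behaviour B2 costs `c2` and loops between the
#'     states without affecting reachability, but carries an elevated
#'     exploration bias.}
#'   \item{`cronin_nondiagnostic`}{Delayed-reward key discrimination where
#'     both keys lead to the same white delay stimulus (two true states
#'     aliased to one observation): the delay cue is non-diagnostic and the
#'     discrimination cannot be solved.}
#'   \item{`cronin_distinct`}{As above but with distinct delay cues
#'     (yellow after the rewarded red key, blue after green): solvable.}
#'   \item{`cronin_reverse`}{Reverse-cue variant: red leads to yellow then
#'     blue then food, green to blue then yellow then no food, with the
#'     same-colour states aliased. Conditioned value accrues to blue, which
#'     reinforces pecking the unrewarded green key.}
#' }
#'
#' @param name Preset name (see above).
#' @param overrides Named list of parameter overrides; unknown names are an
#'   error. Available parameters are printed in each bundle's provenance
#'   (e.g. `b`, `c`, `beta`, `alpha_v`, `alpha_w`).
#' @return A `preset_bundle` with elements `task`, `agent` (recommended
#'   configuration) and `provenance`.
#' @export
#' @examples
#' build_preset("self_control")
#' build_preset("cronin_reverse")
build_preset <- function(name = c("self_control", "nut_cracking", "raccoon",
                                  "generic_misbehaviour",
                                  "cronin_nondiagnostic", "cronin_distinct",
                                  "cronin_reverse"),
                         overrides = list()) {
  name <- match.arg(name)
  f <- switch(name,
    self_control = preset_self_control,
    nut_cracking = preset_nut_cracking,
    raccoon = preset_raccoon,
    generic_misbehaviour = preset_generic_misbehaviour,
    cronin_nondiagnostic = function(ov) preset_cronin("nondiagnostic", ov),
    cronin_distinct = function(ov) preset_cronin("distinct", ov),
    cronin_reverse = function(ov) preset_cronin("reverse", ov))
  f(overrides)
}

apply_overrides <- function(defaults, overrides) {
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    abort(sprintf("Unknown override(s): %s.", paste(bad, collapse = ", ")))
  }
  utils::modifyList(defaults, overrides)
}

preset_self_control <- function(overrides = list()) {
  pp <- apply_overrides(list(b1 = 1, b2 = 5, c = 0.2, alpha_v = 0.1,
                             alpha_w = 0.1, beta = 2), overrides)
  states <- tibble::tibble(
    state = c("small_reward", "large_reward", "food_small", "food_large"),
    u = c(-pp$c, -pp$c, pp$b1, pp$b2),
    terminal = c(FALSE, FALSE, TRUE, TRUE))
  transitions <- tibble::tibble(
    state = c("small_reward", "small_reward", "small_reward",
              "large_reward", "large_reward"),
    behaviour = c("take", "wait", "leave", "take", "leave"),
    next_state = c("food_small", "large_reward", "small_reward",
                   "food_large", "small_reward"),
    prob = 1)
  task <- task_spec(states, transitions, entry = "small_reward",
                    name = "self_control")
  agent <- agent_config(alpha_v = pp$alpha_v, alpha_w = pp$alpha_w,
                        beta = pp$beta)
  new_preset_bundle(task, agent, provenance = c(
    sprintf("printed: c=%g, b1=%g, b2=%g, alpha_v=%g, alpha_w=%g, beta=%g",
            pp$c, pp$b1, pp$b2, pp$alpha_v, pp$alpha_w, pp$beta),
    "third action 'leave' in all states returns to the initial state, closing the attempt",
    "attempt = segment between two successive visits to the initial state"),
    name = "self_control")
}

preset_nut_cracking <- function(overrides = list()) {
  pp <- apply_overrides(list(
    b = 5, c = 0.2, n_behaviours = 40, steal = 0.01, stay = 0.75,
    strike_success = 0.75, alpha_v = 0.05, alpha_w = 0.05, beta = 5),
    overrides)
  stages <- c("start", "nut", "nut_on_anvil", "hammer_in_hand", "open_nut",
              "eaten")
  functional <- c("take_nut", "put_on_anvil", "take_hammer", "strike", "eat")
  others <- paste0("other", seq_len(pp$n_behaviours - length(functional)))
  beh <- c(functional, others)
  n_stage <- length(stages)

  states <- tibble::tibble(
    state = stages,
    u = c(rep(-pp$c, n_stage - 1), pp$b),
    terminal = c(rep(FALSE, n_stage - 1), TRUE))

  rows <- list()
  for (k in seq_len(n_stage - 1)) {
    s <- stages[k]
    nxt <- stages[k + 1]
    for (bb in beh) {
      if (bb == functional[k]) {
        if (bb == "strike") {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            state = s, behaviour = bb,
            next_state = c(nxt, s),
            prob = c(pp$strike_success, 1 - pp$strike_success))
        } else {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            state = s, behaviour = bb, next_state = nxt, prob = 1)
        }
      } else {
        # mistakes: stay in place with prob `stay`, else back to start
        if (s == "start") {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            state = s, behaviour = bb, next_state = "start", prob = 1)
        } else {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            state = s, behaviour = bb,
            next_state = c(s, "start"),
            prob = c(pp$stay, 1 - pp$stay))
        }
      }
    }
  }
  entry <- tibble::tibble(state = c("start", "open_nut"),
                          prob = c(1 - pp$steal, pp$steal))
  # a failed action at the start leaves the animal in place, still engaged
  # with the task: staying at the start is one continuous visit, so only
  # arrivals from another state close an attempt
  task <- task_spec(states, dplyr::bind_rows(rows), entry, start = "start",
                    attempt_closure = "arrival", name = "nut_cracking")
  task$meta <- list(kind = "chain_like", functional = functional)
  agent <- agent_config(alpha_v = pp$alpha_v, alpha_w = pp$alpha_w,
                        beta = pp$beta)
  new_preset_bundle(task, agent, provenance = c(
    sprintf("printed: steal entry prob %g, mistakes stay with prob %g, strike succeeds with prob %g",
            pp$steal, pp$stay, pp$strike_success),
    sprintf("printed: repertoire of %d behaviours per state, initial choice probability %.3g%% each; alpha_v=%g, alpha_w=%g, beta=%g",
            pp$n_behaviours, 100 / pp$n_behaviours, pp$alpha_v, pp$alpha_w,
            pp$beta),
    sprintf("defaulted (not printed): u(eaten)=+%g, u(other states)=-%g",
            pp$b, pp$c)),
    name = "nut_cracking")
}

preset_raccoon <- function(overrides = list()) {
  pp <- apply_overrides(list(b = 2, c = 0.2, alpha_v = 0.25, alpha_w = 0.25,
                             beta = 1, beta_keep = 3, v_high = 5), overrides)
  states <- tibble::tibble(
    state = c("no_token", "token", "food"),
    u = c(-pp$c, -pp$c, pp$b),
    terminal = c(FALSE, FALSE, TRUE))
  transitions <- tibble::tibble(
    state = c("no_token", "no_token", "token", "token", "token"),
    behaviour = c("pick_up", "do_nothing", "deposit", "keep", "drop"),
    next_state = c("token", "no_token", "food", "token", "no_token"),
    prob = 1)
  task <- task_spec(states, transitions, entry = "no_token",
                    name = "raccoon")
  agent <- agent_config(
    alpha_v = pp$alpha_v, alpha_w = pp$alpha_w, beta = pp$beta,
    beta_map = tibble::tibble(observation = "token", behaviour = "keep",
                              beta = pp$beta_keep),
    v_init = tibble::tibble(
      observation = c("no_token", "token"),
      behaviour = c("do_nothing", "drop"),
      value = pp$v_high))
  new_preset_bundle(task, agent, provenance = c(
    sprintf("printed: c=%g, b=%g, alpha_v=alpha_w=%g; beta=%g everywhere except beta=%g for 'keep' in state 'token'",
            pp$c, pp$b, pp$alpha_v, pp$beta, pp$beta_keep),
    sprintf("printed: initial v(no_token->do_nothing)=v(token->drop)=%g",
            pp$v_high),
    "task graph (pick up / do nothing; deposit / keep / drop) is a reconstruction"),
    name = "raccoon")
}

preset_generic_misbehaviour <- function(overrides = list()) {
  pp <- apply_overrides(list(b = 1, c = 0.2, c2 = 0.2, alpha_v = 0.1,
                             alpha_w = 0.1, beta = 1, beta_b2 = 3),
                        overrides)
  states <- tibble::tibble(
    state = c("S1", "S2", "reward"),
    u = c(-pp$c, -pp$c2, pp$b),
    terminal = c(FALSE, FALSE, TRUE))
  transitions <- tibble::tibble(
    state = c("S1", "S1", "S2", "S2"),
    behaviour = c("B1", "B2", "B1", "B2"),
    next_state = c("reward", "S2", "reward", "S2"),
    prob = 1)
  task <- task_spec(states, transitions, entry = "S1",
                    name = "generic_misbehaviour")
  agent <- agent_config(
    alpha_v = pp$alpha_v, alpha_w = pp$alpha_w, beta = pp$beta,
    beta_map = tibble::tibble(observation = c("S1", "S2"),
                              behaviour = "B2", beta = pp$beta_b2))
  new_preset_bundle(task, agent, provenance = c(
    "useful behaviour B1 reaches the reward from either state; useless B2 costs c2 per choice and loops without affecting reachability",
    sprintf("defaulted (loop topology and values not printed): b=%g, c=%g, c2=%g, beta(B2)=%g elevated vs baseline %g, alpha=%g",
            pp$b, pp$c, pp$c2, pp$beta_b2, pp$beta, pp$alpha_v)),
    name = "generic_misbehaviour")
}

preset_cronin <- function(variant, overrides = list()) {
  pp <- apply_overrides(list(b = 1, c = 0.2, alpha_v = 0.1, alpha_w = 0.05,
                             beta = 5), overrides)
  mk <- function(states, transitions, observe = NULL) {
    task_spec(states, transitions, entry = "choice",
              observe = observe, name = paste0("cronin_", variant))
  }
  if (variant == "nondiagnostic") {
    states <- tibble::tibble(
      state = c("choice", "white1", "white2", "food", "no_food"),
      u = c(-pp$c, -pp$c, -pp$c, pp$b, -pp$c),
      terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE))
    transitions <- tibble::tibble(
      state = c("choice", "choice", "white1", "white2"),
      behaviour = c("peck_red", "peck_green", "wait", "wait"),
      next_state = c("white1", "white2", "food", "no_food"),
      prob = 1)
    observe <- tibble::tibble(
      state = states$state,
      observation = c("choice", "white", "white", "food", "no_food"))
    task <- mk(states, transitions, observe)
    aliased <- "delay cue aliased: white1/white2 -> 'white'"
  } else if (variant == "distinct") {
    states <- tibble::tibble(
      state = c("choice", "yellow", "blue", "food", "no_food"),
      u = c(-pp$c, -pp$c, -pp$c, pp$b, -pp$c),
      terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE))
    transitions <- tibble::tibble(
      state = c("choice", "choice", "yellow", "blue"),
      behaviour = c("peck_red", "peck_green", "wait", "wait"),
      next_state = c("yellow", "blue", "food", "no_food"),
      prob = 1)
    task <- mk(states, transitions)
    aliased <- "distinct delay cues; no aliasing"
  } else {
    states <- tibble::tibble(
      state = c("choice", "yellow1", "blue2", "blue1", "yellow2", "food",
                "no_food"),
      u = c(rep(-pp$c, 5), pp$b, -pp$c),
      terminal = c(rep(FALSE, 5), TRUE, TRUE))
    transitions <- tibble::tibble(
      state = c("choice", "choice", "yellow1", "blue2", "blue1", "yellow2"),
      behaviour = c("peck_red", "peck_green", rep("wait", 4)),
      next_state = c("yellow1", "blue1", "blue2", "food", "yellow2",
                     "no_food"),
      prob = 1)
    observe <- tibble::tibble(
      state = states$state,
      observation = c("choice", "yellow", "blue", "blue", "yellow", "food",
                      "no_food"))
    task <- mk(states, transitions, observe)
    aliased <- "working-memory aliasing: yellow1/yellow2 -> 'yellow', blue1/blue2 -> 'blue'"
  }
  agent <- agent_config(alpha_v = pp$alpha_v, alpha_w = pp$alpha_w,
                        beta = pp$beta)
  new_preset_bundle(task, agent, provenance = c(
    sprintf("printed: c=%g (cost of non-rewarding states, incl. the no-food outcome), b=%g, alpha_v=%g, alpha_w=%g, beta=%g",
            pp$c, pp$b, pp$alpha_v, pp$alpha_w, pp$beta),
    aliased),
    name = paste0("cronin_", variant))
}
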