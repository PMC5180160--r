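# Small tasks built in code, shared across test files.

# single-choice task: one non-terminal state, one behaviour to a reward,
# the rest self-loop back to the start
one_step_task <- function(m = 2, b = 1, c = 0.2) {
  states <- tibble::tibble(state = c("0", "1"),
                           u = c(-c, b), terminal = c(FALSE, TRUE))
  beh <- paste0("B", seq_len(m))
  transitions <- tibble::tibble(
    state = "0", behaviour = beh,
    next_state = c("1", rep("0", m - 1)), prob = 1)
  task_spec(states, transitions, entry = "0", name = "one_step")
}

# one state whose single behaviour succeeds to a reward with probability p
# and otherwise stays in place (a mild exit pattern)
sticky_task <- function(p = 0.75, b = 1, c = 0.2) {
  states <- tibble::tibble(state = c("try", "win"),
                           u = c(-c, b), terminal = c(FALSE, TRUE))
  transitions <- tibble::tibble(
    state = "try", behaviour = "go",
    next_state = c("win", "try"), prob = c(p, 1 - p))
  task_spec(states, transitions, entry = "try", name = "sticky")
}

# two aliased delay states with different outcomes
aliased_task <- function(b = 1, c = 0.2) {
  states <- tibble::tibble(
    state = c("choice", "d1", "d2", "food", "none"),
    u = c(-c, -c, -c, b, -c),
    terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  transitions <- tibble::tibble(
    state = c("choice", "choice", "d1", "d2"),
    behaviour = c("left", "right", "wait", "wait"),
    next_state = c("d1", "d2", "food", "none"), prob = 1)
  observe <- tibble::tibble(
    state = states$state,
    observation = c("choice", "delay", "delay", "food", "none"))
  task_spec(states, transitions, entry = "choice", observe = observe,
            name = "aliased")
}

softmax_of <- function(sim, observation, beta) {
  v <- sim$v
  vv <- setNames(v$value[v$observation == observation],
                 v$behaviour[v$observation == observation])
  action_probabilities(vv, beta)
}
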