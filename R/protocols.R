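#' Backward-chaining training protocol
#'
#' Returns a simulation hook implementing the animal-training technique of
#' teaching a sequence from its last step: the learner is always placed at
#' the highest chain state whose correct behaviour has not yet been
#' mastered, so that exactly one behaviour is being learned at a time and
#' the states ahead of it have already acquired conditioned value. Once all
#' steps are mastered, entry reverts to state 0. Learning time under this
#' protocol grows linearly in the sequence length instead of exponentially.
#'
#' @param bundle A chain-structured [preset_bundle][chain_task()].
#' @param threshold A chain step counts as learned when the agent's softmax
#'   probability of its correct behaviour exceeds this value.
#' @return A hook function for [run_simulation()] (class
#'   `chaining_protocol`); its environment exposes `complete`.
#' @export
backward_chaining_protocol <- function(bundle, threshold = 0.75) {
  meta <- chain_meta(bundle)
  l <- meta$l
  env <- new.env(parent = emptyenv())
  env$complete <- FALSE
  hook <- function(ctx) {
    ct <- ctx$task
    learned <- correct_probs(ct, ctx$agent, meta) > threshold
    if (all(learned)) {
      env$complete <- TRUE
      set_entry(ct, tibble::tibble(state = "0", prob = 1))
    } else {
      env$complete <- FALSE
      target <- max(which(!learned)) - 1L  # states are labelled 0..l-1
      set_entry(ct, tibble::tibble(state = as.character(target), prob = 1))
    }
    invisible(NULL)
  }
  structure(hook, class = c("chaining_protocol", "function"), env = env)
}

#' Forward-chaining training protocol
#'
#' Returns a simulation hook implementing forward chaining: training starts
#' from the first step with the reward structure altered so that reaching
#' state 1 is itself rewarded (state 1 is made temporarily terminal with
#' the reward value). Each time the trailing-window criterion is met, the
#' reward frontier advances one state (the original values restored behind
#' it) until the true reward state is reached. Entry stays at state 0
#' throughout; learning time grows linearly in the sequence length.
#'
#' @param bundle A chain-structured [preset_bundle][chain_task()].
#' @param criterion A [learning_criterion()] deciding when the frontier
#'   advances (evaluated on attempts since the last advance).
#' @return A hook function for [run_simulation()] (class
#'   `chaining_protocol`); its environment exposes `frontier` and
#'   `complete` (frontier at the true reward state).
#' @export
forward_chaining_protocol <- function(bundle,
                                      criterion = learning_criterion()) {
  meta <- chain_meta(bundle)
  l <- meta$l
  env <- new.env(parent = emptyenv())
  env$frontier <- 1L
  env$since <- 0L
  env$complete <- l == 1L
  hook <- function(ctx) {
    ct <- ctx$task
    if (!env$complete) {
      # criterion on attempts since the frontier was last moved
      n <- length(ctx$reached) - env$since
      if (n >= criterion$window) {
        recent <- tail(ctx$reached, criterion$window)
        if (mean(recent) >= criterion$threshold) {
          env$frontier <- env$frontier + 1L
          env$since <- length(ctx$reached)
          env$complete <- env$frontier >= l
        }
      }
    }
    k <- min(env$frontier, l)
    # state k temporarily terminal and rewarded; original chain beyond it
    for (s in seq_len(ct$n_s)) {
      idx <- s - 1L  # chain labels are 0..l
      ct$terminal[s] <- idx >= k
      ct$u[s] <- if (idx >= k) meta$b else -meta$c
    }
    invisible(NULL)
  }
  structure(hook, class = c("chaining_protocol", "function"), env = env)
}

chain_meta <- function(bundle) {
  task <- as_task(bundle)
  meta <- task$meta
  if (is.null(meta$kind) || meta$kind != "chain") {
    abort("This protocol requires a chain-structured task (see chain_task()).")
  }
  meta
}

# softmax probability of the correct behaviour in each chain state 0..l-1
correct_probs <- function(ct, ag, meta) {
  vapply(seq_len(meta$l), function(k) {
    s <- match(as.character(k - 1), ct$state_names)
    o <- ct$obs_of[s]
    cols <- ct$rep_cols[[s]]
    p <- action_probabilities(ag$V[o, cols], ag$Beta[o, cols])
    names(p) <- ct$beh_names[cols]
    p[[meta$correct[[as.character(k - 1)]]]]
  }, numeric(1))
}
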