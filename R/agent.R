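#' Configure a chaining agent
#'
#' The agent learns two tables keyed by observation labels: state-behaviour
#' values `v` (the estimated total primary-plus-conditioned value obtained by
#' choosing a behaviour), and conditioned reinforcement values `w` (the
#' learned value of a state that predicts reward). Behaviour is chosen by a
#' softmax over `beta * v`; after a transition to state S' the updates are
#'
#' \deqn{\Delta v_{S \to B} = \alpha_v (u_{S'} + w_{S'} - v_{S \to B})}
#' \deqn{\Delta w_S = \alpha_w (u_{S'} + w_{S'} - w_S)}
#'
#' both computed from the same pre-update snapshot. Every parameter can be
#' made context dependent, which is how genetic predispositions enter the
#' model: per-pair `beta` biases which behaviours are explored, per-context
#' learning rates control which associations can form, and initial `v`
#' overrides encode innate responses.
#'
#' @param alpha_v Learning rate for `v`, in `[0, 1]`. Either a scalar or a
#'   data frame of overrides with columns `observation`, `behaviour`,
#'   optionally `next_observation`, and `alpha` (unlisted contexts fall back
#'   to `default`, which then must be supplied as the `default` column-less
#'   scalar via `alpha_v_default`).
#' @param alpha_w Learning rate for `w`, in `[0, 1]`; scalar or data frame
#'   with columns `observation`, optionally `next_observation`, and `alpha`.
#' @param alpha_v_default,alpha_w_default Scalar fallbacks used when the
#'   corresponding rate is given as an override table.
#' @param beta Scalar default exploration parameter. `beta = 0` makes all
#'   behaviours equally likely; large `beta` concentrates choice on the
#'   highest-valued behaviour.
#' @param beta_map Optional data frame `(observation, behaviour, beta)` of
#'   static per-pair exploration parameters overriding the default.
#' @param modulation Optional data frame `(observation, behaviour, beta0)`
#'   of prediction-error modulation rules: for a matching pair the effective
#'   exploration parameter is `beta0 - d_v`, where `d_v` is the prediction
#'   error of the immediately preceding transition of the attempt (treated
#'   as 0 at the first step of an attempt). A negative `d_v` (smaller reward
#'   than expected) therefore makes the behaviour more likely. At most one
#'   rule may match a behaviour per observation.
#' @param v_init Optional data frame `(observation, behaviour, value)` of
#'   initial `v` entries; unlisted pairs start at 0.
#' @param w_init Initial conditioned value: scalar (default 0) or data frame
#'   `(observation, value)`. Terminal observations are pinned to 0 and are
#'   never updated.
#' @param chaining If `FALSE` the conditioned reinforcement term is removed
#'   entirely: `w` stays at 0 and the `v` update target is the primary value
#'   alone (the classic single-behaviour delta rule). Used as the baseline
#'   model that can optimise single choices but not sequences.
#'
#' @return An object of class `agent_config`.
#' @export
#' @examples
#' agent_config(alpha_v = 0.1, alpha_w = 0.1, beta = 2)
agent_config <- function(alpha_v = 0.1, alpha_w = 0.1,
                         alpha_v_default = NULL, alpha_w_default = NULL,
                         beta = 1, beta_map = NULL, modulation = NULL,
                         v_init = NULL, w_init = 0, chaining = TRUE) {
  chk_rate_arg <- function(x, default, what) {
    if (is.data.frame(x)) {
      x <- tibble::as_tibble(x)
      if (!"alpha" %in% names(x) || !"observation" %in% names(x)) {
        abort(sprintf("`%s` override table needs `observation` and `alpha`.",
                      what))
      }
      assert_rate(x$alpha, what)
      default <- default %||% 0
      assert_rate(default, paste0(what, "_default"))
      list(default = default, map = x)
    } else {
      assert_scalar_number(x, what)
      assert_rate(x, what)
      list(default = x, map = NULL)
    }
  }
  av <- chk_rate_arg(alpha_v, alpha_v_default, "alpha_v")
  aw <- chk_rate_arg(alpha_w, alpha_w_default, "alpha_w")
  assert_scalar_number(beta, "beta")
  if (!is.null(beta_map)) {
    beta_map <- tibble::as_tibble(beta_map)
    assert_finite(beta_map$beta, "beta_map$beta")
  }
  if (!is.null(modulation)) {
    modulation <- tibble::as_tibble(modulation)
    assert_finite(modulation$beta0, "modulation$beta0")
    if (anyDuplicated(modulation[c("observation", "behaviour")])) {
      abort("A behaviour may match at most one modulation rule per observation.")
    }
  }
  if (!is.null(v_init)) {
    v_init <- tibble::as_tibble(v_init)
    assert_finite(v_init$value, "v_init$value")
  }
  if (is.data.frame(w_init)) {
    w_init <- tibble::as_tibble(w_init)
    assert_finite(w_init$value, "w_init$value")
  } else {
    assert_scalar_number(w_init, "w_init")
  }
  structure(
    list(alpha_v = av$default, alpha_v_map = av$map,
         alpha_w = aw$default, alpha_w_map = aw$map,
         beta = beta, beta_map = beta_map, modulation = modulation,
         v_init = v_init, w_init = w_init, chaining = chaining),
    class = "agent_config")
}

#' @export
print.agent_config <- function(x, ...) {
  cat(sprintf("<agent_config> alpha_v=%s alpha_w=%s beta=%s%s\n",
              format(x$alpha_v), format(x$alpha_w), format(x$beta),
              if (!x$chaining) " (no conditioned reinforcement)" else ""))
  if (!is.null(x$beta_map)) cat(sprintf("  %d beta override(s)\n", nrow(x$beta_map)))
  if (!is.null(x$modulation)) cat(sprintf("  %d modulation rule(s)\n", nrow(x$modulation)))
  if (!is.null(x$v_init)) cat(sprintf("  %d initial-v override(s)\n", nrow(x$v_init)))
  invisible(x)
}

#' Softmax choice probabilities
#'
#' Probability of each behaviour under the softmax decision rule
#' \eqn{P(B) \propto e^{\beta_B v_B}}, computed overflow-safely by shifting
#' scores by their maximum before exponentiation. With a common `beta` the
#' relative choice odds of two behaviours are `exp(beta * (v1 - v2))`, the
#' matching-law form.
#'
#' @param values Numeric vector of state-behaviour values, one per available
#'   behaviour (names, if any, are preserved).
#' @param betas Exploration parameter(s): scalar or a vector aligned with
#'   `values`.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' action_probabilities(c(3, -1, 7), 0)      # uniform at beta = 0
#' action_probabilities(c(1, 0.5), 2)        # odds ratio exp(1)
action_probabilities <- function(values, betas) {
  if (length(values) == 0L) abort("At least one behaviour is required.")
  assert_finite(values, "values")
  assert_finite(betas, "betas")
  if (length(betas) == 1L) betas <- rep(betas, length(values))
  if (length(betas) != length(values)) {
    abort("`betas` must be scalar or aligned with `values`.")
  }
  s <- betas * values
  e <- exp(s - max(s))
  p <- e / sum(e)
  names(p) <- names(values)
  p
}

#' Sample behaviours from a choice distribution
#'
#' @param prob Probability vector (non-negative, positive sum); normalised
#'   internally.
#' @param n Number of draws.
#' @return Integer indices into `prob` (named if `prob` has names, the
#'   labels are returned instead).
#' @export
sample_behaviour <- function(prob, n = 1) {
  assert_finite(prob, "prob")
  if (any(prob < 0) || sum(prob) <= 0) {
    abort("`prob` must be non-negative with positive sum.")
  }
  p <- prob / sum(prob)
  idx <- findInterval(runif(n), cumsum(p), left.open = TRUE) + 1L
  idx <- pmin(idx, length(p))
  if (!is.null(names(prob))) names(prob)[idx] else idx
}

#' Prediction error of a transition
#'
#' The discrepancy `d_v = u' + w' - v` between the realised value of the
#' state entered (primary plus conditioned) and the current estimate for the
#' chosen behaviour. Negative values signal a smaller reward than expected.
#' Vectorised over its arguments.
#'
#' @param u_next Primary value of the state entered.
#' @param w_next Conditioned value of the state entered (0 for terminals).
#' @param v_current Current state-behaviour value estimate.
#' @return Numeric prediction error(s).
#' @export
prediction_error <- function(u_next, w_next, v_current) {
  assert_finite(u_next, "u_next")
  assert_finite(w_next, "w_next")
  assert_finite(v_current, "v_current")
  u_next + w_next - v_current
}

#' Single-behaviour value update (no conditioned reinforcement)
#'
#' The classic delta-rule update `v + alpha_v * (u' - v)`, which tracks the
#' (average) primary value of the following state. It can optimise a single
#' behavioural choice but not a sequence, because intermediate states carry
#' no primary value.
#'
#' @param v_current Current value estimate.
#' @param u_next Primary value experienced.
#' @param alpha_v Learning rate in `[0, 1]`.
#' @return Updated value.
#' @export
update_value_simple <- function(v_current, u_next, alpha_v) {
  assert_finite(v_current, "v_current")
  assert_finite(u_next, "u_next")
  assert_rate(alpha_v, "alpha_v")
  v_current + alpha_v * (u_next - v_current)
}

#' Apply the chaining updates to value tables
#'
#' Applies one experienced transition to tabular `v` and `w` tables. Both
#' update targets are computed from the same pre-update snapshot, only the
#' entries of the current observation (and chosen behaviour) change, and the
#' conditioned value of a terminal observation is pinned at 0: if the state
#' entered is terminal its stored `w` is ignored and 0 is used, because an
#' attempt's return sums primary values only up to the task-ending state.
#'
#' @param v Data frame `(observation, behaviour, value)`.
#' @param w Data frame `(observation, value, terminal)`.
#' @param transition List or one-row data frame with `observation`,
#'   `behaviour`, `next_observation`, `u_next` and `terminal` (whether the
#'   state entered is terminal).
#' @param alpha_v,alpha_w Learning rates in `[0, 1]`.
#' @return A list with the updated `v` and `w` tibbles and the scalar
#'   `prediction_error`.
#' @export
update_values <- function(v, w, transition, alpha_v = 0.1, alpha_w = 0.1) {
  assert_rate(alpha_v, "alpha_v")
  assert_rate(alpha_w, "alpha_w")
  v <- tibble::as_tibble(v)
  w <- tibble::as_tibble(w)
  tr <- as.list(transition)
  iv <- which(v$observation == tr$observation & v$behaviour == tr$behaviour)
  iw <- which(w$observation == tr$observation)
  if (length(iv) != 1L) {
    abort(sprintf("No v entry for (%s, %s).", tr$observation, tr$behaviour))
  }
  if (length(iw) != 1L) {
    abort(sprintf("No w entry for observation %s.", tr$observation))
  }
  w_next <- if (isTRUE(tr$terminal)) 0 else {
    iw2 <- which(w$observation == tr$next_observation)
    if (length(iw2) != 1L) {
      abort(sprintf("No w entry for observation %s.", tr$next_observation))
    }
    if (isTRUE(w$terminal[iw2])) 0 else w$value[iw2]
  }
  target <- tr$u_next + w_next
  d_v <- target - v$value[iv]
  d_w <- target - w$value[iw]
  v$value[iv] <- v$value[iv] + alpha_v * d_v
  if (!isTRUE(w$terminal[iw])) {
    w$value[iw] <- w$value[iw] + alpha_w * d_w
  }
  list(v = v, w = w, prediction_error = d_v)
}

#' Effective exploration parameter for one choice
#'
#' Resolves the exploration parameter used for a behaviour in an
#' observation: if a modulation rule matches, the rule's baseline minus the
#' most recent prediction error (`beta0 - d_v`; the baseline itself at the
#' first step of an attempt, when no transition has yet occurred); otherwise
#' the static per-pair entry, falling back to the scalar default.
#'
#' @param agent An [agent_config()].
#' @param observation,behaviour Labels identifying the choice.
#' @param last_d_v Prediction error of the immediately preceding transition,
#'   or `NULL` at the start of an attempt.
#' @return The effective `beta` (scalar).
#' @export
effective_beta <- function(agent, observation, behaviour, last_d_v = NULL) {
  if (!is.null(agent$modulation)) {
    m <- agent$modulation
    i <- which(m$observation == observation & m$behaviour == behaviour)
    if (length(i) == 1L) {
      return(m$beta0[i] - (if (is.null(last_d_v)) 0 else last_d_v))
    }
  }
  if (!is.null(agent$beta_map)) {
    b <- agent$beta_map
    i <- which(b$observation == observation & b$behaviour == behaviour)
    if (length(i) == 1L) return(b$beta[i])
  }
  agent$beta
}

#' Initial value tables of an agent bound to a task
#'
#' @param task A [task_spec()].
#' @param agent An [agent_config()].
#' @return List of tibbles `v` (`observation`, `behaviour`, `value`) and `w`
#'   (`observation`, `value`, `terminal`).
#' @export
value_tables <- function(task, agent = agent_config()) {
  ct <- compile_task(task)
  ag <- compile_agent(ct, agent)
  list(v = v_table_from_matrix(ct, ag$V), w = w_table_from_vector(ct, ag$W))
}
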