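test_that("softmax choice probabilities match the closed forms", {
  # beta = 0 makes all behaviours equally likely
  expect_equal(unname(action_probabilities(c(3, -1, 7), 0)), rep(1 / 3, 3))
  # matching law: odds scale as exp(beta * (v1 - v2))
  p <- action_probabilities(c(1, 0.5), 2)
  expect_equal(p[1] / p[2], exp(1), tolerance = 1e-12)
  # single behaviour gets probability 1 regardless of value or beta
  expect_equal(unname(action_probabilities(5, -3)), 1)
  expect_error(action_probabilities(numeric(0), 1), "one behaviour")
})

test_that("softmax is normalized, shift-invariant and monotone", {
  set.seed(42)
  for (i in 1:30) {
    # extreme scores, |beta * v| up to 1e4: still normalized, no overflow
    k <- sample(2:8, 1)
    v <- runif(k, -100, 100)
    beta <- runif(1, 0, 100)
    p <- action_probabilities(v, beta)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  for (i in 1:30) {
    # moderate scores: shift invariance and strict monotonicity
    k <- sample(2:8, 1)
    v <- runif(k, -3, 3)
    beta <- runif(1, 0.1, 5)
    p <- action_probabilities(v, beta)
    # adding a constant to all values leaves the distribution unchanged
    p2 <- action_probabilities(v + 57.3, beta)
    expect_equal(p, p2, tolerance = 1e-12)
    # increasing one value strictly increases its probability (beta > 0)
    j <- sample(k, 1)
    v3 <- v
    v3[j] <- v3[j] + 1
    p3 <- action_probabilities(v3, beta)
    expect_gt(p3[j], p[j])
  }
  # extreme scores do not overflow
  p <- action_probabilities(c(1e4, -1e4), 1)
  expect_equal(sum(p), 1)
  expect_false(anyNA(p))
})

test_that("behaviour sampling is seeded and matches its distribution", {
  set.seed(1)
  a <- sample_behaviour(c(x = 0.25, y = 0.75), 20)
  set.seed(1)
  b <- sample_behaviour(c(x = 0.25, y = 0.75), 20)
  expect_identical(a, b)
  expect_identical(sample_behaviour(c(only = 1), 5), rep("only", 5))
  expect_error(sample_behaviour(c(0, 0)), "positive sum")
  # goodness of fit on a large sample
  set.seed(99)
  draws <- sample_behaviour(c(A = 0.25, B = 0.75), 1e5)
  tab <- table(factor(draws, levels = c("A", "B")))
  expect_gt(stats::chisq.test(tab, p = c(0.25, 0.75))$p.value, 0.001)
})

test_that("prediction error is the realized-minus-estimated value", {
  expect_equal(prediction_error(1, 0, 0), 1)
  expect_equal(prediction_error(0, 0, 1), -1)   # omitted reward
  expect_equal(prediction_error(-0.2, 0.5, 0.3), 0)
  expect_error(prediction_error(NA, 0, 0), "finite")
})

test_that("the single-behaviour delta rule converges geometrically", {
  expect_equal(update_value_simple(0, 1, 1), 1)
  v <- 0
  for (i in 1:3) v <- update_value_simple(v, 1, 0.5)
  expect_equal(v, 1 - 0.5^3)
  expect_error(update_value_simple(0, 1, 1.5), "rejected")
})

test_that("the delta rule tracks the average reward of a stochastic outcome", {
  set.seed(7)
  v <- 0
  u <- rep(c(0, 1), 5000)  # alternating outcomes, mean 0.5
  for (x in u) v <- update_value_simple(v, x, 0.01)
  expect_lt(abs(v - 0.5), 0.05)
})

test_that("table updates follow the chaining rules from one snapshot", {
  v <- tibble::tibble(observation = c("a", "a"), behaviour = c("go", "stay"),
                      value = c(0, 0))
  w <- tibble::tibble(observation = c("a", "b", "end"),
                      value = c(0, 0.5, 0.7),
                      terminal = c(FALSE, FALSE, TRUE))
  out <- update_values(v, w, list(observation = "a", behaviour = "go",
                                  next_observation = "b", u_next = 1,
                                  terminal = FALSE),
                       alpha_v = 0.1, alpha_w = 0.1)
  expect_equal(out$v$value[out$v$behaviour == "go"], 0.15)   # 0.1*(1+0.5)
  expect_equal(out$w$value[out$w$observation == "a"], 0.15)
  expect_equal(out$prediction_error, 1.5)
  # only the touched entries change
  expect_equal(out$v$value[out$v$behaviour == "stay"], 0)
  expect_equal(out$w$value[out$w$observation == "b"], 0.5)

  # a negative-value outcome
  out2 <- update_values(v, w, list(observation = "a", behaviour = "go",
                                   next_observation = "b", u_next = -0.2,
                                   terminal = FALSE),
                        alpha_v = 0.1, alpha_w = 0.1)
  expect_equal(out2$w$value[1], 0.1 * (-0.2 + 0.5))

  # a terminal successor contributes 0, not its stored w
  out3 <- update_values(v, w, list(observation = "a", behaviour = "go",
                                   next_observation = "end", u_next = 1,
                                   terminal = TRUE),
                        alpha_v = 0.1, alpha_w = 0.1)
  expect_equal(out3$v$value[1], 0.1 * 1)

  expect_error(update_values(v, w, list(observation = "zz", behaviour = "go",
                                        next_observation = "b", u_next = 0,
                                        terminal = FALSE)),
               "No v entry")
  expect_error(update_values(v, w, list(observation = "a", behaviour = "go",
                                        next_observation = "b", u_next = 0,
                                        terminal = FALSE), alpha_v = -0.1),
               "non-negative")
})

test_that("prediction-error modulation adjusts the exploration parameter", {
  agent <- agent_config(
    beta = 2,
    beta_map = tibble::tibble(observation = "s", behaviour = "flee",
                              beta = 7),
    modulation = tibble::tibble(observation = "s", behaviour = "attack",
                                beta0 = 2))
  # no matching rule: static map entry, then the scalar default
  expect_equal(effective_beta(agent, "s", "flee", last_d_v = -1), 7)
  expect_equal(effective_beta(agent, "s", "peck", last_d_v = -1), 2)
  # omitted reward (d_v < 0) raises beta for the modulated behaviour
  expect_equal(effective_beta(agent, "s", "attack", last_d_v = -1), 3)
  # larger-than-expected reward suppresses it
  expect_equal(effective_beta(agent, "s", "attack", last_d_v = 1), 1)
  # first step of an attempt: the baseline
  expect_equal(effective_beta(agent, "s", "attack", last_d_v = NULL), 2)
})

test_that("agent configuration rejects invalid rates and duplicate rules", {
  expect_error(agent_config(alpha_v = 1.2), "rejected")
  expect_error(agent_config(alpha_v = -0.1), "non-negative")
  expect_error(agent_config(modulation = tibble::tibble(
    observation = c("s", "s"), behaviour = c("a", "a"), beta0 = c(1, 2))),
    "at most one")
})

test_that("initial-v overrides must reference existing pairs", {
  task <- one_step_task()
  agent <- agent_config(v_init = tibble::tibble(
    observation = "0", behaviour = "nosuch", value = 1))
  expect_error(value_tables(task, agent), "unknown")
  tabs <- value_tables(task, agent_config(
    v_init = tibble::tibble(observation = "0", behaviour = "B2", value = 5)))
  expect_equal(tabs$v$value[tabs$v$behaviour == "B2"], 5)
  expect_equal(tabs$v$value[tabs$v$behaviour == "B1"], 0)
  expect_true(all(tabs$w$value == 0))
})
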