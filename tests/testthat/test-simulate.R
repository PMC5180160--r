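test_that("both engines produce bit-identical trajectories and tables", {
  for (seed in 1:5) {
    b <- random_task(fixture_params(reset_prob = 0.3), seed = seed)
    s_cpp <- run_simulation(b, n_attempts = 200, seed = seed, engine = "cpp")
    s_r <- run_simulation(b, n_attempts = 200, seed = seed, engine = "r")
    expect_identical(s_cpp$attempts, s_r$attempts)
    expect_identical(s_cpp$transitions, s_r$transitions)
    expect_identical(s_cpp$state$V, s_r$state$V)
    expect_identical(s_cpp$state$W, s_r$state$W)
  }
  # also on a preset with beta maps and aliasing
  s1 <- run_simulation(build_preset("cronin_reverse"), n_attempts = 300,
                       seed = 9, engine = "cpp")
  s2 <- run_simulation(build_preset("cronin_reverse"), n_attempts = 300,
                       seed = 9, engine = "r")
  expect_identical(s1$state$V, s2$state$V)
})

test_that("simulations are seed-deterministic end to end", {
  b <- build_preset("raccoon")
  a <- run_simulation(b, n_attempts = 300, seed = 123, snapshot_every = 50)
  c <- run_simulation(b, n_attempts = 300, seed = 123, snapshot_every = 50)
  expect_identical(a$attempts, c$attempts)
  expect_identical(a$snapshots, c$snapshots)
  expect_identical(a$v, c$v)
})

test_that("attempts are delimited by start-state visits and terminals", {
  # single correct step at high beta: attempt = one step to reward
  task <- one_step_task(m = 2)
  agent <- agent_config(beta = 50,
                        v_init = tibble::tibble(observation = "0",
                                                behaviour = "B1", value = 1))
  sim <- run_simulation(task, agent, n_attempts = 20, seed = 1)
  expect_true(all(sim$attempts$steps == 1))
  expect_true(all(sim$attempts$ended == "terminal"))
  expect_true(all(sim$attempts$reached_reward))

  # mistakes close the attempt by returning to the start
  agent2 <- agent_config(beta = 50,
                         v_init = tibble::tibble(observation = "0",
                                                 behaviour = "B2", value = 1))
  sim2 <- run_simulation(task, agent2, n_attempts = 5, seed = 1)
  expect_equal(sim2$attempts$ended[1], "reset")

  # transitions partition into attempts and conserve collected value
  b <- chain_task(l = 3, m = 2)
  sim3 <- run_simulation(b, n_attempts = 100, seed = 2)
  tr <- sim3$transitions
  expect_equal(nrow(tr), sum(sim3$attempts$steps))
  sums <- tapply(tr$u, tr$attempt, sum)
  expect_equal(as.numeric(sums[as.character(sim3$attempts$attempt)]),
               sim3$attempts$total_u)
  # observation bookkeeping is consistent in the trace
  expect_equal(tr$observation, tr$state)  # identity map here
})

test_that("the step cap flags an attempt instead of raising", {
  # a task whose only behaviour loops without reaching the start or a
  # terminal within the cap
  states <- tibble::tibble(state = c("a", "b", "win"),
                           u = c(-0.1, -0.1, 1),
                           terminal = c(FALSE, FALSE, TRUE))
  transitions <- tibble::tibble(
    state = c("a", "b", "b"), behaviour = "go",
    next_state = c("b", "b", "win"), prob = c(1, 0.999, 0.001))
  task <- task_spec(states, transitions, entry = "a")
  sim <- run_simulation(task, agent_config(beta = 0), n_attempts = 3,
                        seed = 1, max_steps = 50, record = "attempts")
  expect_true(any(sim$attempts$ended == "cap"))
})

test_that("an empty simulation returns the parameter echo", {
  sim <- run_simulation(one_step_task(), n_attempts = 0, seed = 1)
  expect_equal(nrow(sim$attempts), 0)
  expect_equal(sim$params$n_attempts, 0)
  expect_s3_class(sim$params$agent, "agent_config")
})

test_that("aliased states share value-table entries", {
  sim <- run_simulation(aliased_task(), n_attempts = 200, seed = 5)
  # only observation labels appear in the tables
  expect_setequal(unique(sim$v$observation),
                  c("choice", "delay"))
  tr <- sim$transitions
  expect_true(all(tr$observation[tr$state %in% c("d1", "d2")] == "delay"))
})

test_that("values stay bounded by the maximal attempt return", {
  # |v|, |w| <= U * T under rates <= 1, attempts capped at T steps
  for (seed in 1:5) {
    b <- random_task(fixture_params(reset_prob = 0.3), seed = seed)
    U <- max(abs(b$task$states$u))
    Tcap <- 200
    ag <- agent_config(alpha_v = 1, alpha_w = 1, beta = 2)
    sim <- run_simulation(b$task, ag, n_attempts = 500, seed = seed,
                          max_steps = Tcap, record = "attempts")
    expect_true(all(abs(sim$v$value) <= U * Tcap))
    expect_true(all(abs(sim$w$value) <= U * Tcap))
  }
})

test_that("the expected one-step change in w matches its analytic form", {
  # hold the tables fixed and resample one transition many times: the mean
  # change in w must equal alpha_w * (sum_S' P(S,S') (u' + w') - w) within
  # Monte-Carlo error
  task <- sticky_task(p = 0.6, b = 2, c = 0.3)
  v <- tibble::tibble(observation = c("try", "try"),
                      behaviour = c("go", "go"), value = 0.4)[1, ]
  w <- tibble::tibble(observation = c("try", "win"), value = c(0.25, 0),
                      terminal = c(FALSE, TRUE))
  alpha_w <- 0.1
  outcomes <- list(
    list(next_observation = "win", u_next = 2, terminal = TRUE, p = 0.6),
    list(next_observation = "try", u_next = -0.3, terminal = FALSE, p = 0.4))
  dw <- vapply(outcomes, function(o) {
    res <- update_values(v, w, c(list(observation = "try",
                                      behaviour = "go"), o),
                         alpha_v = 0.1, alpha_w = alpha_w)
    res$w$value[1] - w$value[1]
  }, numeric(1))
  set.seed(20)
  n <- 1e5
  draws <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  mc <- mean(dw[draws])
  se <- stats::sd(dw[draws]) / sqrt(n)
  analytic <- alpha_w * (0.6 * (2 + 0) + 0.4 * (-0.3 + 0.25) - 0.25)
  expect_lt(abs(mc - analytic), 3 * se + 1e-12)
})

test_that("simulation results tidy, glance and plot", {
  sim <- run_simulation(chain_task(2, 2), n_attempts = 150, seed = 1,
                        snapshot_every = 50)
  expect_s3_class(tidy(sim), "tbl_df")
  expect_equal(nrow(tidy(sim)), 150)
  expect_named(glance(sim),
               c("n_attempts", "n_steps", "reward_rate",
                 "final_reward_rate", "total_u", "capped_attempts", "seed"))
  expect_s3_class(tidy(sim, "snapshots"), "tbl_df")
  expect_s3_class(autoplot(sim), "ggplot")
})

test_that("single attempts carry a full per-step trace", {
  tr <- run_attempt(chain_task(2, 2), seed = 3)
  expect_true(all(c("state", "observation", "behaviour", "next_state",
                    "u", "d_v", "terminal") %in% names(tr)))
  expect_equal(nrow(tr), attr(tr, "summary")$steps)
})
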