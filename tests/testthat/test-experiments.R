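test_that("scaling formulas reproduce the printed closed forms", {
  expect_equal(formula_learning_time("start", a = 1, m = 2, l = 3), 8)
  expect_equal(formula_learning_time("random", a = 1, m = 2, l = 3), 12)
  expect_equal(formula_learning_time("highest_unlearned", a = 1, m = 2,
                                     l = 3), 6)
  expect_equal(formula_learning_time("forward", a = 2, m = 3, l = 4), 24)
  expect_equal(formula_learning_time("favourable_exit", m = 2, l = 3), 12)
  expect_equal(formula_learning_time("start", a = 1, m = 10, l = 4), 10000)
  expect_error(formula_learning_time("start", a = 0, m = 2, l = 2),
               "positive")
  expect_error(formula_learning_time("nosuch", 1, 2, 2))

  expect_equal(sequence_count(40, 5), 40^5)
  expect_equal(repertoire_reduction(3), 0.125)
  expect_equal(repertoire_reduction(4), 0.0625)
})

test_that("trivially easy tasks meet the criterion almost immediately", {
  res <- attempts_to_learn(chain_task(l = 1, m = 1), seed = 1, cap = 1000)
  expect_false(res$capped)
  expect_lte(res$attempts, 25)
})

test_that("capped replicates are flagged, never reported as finite times", {
  # an unlearnable criterion (threshold 1 over a long window, m large)
  res <- attempts_to_learn(chain_task(l = 3, m = 10),
                           learning_criterion(window = 50, threshold = 1),
                           seed = 2, cap = 200)
  expect_true(res$capped)
  expect_equal(res$attempts, 200)
})

test_that("uniform search finds the chain reward in about m^l attempts", {
  for (cfg in list(c(m = 2, l = 2), c(m = 2, l = 3), c(m = 3, l = 2))) {
    times <- vapply(1:40, function(sd) {
      attempts_to_first_reward(chain_task(l = cfg["l"], m = cfg["m"]),
                               seed = sd * 31)$attempts
    }, numeric(1))
    expected <- cfg[["m"]]^cfg[["l"]]
    se <- stats::sd(times) / sqrt(length(times))
    expect_lt(abs(mean(times) - expected), 4 * se + 0.05 * expected)
  }
})

test_that("learning time stochastically dominates time to first reward", {
  crit <- learning_criterion()
  for (sd in 1:5) {
    b <- chain_task(l = 2, m = 3)
    t_learn <- attempts_to_learn(b, crit, seed = sd * 7, cap = 50000)
    t_first <- attempts_to_first_reward(b, seed = sd * 7,
                                        agent = b$agent)
    expect_gte(t_learn$attempts, t_first$attempts)
  }
})

test_that("random and facilitated entry shorten learning relative to start entry", {
  start3 <- vapply(1:6, function(sd) {
    attempts_to_learn(chain_task(l = 4, m = 2, p = 0), seed = sd * 3,
                      cap = 50000)$attempts
  }, numeric(1))
  rand3 <- vapply(1:6, function(sd) {
    attempts_to_learn(chain_task(l = 4, m = 2, p = 1), seed = sd * 3,
                      cap = 50000)$attempts
  }, numeric(1))
  expect_lt(mean(rand3), mean(start3))
})

test_that("learning-time studies record replicates with their seeds", {
  st <- learning_time_study("start", 2:3, m = 2, replicates = 3, seed = 5,
                            cap = 5000)
  expect_equal(nrow(st), 6)
  expect_false(anyNA(st$seed))
  expect_s3_class(st, "learning_time_study")
  summ <- summarise_learning_times(st)
  expect_equal(nrow(summ), 2)
  expect_true(all(summ$n == 3))
  expect_s3_class(autoplot(st), "ggplot")
  expect_error(learning_time_study("start", 2, m = 2), "at least two")
})

test_that("running statistics smooth per-attempt series", {
  sim <- run_simulation(chain_task(2, 2), n_attempts = 200, seed = 1,
                        snapshot_every = 50)
  # window 1 returns the raw series
  raw <- running_statistic(sim, "reward_rate", window = 1)
  expect_equal(raw$value, as.numeric(sim$attempts$reached_reward))
  # a constant series stays constant under smoothing
  sim_const <- sim
  sim_const$attempts$reached_reward <- TRUE
  sm <- running_statistic(sim_const, "reward_rate", window = 20)
  expect_true(all(sm$value == 1))
  # highest state runs over state indices
  hs <- running_statistic(sim, "highest_state", window = 20)
  expect_true(all(hs$value >= 1 & hs$value <= 3))
  # choice probability from snapshots (softmax) and from the trace
  cp_soft <- running_statistic(sim, "choice_probability",
                               observation = "0", behaviour = "B1",
                               mode = "softmax")
  expect_equal(unique(cp_soft$mode), "softmax")
  expect_true(all(cp_soft$value >= 0 & cp_soft$value <= 1))
  cp_emp <- running_statistic(sim, "choice_probability", window = 50,
                              observation = "0", behaviour = "B1",
                              mode = "empirical")
  expect_equal(unique(cp_emp$mode), "empirical")
  # both agree on the asymptote of an easy task
  expect_lt(abs(tail(cp_soft$value, 1) - tail(cp_emp$value, 1)), 0.2)
  expect_error(running_statistic(sim, "choice_probability"), "observation")
})
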