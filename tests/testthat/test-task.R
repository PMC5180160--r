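test_that("well-formed tasks validate cleanly", {
  expect_equal(nrow(validate_task(one_step_task())), 0)
  expect_equal(nrow(validate_task(chain_task(4, 10)$task)), 0)
  expect_equal(nrow(validate_task(aliased_task())), 0)
})

test_that("violations are returned as data naming the offending parts", {
  bad <- one_step_task()
  bad$transitions$prob[1] <- 0.9
  v <- validate_task(bad)
  expect_true(any(v$check == "kernel_sums"))
  expect_match(v$message[v$check == "kernel_sums"], "B1")

  # reward unreachable from entry
  states <- tibble::tibble(state = c("a", "b", "win"),
                           u = c(-0.2, -0.2, 1),
                           terminal = c(FALSE, FALSE, TRUE))
  transitions <- tibble::tibble(state = c("a", "b"), behaviour = "go",
                                next_state = c("a", "win"), prob = 1)
  t2 <- task_spec(states, transitions, entry = "a")
  v2 <- validate_task(t2)
  expect_true(any(v2$check == "reward_reachable"))

  # aliased states must share a repertoire
  t3 <- aliased_task()
  t3$transitions$behaviour[3] <- "linger"
  v3 <- validate_task(t3)
  expect_true(any(v3$check == "alias_repertoire"))
})

test_that("entry sampling follows the structured entry-pattern family", {
  # p = 0: always the first state
  expect_equal(unique(sample_entry(chain_task(4, 2, p = 0)$task, 50)), "0")
  # p = 1, l = 4: uniform over states 0..3
  set.seed(3)
  draws <- sample_entry(chain_task(4, 2, p = 1)$task, 1e5)
  tab <- table(factor(draws, levels = as.character(0:3)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # p = 0.5, l = 4: P(state 0) = (1 - p) + p / l = 0.625
  b <- chain_task(4, 2, p = 0.5)
  expect_equal(b$task$entry$prob[b$task$entry$state == "0"], 0.625)
  set.seed(4)
  frac0 <- mean(sample_entry(b$task, 1e5) == "0")
  expect_lt(abs(frac0 - 0.625), 3 * sqrt(0.625 * 0.375 / 1e5))
})

test_that("environment steps draw from the kernel and collect u of the state entered", {
  task <- one_step_task(m = 2, b = 1, c = 0.2)
  st <- step_task(task, "0", "B1")
  expect_equal(st$next_state, "1")
  expect_equal(st$u, 1)
  expect_true(st$terminal)
  expect_error(step_task(task, "0", "B9"), "repertoire")
  expect_error(step_task(task, "zz", "B1"), "Unknown state")

  # stochastic edge frequencies (the nut-cracking strike has p = 0.75)
  sticky <- sticky_task(p = 0.75)
  set.seed(11)
  hits <- mean(vapply(1:2e4, function(i) {
    step_task(sticky, "try", "go")$next_state == "win"
  }, logical(1)))
  expect_lt(abs(hits - 0.75), 3 * sqrt(0.75 * 0.25 / 2e4))
})

test_that("observation maps implement perceptual aliasing", {
  task <- one_step_task()
  expect_equal(observe(task, "0"), "0")   # identity when no map
  al <- aliased_task()
  expect_equal(observe(al, c("d1", "d2")), c("delay", "delay"))
  al$observe <- al$observe[-2, ]          # partial map
  expect_error(observe(al, "d1"), "not covered")

  rv <- build_preset("cronin_reverse")$task
  expect_equal(observe(rv, c("blue1", "blue2")), c("blue", "blue"))
  expect_equal(observe(rv, c("yellow1", "yellow2")), c("yellow", "yellow"))
})
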