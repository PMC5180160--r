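preset_names <- c("self_control", "nut_cracking", "raccoon",
                  "generic_misbehaviour", "cronin_nondiagnostic",
                  "cronin_distinct", "cronin_reverse")

test_that("every preset passes validation with zero violations", {
  for (nm in preset_names) {
    b <- build_preset(nm)
    expect_equal(nrow(validate_task(b$task)), 0, label = nm)
    expect_s3_class(b$agent, "agent_config")
    expect_true(length(b$provenance) > 0)
  }
  expect_error(build_preset("nosuch"), "arg")
})

test_that("chain tasks have the stated structure and values", {
  b <- chain_task(l = 4, m = 10)
  expect_equal(nrow(b$task$states), 5)
  expect_equal(nrow(unique(b$task$transitions[c("state", "behaviour")])), 40)
  # degenerate single-choice case
  b1 <- chain_task(l = 1, m = 2)
  expect_equal(nrow(b1$task$states), 2)
  # printed values of the l = 2, b = 1, c = 0.2 instance
  b2 <- chain_task(l = 2, m = 2, b = 1, c = 0.2)
  expect_equal(b2$task$states$u, c(-0.2, -0.2, 1))
  expect_error(chain_task(0, 2), ">= 1")
})

test_that("the nut-cracking preset matches the printed task features", {
  b <- build_preset("nut_cracking")
  task <- b$task
  # 6 stages, 40 behaviours in every non-terminal state
  expect_equal(nrow(task$states), 6)
  nonterm <- task$states$state[!task$states$terminal]
  for (s in nonterm) {
    expect_length(unique(task$transitions$behaviour[
      task$transitions$state == s]), 40)
  }
  # entry: steal shortcut straight to the open nut with probability 0.01
  expect_equal(task$entry$prob[task$entry$state == "open_nut"], 0.01)
  # strike succeeds with probability 0.75, else the animal tries again
  strike <- task$transitions[task$transitions$state == "hammer_in_hand" &
                               task$transitions$behaviour == "strike", ]
  expect_equal(strike$prob[strike$next_state == "open_nut"], 0.75)
  expect_equal(strike$next_state[strike$prob == 0.25], "hammer_in_hand")
  # mistakes: stay with probability 0.75, else back to start
  mist <- task$transitions[task$transitions$state == "nut" &
                             task$transitions$behaviour == "strike", ]
  expect_equal(mist$prob[mist$next_state == "nut"], 0.75)
  expect_equal(mist$prob[mist$next_state == "start"], 0.25)
  # initial choice probability is exactly 2.5% per behaviour
  tabs <- value_tables(task, b$agent)
  v0 <- tabs$v[tabs$v$observation == "start", ]
  p <- action_probabilities(setNames(v0$value, v0$behaviour), 5)
  expect_equal(unname(p), rep(1 / 40, 40))
})

test_that("the raccoon preset carries the printed predispositions", {
  b <- build_preset("raccoon")
  # exactly one (observation, behaviour) pair with beta = 3
  expect_equal(nrow(b$agent$beta_map), 1)
  expect_equal(b$agent$beta_map$observation, "token")
  expect_equal(b$agent$beta_map$behaviour, "keep")
  expect_equal(b$agent$beta_map$beta, 3)
  expect_equal(b$agent$beta, 1)
  # initial v overrides of 5 on do-nothing and drop
  expect_equal(sort(b$agent$v_init$behaviour), c("do_nothing", "drop"))
  expect_true(all(b$agent$v_init$value == 5))
  expect_equal(b$agent$alpha_v, 0.25)
  expect_equal(b$task$states$u[b$task$states$state == "food"], 2)
})

test_that("cronin presets implement the delayed-cue structures", {
  rv <- build_preset("cronin_reverse")
  # four colour states collapse to two observations
  obs <- rv$task$observe
  expect_equal(sum(obs$observation == "blue"), 2)
  expect_equal(sum(obs$observation == "yellow"), 2)
  expect_equal(length(unique(obs$observation)), nrow(rv$task$states) - 2)
  # red path: yellow then blue then food; green path: blue, yellow, no food
  tr <- rv$task$transitions
  expect_equal(tr$next_state[tr$behaviour == "peck_red"], "yellow1")
  expect_equal(tr$next_state[tr$state == "blue2"], "food")
  expect_equal(tr$next_state[tr$behaviour == "peck_green"], "blue1")
  expect_equal(tr$next_state[tr$state == "yellow2"], "no_food")

  nd <- build_preset("cronin_nondiagnostic")
  expect_equal(sum(nd$task$observe$observation == "white"), 2)

  di <- build_preset("cronin_distinct")
  expect_null(di$task$observe)
  # the oracle prefers pecking red in the distinct-cue task
  pol <- optimal_values(di)$policy
  expect_equal(pol$prob[pol$behaviour == "peck_red"], 1)
})

test_that("preset overrides replace printed parameters and reject unknowns", {
  b <- build_preset("self_control", overrides = list(b2 = 10))
  expect_equal(b$task$states$u[b$task$states$state == "food_large"], 10)
  expect_error(build_preset("self_control", overrides = list(zz = 1)),
               "Unknown override")
})
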