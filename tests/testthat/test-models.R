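task2 <- bandit_task(2, 10, c(0.2, 0.8))

test_that("parameter sets are validated against the model definition", {
  expect_error(param_set("M3", alpha = 0.1), "beta")
  expect_error(param_set("M3", alpha = 0.1, beta = 5, epsilon = 0.1),
               "not in M3")
  expect_error(param_set("M3", alpha = 1.2, beta = 5), "out of bounds")
  expect_error(param_set("nope", a = 1), "unknown model")
  ps <- param_set("M5", alpha = 0.1, beta = 5, alpha_c = 0.2, beta_c = 1)
  expect_named(ps$values, c("alpha", "beta", "alpha_c", "beta_c"))
})

test_that("fresh state matches the initialization contract", {
  s <- init_state(param_set("M3", alpha = 0.1, beta = 5), task2)
  expect_equal(s$q, c(0, 0))
  expect_equal(s$ck, c(0, 0))
  expect_true(is.na(s$last_choice))

  s5 <- init_state(param_set("M3bias", alpha = 0.1, beta = 5, bias = 0.3,
                             q0 = 0.5), task2)
  expect_equal(s5$q, c(0.5, 0.5))

  stask <- stimulus_task(20)
  srl <- init_state(param_set("stateRL", alpha = 0.1, beta = 2, q0 = 0.2),
                    stask)
  expect_equal(dim(srl$q), c(3L, 3L))
  expect_true(all(srl$q == 0.2))

  expect_error(init_state(param_set("stateRL", alpha = .1, beta = 2), task2),
               "stimulus")
  expect_error(init_state(param_set("M1", b = .5),
                          bandit_task(3, 5, c(.2, .5, .8))),
               "two options")
})

test_that("choice probabilities match closed-form evaluations", {
  s <- init_state(param_set("M1", b = 0.5), task2)
  expect_equal(choice_probs(param_set("M1", b = 0.5), s), c(0.5, 0.5))
  expect_equal(choice_probs(param_set("M1", b = 0.3), s), c(0.3, 0.7))

  # WSLS: stay on a win with probability 1 - eps/2
  p2 <- param_set("M2", epsilon = 0.05)
  s2 <- init_state(p2, task2)
  expect_equal(choice_probs(p2, s2), c(0.5, 0.5)) # first trial: uniform
  s2 <- update_state(p2, s2, choice = 2L, reward = 1L)
  expect_equal(choice_probs(p2, s2), c(0.025, 0.975))
  s2 <- update_state(p2, s2, choice = 2L, reward = 0L) # lose-shift
  expect_equal(choice_probs(p2, s2), c(0.975, 0.025))

  # softmax on a value difference of 0.6 at beta = 5: logistic(3)
  p3 <- param_set("M3", alpha = 0.1, beta = 5)
  s3 <- init_state(p3, task2)
  s3$q <- c(0.2, 0.8)
  expect_equal(choice_probs(p3, s3)[2], 1 / (1 + exp(-3)), tolerance = 1e-12)

  # beta = 0: uniform regardless of values
  p0 <- param_set("M3", alpha = 0.1, beta = 0)
  expect_equal(choice_probs(p0, s3), c(0.5, 0.5))

  # side bias with equal values: p(left) = logistic(beta * B)
  pb <- param_set("M3bias", alpha = 0.1, beta = 1, bias = log(3))
  sb <- init_state(pb, task2)
  expect_equal(choice_probs(pb, sb)[1], 0.75, tolerance = 1e-12)
})

test_that("state updates follow the delta rules", {
  p3 <- param_set("M3", alpha = 0.1, beta = 5)
  s <- init_state(p3, task2)
  s <- update_state(p3, s, 1L, 1L)
  expect_equal(s$q, c(0.1, 0)) # Q <- Q + alpha (r - Q)
  expect_equal(s$ck, c(0, 0))  # untouched component

  p4 <- param_set("M4", alpha_c = 0.1, beta_c = 3)
  s4 <- init_state(p4, task2)
  s4 <- update_state(p4, s4, 1L, 0L)
  expect_equal(s4$ck, c(0.1, 0))
  # alpha_c = 1 snaps the kernel to the last choice regardless of history
  p41 <- param_set("M4", alpha_c = 1, beta_c = 3)
  s41 <- init_state(p41, task2)
  for (ch in c(2L, 2L, 1L)) s41 <- update_state(p41, s41, ch, 1L)
  expect_equal(s41$ck, c(1, 0))

  # alpha = 0 freezes values
  pz <- param_set("M3", alpha = 0, beta = 5)
  sz <- init_state(pz, task2)
  sz <- update_state(pz, sz, 1L, 1L)
  expect_equal(sz$q, c(0, 0))
})

test_that("choice probabilities normalize for every model and random state", {
  set.seed(11)
  for (i in 1:50) {
    model <- sample(c("M1", "M2", "M3", "M4", "M5", "M3bias"), 1)
    ps <- sample_parameters(model)
    s <- init_state(ps, task2)
    s$q[] <- runif(length(s$q), -1, 2)
    s$ck <- runif(2)
    if (runif(1) < 0.5) {
      s$last_choice <- sample(2L, 1)
      s$last_reward <- sample(0:1, 1)
    }
    p <- choice_probs(ps, s)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("nested models coincide when the extra component is switched off", {
  d <- simulate_agent(param_set("M3", alpha = 0.3, beta = 3),
                      bandit_task(2, 300, c(0.2, 0.8)), seed = 5)
  m3 <- param_set("M3", alpha = 0.3, beta = 3)
  m5a <- param_set("M5", alpha = 0.3, beta = 3, alpha_c = 0.7, beta_c = 0)
  expect_equal(negative_log_likelihood(m5a, d),
               negative_log_likelihood(m3, d))
  m4 <- param_set("M4", alpha_c = 0.7, beta_c = 2)
  m5b <- param_set("M5", alpha = 0.3, beta = 0, alpha_c = 0.7, beta_c = 2)
  expect_equal(negative_log_likelihood(m5b, d),
               negative_log_likelihood(m4, d))
  mb <- param_set("M3bias", alpha = 0.3, beta = 3, bias = 0)
  expect_equal(negative_log_likelihood(mb, d),
               negative_log_likelihood(m3, d))
})

test_that("softmax limits: large beta picks the argmax, alpha = 1 tracks last reward", {
  p <- param_set("M3", alpha = 0.5, beta = 30)
  s <- init_state(p, task2)
  s$q <- c(0.2, 0.8)
  expect_gt(choice_probs(p, s)[2], 0.999)

  p1 <- param_set("M3", alpha = 1, beta = 5)
  s1 <- init_state(p1, task2)
  s1 <- update_state(p1, s1, 1L, 1L)
  expect_equal(s1$q[1], 1)
  s1 <- update_state(p1, s1, 1L, 0L)
  expect_equal(s1$q[1], 0)
})

test_that("every model's implied distribution over full sequences sums to 1", {
  set.seed(21)
  cases <- list(
    param_set("M1", b = 0.37),
    param_set("M2", epsilon = 0.2),
    param_set("M3", alpha = 0.4, beta = 2.5),
    param_set("M4", alpha_c = 0.6, beta_c = 1.5),
    param_set("M5", alpha = 0.3, beta = 2, alpha_c = 0.5, beta_c = 1),
    param_set("M3bias", alpha = 0.4, beta = 2, bias = 0.4)
  )
  for (ps in cases) {
    expect_equal(sequence_probability_sum(ps, T_n = 6L), 1,
                 tolerance = 1e-9)
  }
})

test_that("simulation is reproducible and consistent with its own likelihood", {
  task <- bandit_task(2, 200, c(0.2, 0.8))
  p <- param_set("M5", alpha = 0.2, beta = 3, alpha_c = 0.3, beta_c = 1)
  d1 <- simulate_agent(p, task, seed = 9)
  d2 <- simulate_agent(p, task, seed = 9)
  expect_identical(d1$choice, d2$choice)
  expect_identical(d1$reward, d2$reward)
  # log-prob of its own sequence equals the probabilities used during simulation
  expect_equal(one_step_predictions(p, d1), attr(d1, "sim_choice_prob"),
               tolerance = 1e-12)

  # degenerate bias: all choices are option 1
  db <- simulate_agent(param_set("M1", b = 1), task, seed = 1)
  expect_true(all(db$choice == 1L))
})

test_that("first-trial choice frequencies match the fresh-state probabilities", {
  task <- bandit_task(2, 1, c(0.2, 0.8))
  p <- param_set("M1", b = 0.3)
  firsts <- vapply(1:4000, function(i) {
    simulate_agent(p, task, seed = i)$choice[1]
  }, integer(1))
  expect_lt(abs(mean(firsts == 1L) - 0.3), binom_tol(0.3, 4000))
})

test_that("per-block state reset restarts learning within each block", {
  task <- reversal_task(2, 50, list(c(0, 1), c(0, 1)))
  p <- param_set("M3", alpha = 0.5, beta = 10)
  d <- simulate_agent(p, task, seed = 3, reset_blocks = TRUE)
  lat <- extract_latents(p, d, reset_blocks = TRUE)
  expect_equal(lat$q[51, ], c(0, 0)) # fresh values at the block start
  expect_equal(lat$choice_prob[51, ], c(0.5, 0.5))
})
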