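test_that("prior draws respect their supports and moments", {
  set.seed(5)
  ps <- replicate(200, sample_parameters(
    "M3", list(alpha = prior_unif(), beta = prior_exp(10))),
    simplify = FALSE)
  alphas <- vapply(ps, function(p) p$values[["alpha"]], numeric(1))
  betas <- vapply(ps, function(p) p$values[["beta"]], numeric(1))
  expect_true(all(alphas >= 0 & alphas <= 1))
  expect_true(all(betas >= 0))

  set.seed(6)
  draws <- prior_exp(10)(1e4)
  expect_lt(abs(mean(draws) - 10), 3 * 10 / sqrt(1e4)) # SE of Exp mean = mean/sqrt(n)

  shifted <- prior_exp(1, shift = 1)(1e4)
  expect_gte(min(shifted), 1)

  expect_error(sample_parameters("M3", list(alpha = prior_unif())),
               "no prior")
})

test_that("recovery of the random responder is near-perfect", {
  report <- recover_parameters("M1", n_reps = 30,
                               task = bandit_task(2, 500, c(0.2, 0.8)),
                               options = fit_options(n_starts = 3),
                               seed = 2)
  expect_equal(report$n_failed, 0L)
  expect_gte(report$summary$pearson[report$summary$param == "b"], 0.99)
  expect_lt(abs(report$summary$bias[report$summary$param == "b"]), 0.02)
})

test_that("recovery bias of the responder bias shrinks with session length", {
  biases <- vapply(c(100L, 1000L, 10000L), function(T_n) {
    rep <- recover_parameters("M1", n_reps = 20,
                              task = bandit_task(2, T_n, c(0.2, 0.8)),
                              options = fit_options(n_starts = 2), seed = 9)
    abs(rep$summary$bias[1])
  }, numeric(1))
  expect_true(all(diff(biases) <= 0) || biases[3] < biases[1])
})

test_that("degenerate recovery inputs are handled, not fatal", {
  # constant prior -> zero variance in simulated values -> NA correlation
  report <- recover_parameters(
    "M1", priors = list(b = prior_const(0.5)), n_reps = 2,
    task = bandit_task(2, 50, c(0.2, 0.8)),
    options = fit_options(n_starts = 1), seed = 1)
  expect_true(is.na(report$summary$pearson[1]))
  expect_equal(nrow(report$replicates), 2L)
})

test_that("poor-recovery flags select exactly the large discrepancies", {
  report <- recover_parameters("M3", n_reps = 10,
                               task = bandit_task(2, 200, c(0.2, 0.8)),
                               options = fit_options(n_starts = 3), seed = 4)
  expect_identical(flag_poor_recovery(report, "alpha", Inf), integer(0))
  disc <- abs(report$replicates$sim_alpha - report$replicates$fit_alpha)
  expect_setequal(flag_poor_recovery(report, "alpha", 0),
                  report$replicates$replicate[disc > 0])
  expect_setequal(flag_poor_recovery(report, "alpha", 0.25),
                  report$replicates$replicate[disc > 0.25])
  expect_error(flag_poor_recovery(report, "gamma", 1), "unknown parameter")
})

test_that("recovery scatter round-trips through CSV losslessly", {
  report <- recover_parameters("M3", n_reps = 5,
                               task = bandit_task(2, 100, c(0.2, 0.8)),
                               options = fit_options(n_starts = 2), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_recovery_csv(report, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 10L) # 5 replicates x 2 parameters
  expect_equal(back$sim[back$param == "alpha"],
               report$replicates$sim_alpha)
  expect_equal(back$fit[back$param == "beta"],
               report$replicates$fit_beta)
})

test_that("nested recovery agrees between full and reduced fit when the nuisance is absent", {
  res <- compare_nested_recovery(
    "M3bias", "M3",
    priors = list(alpha = prior_unif(0.2, 0.8), beta = prior_exp(1, shift = 1),
                  bias = prior_const(0)),
    n_reps = 8, task = reversal_task(4, 50, list(c(0.2, 0.8), c(0.8, 0.2))),
    options = fit_options(n_starts = 4), seed = 11)
  # with B = 0 generated, both fits recover alpha comparably
  diff_r <- abs(res$summary$pearson_full - res$summary$pearson_reduced)
  expect_true(all(diff_r < 0.35))
  expect_error(compare_nested_recovery("M3", "M4"), "nest")
})

test_that("group-difference power analysis is calibrated at zero effect", {
  # two groups simulated with identical alpha distributions: the nominal
  # 5% test should reject at about its nominal level
  task <- bandit_task(2, 300, c(0.2, 0.8))
  pvals <- vapply(1:20, function(i) {
    r1 <- recover_parameters("M3",
      priors = list(alpha = prior_unif(0.3, 0.7), beta = prior_const(5)),
      n_reps = 8, task = task, options = fit_options(n_starts = 3),
      seed = 100 + i)
    r2 <- recover_parameters("M3",
      priors = list(alpha = prior_unif(0.3, 0.7), beta = prior_const(5)),
      n_reps = 8, task = task, options = fit_options(n_starts = 3),
      seed = 500 + i)
    t.test(r1$replicates$fit_alpha, r2$replicates$fit_alpha)$p.value
  }, numeric(1))
  # detection rate at Delta = 0 within binomial error of the nominal level
  expect_lte(mean(pvals < 0.05), 0.05 + binom_tol(0.05, 20))
})
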