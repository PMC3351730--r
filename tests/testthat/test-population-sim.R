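test_that("population sampling is seeded, validated and concentrated", {
  m <- scc_fixture("basic")
  expect_error(sample_population(m, 0, seed = 1), "positive")

  m1 <- m
  m1$components$prevalence <- c(U = 0.3, W = 0, X = 1)[m1$components$component]
  pop <- sample_population(m1, 10, seed = 1)
  expect_true(all(pop$X))
  expect_false(any(pop$W))

  # identical call, identical population
  p1 <- sample_population(m, 5000, seed = 42)
  p2 <- sample_population(m, 5000, seed = 42)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))

  # binomial concentration around the closed form P(U, no X) = 0.3 * 0.8
  m2 <- m
  m2$components$prevalence <- c(U = 0.3, W = 0, X = 0.2)[m2$components$component]
  big <- sample_population(m2, 100000, seed = 9)
  phat <- mean(big$U & !big$X)
  expect_lt(abs(phat - 0.24), 4 * sqrt(0.24 * 0.76 / 100000))
})

test_that("populations can be drawn from an explicit joint distribution", {
  m <- scc_fixture("basic")
  m$joint <- tibble::tibble(
    U = c(TRUE, FALSE), W = c(FALSE, FALSE), X = c(FALSE, TRUE),
    prob = c(0.7, 0.3))
  pop <- sample_population(m, 20000, seed = 2)
  expect_true(all(pop$U != pop$X))  # only the two listed profiles occur
  expect_lt(abs(mean(pop$U) - 0.7), 4 * sqrt(0.7 * 0.3 / 20000))
})

test_that("trials are deterministic given the spec and recover the analytic RD", {
  m <- apply_monotonicity(scc_fixture("basic"))
  m$components$prevalence <- c(U = 0.3, W = 0, X = 0.2)[m$components$component]
  pop <- sample_population(m, 100000, seed = 17)
  tr <- run_trial(m, pop, trial_spec(seed = 17))
  tr2 <- run_trial(m, pop, trial_spec(seed = 17))
  expect_identical(tr$data, tr2$data)
  expect_identical(tr$estimated_rd, tr2$estimated_rd)

  expect_equal(tr$true_rd, 0.24, tolerance = 1e-12)
  se <- sqrt(sum(tr$arms$risk * (1 - tr$arms$risk) / tr$arms$n))
  expect_lt(abs(tr$estimated_rd - 0.24), 4 * se)
})

test_that("version handling is strict and degenerate mixtures collapse", {
  basic <- scc_fixture("basic")
  pop <- sample_population(basic, 100, seed = 1)
  expect_error(
    run_trial(basic, pop, trial_spec(seed = 1, versions = c(exposed = 1))),
    "no versions")

  v <- apply_monotonicity(scc_fixture("versions"))
  popv <- sample_population(v, 20000, seed = 8)
  expect_error(run_trial(v, popv, trial_spec(seed = 8)), "version distribution")
  expect_error(run_trial(v, popv, trial_spec(seed = 8, versions = c(uphill = 1))),
               "undeclared")

  tr <- run_trial(v, popv, trial_spec(seed = 8, versions = c(flat = 1, hilly = 0)))
  ty <- enumerate_response_types(v)
  rd_flat <- average_causal_rd(ty, "flat", "none")
  expect_equal(tr$true_rd, rd_flat, tolerance = 1e-12)
  se <- sqrt(sum(tr$arms$risk * (1 - tr$arms$risk) / tr$arms$n))
  expect_lt(abs(tr$estimated_rd - rd_flat), 4 * se)
  expect_true(all(tr$data$level[tr$data$arm == "exposed"] == "flat"))
})

test_that("interference contexts are global and can follow a threshold rule", {
  i3 <- apply_monotonicity(scc_fixture("interference"))
  pop <- sample_population(i3, 30000, seed = 21)
  tr_ou <- run_trial(i3, pop, trial_spec(seed = 21, context = c(I = "others_unexposed")))
  tr_oe <- run_trial(i3, pop, trial_spec(seed = 21, context = c(I = "others_exposed")))
  ty <- enumerate_response_types(i3)
  expect_equal(tr_ou$true_rd,
               average_causal_rd(ty, "exposed.others_unexposed",
                                 "unexposed.others_unexposed"), tolerance = 1e-12)
  expect_equal(tr_oe$true_rd,
               average_causal_rd(ty, "exposed.others_exposed",
                                 "unexposed.others_exposed"), tolerance = 1e-12)
  # unstable mass is positive here, so the two context estimands differ
  expect_gt(abs(tr_oe$true_rd - tr_ou$true_rd), 0.01)
  for (tr in list(tr_ou, tr_oe)) {
    se <- sqrt(sum(tr$arms$risk * (1 - tr$arms$risk) / tr$arms$n))
    expect_lt(abs(tr$estimated_rd - tr$true_rd), 4 * se)
  }

  # threshold rule: half the population assigned to exposure trips the context
  tr_thr <- run_trial(i3, pop, trial_spec(
    seed = 21, p_exposed = 0.6,
    context = list(variable = "I", threshold = 0.5)))
  expect_identical(unname(tr_thr$context["I"]), "others_exposed")
  tr_thr2 <- run_trial(i3, pop, trial_spec(
    seed = 21, p_exposed = 0.1,
    context = list(variable = "I", threshold = 0.5)))
  expect_identical(unname(tr_thr2$context["I"]), "others_unexposed")
})

test_that("a model whose causes ignore the exposure yields a null effect", {
  null_model <- scc_model(
    "null", list(exposure_variable("E", c("exposed", "unexposed"))),
    c(X = 0.3), list(sufficient_cause(components = "X")))
  pop <- sample_population(null_model, 50000, seed = 3)
  tr <- run_trial(null_model, pop, trial_spec(seed = 3))
  expect_identical(tr$true_rd, 0)
  se <- sqrt(sum(tr$arms$risk * (1 - tr$arms$risk) / tr$arms$n))
  expect_lt(abs(tr$estimated_rd), 4 * se)
})

test_that("the exchangeability diagnostic is a total-variation distance", {
  fake <- function(arm, type) {
    structure(list(data = tibble::tibble(arm = arm, type = type)),
              class = "scc_trial")
  }
  # identical arm compositions
  expect_equal(exchangeability_diagnostic(
    fake(rep(c("exposed", "unexposed"), each = 4), rep(c("a", "b"), 4))), 0)
  # disjoint type supports
  expect_equal(exchangeability_diagnostic(
    fake(rep(c("exposed", "unexposed"), each = 2), c("a", "a", "b", "b"))), 1)
  expect_error(exchangeability_diagnostic(fake(rep("exposed", 3), c("a", "b", "a"))),
               "both arms")

  m <- apply_monotonicity(scc_fixture("basic"))
  pop <- sample_population(m, 100000, seed = 4)
  tr <- run_trial(m, pop, trial_spec(seed = 4))
  expect_lt(exchangeability_diagnostic(tr), 0.02)
})

test_that("one-replicate bias experiments equal a single trial", {
  v <- apply_monotonicity(scc_fixture("versions"))
  be <- sutva_bias_experiment(v, list(c(flat = 0.5, hilly = 0.5)),
                              n = 5000, replicates = 1, seed = 6)
  expect_identical(nrow(be), 1L)
  s <- sccsutva:::sub_seed(6, 1L * 131071L + 1L)
  pop <- sample_population(v, 5000, seed = s)
  tr <- run_trial(v, pop, trial_spec(seed = s, versions = c(flat = 0.5, hilly = 0.5)))
  expect_equal(be$mean_estimated_rd, tr$estimated_rd, tolerance = 1e-12)
  expect_equal(be$analytic_rd,
               overall_rd(mixture_effect(v, c(flat = 0.5, hilly = 0.5), "ride")),
               tolerance = 1e-12)
  expect_error(sutva_bias_experiment(v, list(), n = 10, replicates = 1, seed = 1),
               "nonempty")
  expect_error(sutva_bias_experiment(v, list(c(flat = 1)), n = 10, replicates = 0,
                                     seed = 1), "replicates")
})
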