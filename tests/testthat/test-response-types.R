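test_that("a single binary exposure implies four response types", {
  ty <- enumerate_response_types(scc_fixture("basic"))
  expect_identical(nrow(ty), 4L)
  expect_identical(ty$type, c("11", "10", "01", "00"))
  expect_equal(sum(ty$probability), 1, tolerance = 1e-12)
  # independent-prevalence closed forms, U=0.3, W=0.1, X=0.2
  expect_equal(ty$probability, c(
    0.2 + 0.3 * 0.1 * 0.8,  # doomed: X, or U and W without X
    0.3 * 0.9 * 0.8,        # causal: U alone among {U,W,X}-relevant splits
    0.1 * 0.7 * 0.8,        # preventive
    0.7 * 0.9 * 0.8),       # immune
    tolerance = 1e-12)
})

test_that("a model with no causes has a single immune type of mass 1", {
  m <- scc_model("null", list(exposure_variable("E", c("exposed", "unexposed"))),
                 c(U = 0.4), list(sufficient_cause(c(E = "exposed"), "U")))
  m$causes <- list()
  ty <- enumerate_response_types(m, scc_conditions(m))
  expect_identical(nrow(ty), 1L)
  expect_identical(ty$type, "00")
  expect_equal(ty$probability, 1, tolerance = 1e-12)
})

test_that("oversized component sets are refused with advice", {
  m <- scc_model("big", list(exposure_variable("E", c("exposed", "unexposed"))),
                 stats::setNames(rep(0.1, 21), paste0("C", 1:21)),
                 list(sufficient_cause(c(E = "exposed"), "C1")))
  expect_error(enumerate_response_types(m), "Monte Carlo")
})

test_that("joint profile distributions override independent prevalences", {
  m <- scc_fixture("basic")
  m$joint <- tibble::tibble(
    U = c(TRUE, FALSE), W = c(FALSE, FALSE), X = c(FALSE, TRUE),
    prob = c(0.6, 0.4))
  expect_length(validate_model(m), 0)
  ty <- enumerate_response_types(m)
  expect_equal(risk_under(ty, "exposed"), 1, tolerance = 1e-12) # U or X always
  expect_equal(risk_under(ty, "unexposed"), 0.4, tolerance = 1e-12)
  expect_types_match_oracle(m, scc_conditions(m))
})

test_that("binary classification maps the four outcome pairs exhaustively", {
  ty <- classify_binary(enumerate_response_types(scc_fixture("basic")),
                        "exposed", "unexposed")
  expect_identical(as.character(ty$label),
                   c("doomed", "causal", "preventive", "immune"))
  expect_false(any(is.na(ty$label)))
  expect_error(classify_binary(ty, "exposed", "nope"), "not present")
})

test_that("monotonicity zeroes preventive partners distributionally", {
  m <- scc_fixture("basic")
  mm <- apply_monotonicity(m, "E")
  expect_equal(mm$components$prevalence[mm$components$component == "W"], 0)
  # untouched input, unchanged structure
  expect_gt(m$components$prevalence[m$components$component == "W"], 0)
  expect_identical(mm$causes, m$causes)

  ty <- enumerate_response_types(mm)
  expect_identical(ty$type, enumerate_response_types(m)$type)
  expect_equal(ty$probability[ty$type == "01"], 0)

  # idempotent
  expect_identical(apply_monotonicity(mm, "E"), mm)

  # nothing to zero when no cause carries a reference-level literal
  no_ref <- scc_model("nr", list(exposure_variable("E", c("exposed", "unexposed"))),
                      c(U = 0.3, X = 0.1),
                      list(sufficient_cause(c(E = "exposed"), "U"),
                           sufficient_cause(components = "X")))
  expect_identical(apply_monotonicity(no_ref, "E"), no_ref)
  expect_error(apply_monotonicity(m, "Q"), "unknown exposure")
})

test_that("monotonicity over both own and others' exposure leaves only white rows", {
  i3 <- apply_monotonicity(scc_fixture("interference"), c("E", "I"))
  prev <- stats::setNames(i3$components$prevalence, i3$components$component)
  expect_equal(unname(prev[c("W1", "W2")]), c(0, 0))
  expect_true(all(prev[c("U1", "U2", "U3", "X")] > 0))

  ty <- enumerate_response_types(i3)
  pos <- ty[ty$probability > 0, ]
  expect_setequal(pos$type,
                  c("1111", "1010", "1011", "0010", "0011", "0000"))
})

test_that("stability splits potential-outcome stability from effect stability", {
  i3 <- apply_monotonicity(scc_fixture("interference"))
  ty <- enumerate_response_types(i3)
  groups <- list(
    others_unexposed = c("exposed.others_unexposed", "unexposed.others_unexposed"),
    others_exposed = c("exposed.others_exposed", "unexposed.others_exposed"))
  rep <- stability_report(ty, groups)

  expect_identical(rep$unstable_type_count, 3L)
  unstable <- rep$types$type[!rep$types$stable_potential_outcomes &
                               rep$types$probability > 0]
  expect_setequal(unstable, c("1011", "0010", "0011"))

  # unstable potential outcomes but a stable (null) causal effect
  row <- rep$types[rep$types$type == "0011", ]
  expect_false(row$stable_potential_outcomes)
  expect_true(row$stable_causal_effect)

  # implication holds on every row
  expect_true(all(rep$types$stable_causal_effect[rep$types$stable_potential_outcomes]))

  # a single contrast group can never be unstable
  b <- enumerate_response_types(scc_fixture("basic"))
  rep1 <- stability_report(b, list(main = c("exposed", "unexposed")))
  expect_true(all(rep1$types$stable_potential_outcomes))
  expect_identical(rep1$unstable_type_count, 0L)

  expect_error(stability_report(ty, list(bad = "exposed.others_exposed")),
               "exactly one")
  expect_error(stability_report(ty, list()), "nonempty")
})

test_that("unstable mass matches the closed form for the versions model", {
  v <- apply_monotonicity(scc_fixture("versions"))
  v$components$prevalence <- c(U1 = 0.5, U2 = 0.5, W = 0, X = 0.2)[
    v$components$component]
  groups <- list(flat = c("flat", "none"), hilly = c("hilly", "none"))
  # P(no X) * P(exactly one of U1, U2)
  expect_equal(unstable_profile_mass(v, groups), 0.8 * 0.5, tolerance = 1e-12)

  # the unstable profile set is exactly {no X, exactly one of U1/U2}
  profs <- unstable_profiles(v, groups)
  expected <- list(c("U1"), c("U2"), c("U1", "W"), c("U2", "W"))
  expect_identical(length(profs), length(expected))
  for (e in expected) {
    expect_true(any(vapply(profs, function(p) setequal(p, e), logical(1))))
  }

  # degenerate prevalences leave only the empty immune profile
  v0 <- v
  v0$components$prevalence[] <- 0
  expect_equal(unstable_profile_mass(v0, groups), 0)

  # no SUTVA violation: zero unstable mass under any prevalences
  set.seed(5)
  for (r in 1:10) {
    b <- scc_fixture("basic")
    b$components$prevalence <- runif(3)
    expect_equal(unstable_profile_mass(b, list(main = c("exposed", "unexposed"))), 0)
  }
})

test_that("type probabilities always sum to one", {
  set.seed(31)
  for (r in 1:25) {
    m <- random_model()
    ty <- enumerate_response_types(m, scc_conditions(m))
    expect_equal(sum(ty$probability), 1, tolerance = 1e-12)
    expect_true(all(ty$probability >= 0))
  }
})
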