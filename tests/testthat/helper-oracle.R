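# Independent brute-force oracle: evaluates each cause literally against an
# explicit profile subset, and enumerates response types by looping over an
# expand.grid of all component subsets. No bit masks, no grouping tricks —
# deliberately naive so it cannot share a bug with the package internals.

oracle_outcome <- function(model, profile, assignment) {
  for (ca in model$causes) {
    lits_ok <- TRUE
    for (v in names(ca$literals)) {
      if (!identical(unname(assignment[v]), unname(ca$literals[v]))) lits_ok <- FALSE
    }
    comps_ok <- TRUE
    for (cp in ca$components) if (!cp %in% profile) comps_ok <- FALSE
    if (lits_ok && comps_ok) return(1L)
  }
  0L
}

oracle_enumerate <- function(model, conditions) {
  comps <- model$components$component
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(comps)))
  if (length(comps)) names(grid) <- comps
  res <- list()
  for (i in seq_len(max(nrow(grid), 1))) {
    profile <- if (length(comps)) comps[unlist(grid[i, ])] else character()
    vec <- vapply(conditions, function(a) oracle_outcome(model, profile, a),
                  integer(1))
    key <- paste(vec, collapse = "")
    if (is.null(model$joint)) {
      p <- 1
      for (j in seq_along(comps)) {
        pj <- model$components$prevalence[j]
        p <- p * if (comps[j] %in% profile) pj else 1 - pj
      }
    } else {
      p <- 0
      for (r in seq_len(nrow(model$joint))) {
        row_prof <- comps[as.logical(model$joint[r, comps, drop = TRUE])]
        if (setequal(row_prof, profile)) p <- p + model$joint$prob[r]
      }
    }
    if (is.null(res[[key]])) res[[key]] <- list(prob = 0, profiles = list())
    res[[key]]$prob <- res[[key]]$prob + p
    res[[key]]$profiles <- c(res[[key]]$profiles, list(profile))
  }
  res
}

expect_types_match_oracle <- function(model, conditions) {
  ty <- enumerate_response_types(model, conditions)
  orc <- oracle_enumerate(model, conditions)
  expect_setequal(ty$type, names(orc))
  for (k in ty$type) {
    expect_equal(ty$probability[ty$type == k], orc[[k]]$prob, tolerance = 1e-12)
    got <- ty$profiles[ty$type == k][[1]]
    want <- orc[[k]]$profiles
    expect_equal(length(got), length(want))
    for (pr in want) {
      expect_true(any(vapply(got, function(g) setequal(g, pr), logical(1))))
    }
  }
}

# Random small valid model for property-style tests.
random_model <- function() {
  n_exp <- sample(1:2, 1)
  exposures <- lapply(seq_len(n_exp), function(i) {
    nl <- sample(2:3, 1)
    exposure_variable(paste0("V", i), paste0("v", i, "_", seq_len(nl)))
  })
  k <- sample(1:5, 1)
  comps <- stats::setNames(round(runif(k), 3), paste0("C", seq_len(k)))
  causes <- lapply(seq_len(sample(1:5, 1)), function(j) {
    lits <- character()
    for (e in exposures) {
      if (runif(1) < 0.6) lits[e$name] <- sample(e$levels, 1)
    }
    nc <- sample(0:min(3, k), 1)
    cc <- if (nc > 0) sample(names(comps), nc) else character()
    if (length(lits) == 0L && length(cc) == 0L) cc <- sample(names(comps), 1)
    sufficient_cause(lits, cc)
  })
  scc_model("random", exposures, comps, causes)
}

random_assignment <- function(model) {
  vapply(model$exposures, function(e) sample(e$levels, 1), character(1))
}

all_fixture_models <- function() {
  mods <- lapply(scc_fixtures(), scc_fixture)
  c(mods, lapply(mods, apply_monotonicity))
}
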