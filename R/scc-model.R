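#' Declare an exposure variable
#'
#' An exposure variable is a manipulable condition with at least two levels,
#' one of which is the reference ("unexposed") level. A binary exposure has
#' levels such as `exposed`/`unexposed`; an exposure with unrepresented
#' versions of treatment carries one level per version plus the reference
#' (e.g. `flat`, `hilly`, `none`).
#'
#' @param name Identifier for the variable (e.g. `"E"`).
#' @param levels Character vector of at least two distinct level identifiers.
#' @param reference The reference (unexposed) level; defaults to the last
#'   element of `levels`.
#' @return An object of class `scc_exposure`.
#' @examples
#' exposure_variable("E", c("exposed", "unexposed"))
#' exposure_variable("ride", c("flat", "hilly", "none"), reference = "none")
#' @export
exposure_variable <- function(name, levels, reference = levels[length(levels)]) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    rlang::abort(sprintf("exposure variable '%s' needs at least 2 levels", name))
  }
  if (anyDuplicated(levels)) {
    rlang::abort(sprintf("exposure variable '%s' has duplicated levels", name))
  }
  if (!reference %in% levels) {
    rlang::abort(sprintf("reference level '%s' is not a level of '%s'", reference, name))
  }
  structure(list(name = name, levels = levels, reference = reference),
            class = "scc_exposure")
}

#' Declare a sufficient cause ("causal pie")
#'
#' A sufficient cause is a minimal set of conditions that jointly complete a
#' mechanism for the outcome: zero or more exposure literals (a variable held
#' at one level) together with zero or more background component causes
#' ("causal partners"). A cause with no exposure literals fires from its
#' components alone, whatever the exposure assignment.
#'
#' @param literals Named character vector mapping exposure-variable names to
#'   the level each must take, e.g. `c(E = "exposed")`. May be empty.
#' @param components Character vector of background component names that must
#'   be present, e.g. `c("U")`. May be empty if `literals` is not.
#' @return An object of class `scc_cause`.
#' @examples
#' sufficient_cause(c(E = "exposed"), "U")
#' sufficient_cause(components = "X") # fires regardless of exposure
#' @export
sufficient_cause <- function(literals = character(), components = character()) {
  literals <- vapply(literals, as.character, character(1))
  components <- as.character(components)
  structure(list(literals = literals, components = components),
            class = "scc_cause")
}

#' Build a sufficient component cause model
#'
#' Collects exposure variables, background component causes (with their
#' population prevalences) and sufficient causes into a single model object.
#' By default component causes are distributed independently across
#' individuals with the stated prevalences; `joint` supplies an explicit
#' joint distribution over component profiles instead.
#'
#' @param name Model name.
#' @param exposures List of [exposure_variable()] objects.
#' @param components Named numeric vector of prevalences in `[0, 1]`, one per
#'   background component (e.g. `c(U = 0.3, X = 0.2)`).
#' @param causes List of [sufficient_cause()] objects.
#' @param joint Optional tibble with one logical column per component plus a
#'   `prob` column summing to 1; overrides the independent prevalences.
#' @return An object of class `scc_model`.
#' @examples
#' m <- scc_model(
#'   "toy",
#'   exposures  = list(exposure_variable("E", c("exposed", "unexposed"))),
#'   components = c(U = 0.3, X = 0.2),
#'   causes     = list(
#'     sufficient_cause(c(E = "exposed"), "U"),
#'     sufficient_cause(components = "X")
#'   )
#' )
#' evaluate_outcome(m, "U", c(E = "exposed"))
#' @export
scc_model <- function(name, exposures, components, causes, joint = NULL) {
  if (inherits(exposures, "scc_exposure")) exposures <- list(exposures)
  if (inherits(causes, "scc_cause")) causes <- list(causes)
  stopifnot(is.list(exposures), is.list(causes))
  comp_tbl <- tibble::tibble(
    component  = names(components) %||% character(),
    prevalence = as.numeric(components)
  )
  names(exposures) <- vapply(exposures, function(e) e$name, character(1))
  model <- structure(
    list(name = as.character(name), exposures = exposures,
         components = comp_tbl, causes = causes, joint = joint),
    class = "scc_model"
  )
  model
}

#' Validate a sufficient component cause model
#'
#' Checks every structural invariant and returns a description of each
#' breach: undeclared components or exposure variables in causes, levels not
#' belonging to their variable, contradictory causes (two literals for the
#' same variable), empty causes, prevalences outside `[0, 1]`, and a joint
#' profile distribution that does not sum to 1.
#'
#' @param model An [scc_model()].
#' @return Character vector of violation messages; empty when the model is
#'   valid.
#' @examples
#' validate_model(scc_fixture("basic"))
#' @export
validate_model <- function(model) {
  if (!inherits(model, "scc_model")) {
    return("not an scc_model object")
  }
  v <- character()
  exp_names <- names(model$exposures)
  if (anyDuplicated(exp_names)) {
    v <- c(v, "duplicated exposure variable names")
  }
  for (e in model$exposures) {
    if (length(e$levels) < 2L) {
      v <- c(v, sprintf("exposure '%s' has fewer than 2 levels", e$name))
    }
  }
  comp <- model$components
  if (anyDuplicated(comp$component)) {
    v <- c(v, "duplicated component names")
  }
  bad_prev <- comp$component[is.na(comp$prevalence) |
                               comp$prevalence < 0 | comp$prevalence > 1]
  for (b in bad_prev) {
    v <- c(v, sprintf("component '%s' has prevalence outside [0, 1]", b))
  }
  for (i in seq_along(model$causes)) {
    ca <- model$causes[[i]]
    lit <- ca$literals
    if (length(lit) == 0L && length(ca$components) == 0L) {
      v <- c(v, sprintf("cause %d is empty", i))
    }
    if (anyDuplicated(names(lit))) {
      v <- c(v, sprintf("cause %d has contradictory literals (two levels for one variable)", i))
    }
    for (var in names(lit)) {
      if (!var %in% exp_names) {
        v <- c(v, sprintf("cause %d references undeclared exposure variable '%s'", i, var))
      } else if (!lit[[var]] %in% model$exposures[[var]]$levels) {
        v <- c(v, sprintf("cause %d uses level '%s' not declared for '%s'",
                          i, lit[[var]], var))
      }
    }
    undecl <- setdiff(ca$components, comp$component)
    for (u in undecl) {
      v <- c(v, sprintf("cause %d references undeclared component '%s'", i, u))
    }
  }
  if (!is.null(model$joint)) {
    j <- model$joint
    if (!"prob" %in% names(j)) {
      v <- c(v, "joint profile distribution lacks a 'prob' column")
    } else {
      if (abs(sum(j$prob) - 1) > 1e-12) {
        v <- c(v, "joint profile probabilities do not sum to 1")
      }
      if (any(j$prob < 0)) v <- c(v, "joint profile probabilities are negative")
      extra <- setdiff(setdiff(names(j), "prob"), comp$component)
      if (length(extra)) {
        v <- c(v, sprintf("joint table has undeclared component columns: %s",
                          paste(extra, collapse = ", ")))
      }
    }
  }
  v
}

assert_valid_model <- function(model) {
  v <- validate_model(model)
  if (length(v)) {
    rlang::abort(c("invalid SCC model:", stats::setNames(v, rep("x", length(v)))))
  }
  invisible(model)
}

as_assignment <- function(model, assignment) {
  assignment <- unlist(assignment)
  exp_names <- names(model$exposures)
  missing <- setdiff(exp_names, names(assignment))
  if (length(missing)) {
    rlang::abort(sprintf("assignment misses exposure variable(s): %s",
                         paste(missing, collapse = ", ")))
  }
  for (var in exp_names) {
    lev <- assignment[[var]]
    if (!lev %in% model$exposures[[var]]$levels) {
      rlang::abort(sprintf("'%s' is not a level of exposure variable '%s'", lev, var))
    }
  }
  assignment[exp_names]
}

as_profile <- function(model, profile) {
  profile <- as.character(unlist(profile))
  extra <- setdiff(profile, model$components$component)
  if (length(extra)) {
    rlang::abort(sprintf("profile contains undeclared component(s): %s",
                         paste(extra, collapse = ", ")))
  }
  unique(profile)
}

cause_matches_assignment <- function(cause, assignment) {
  lits <- cause$literals
  if (length(lits) == 0L) return(TRUE)
  all(vapply(names(lits), function(v) identical(assignment[[v]], lits[[v]]),
             logical(1)))
}

#' Evaluate the end-of-study outcome for one individual
#'
#' The binary outcome is 1 if and only if at least one sufficient cause is
#' completed: all of its component causes are in the individual's profile and
#' every exposure literal matches the assignment. Evaluation is timeless —
#' only end-of-study presence of components matters, so an individual who
#' carries a cause that fires without the exposure is "doomed" regardless of
#' which mechanism would have acted first (the end-of-study, excess-effect
#' convention: priority to the doomed).
#'
#' @param model A valid [scc_model()].
#' @param profile Character vector of component names the individual carries
#'   by end of study (possibly empty).
#' @param assignment Named character vector assigning every exposure variable
#'   exactly one of its levels, e.g. `c(E = "exposed")`.
#' @return Integer 0 or 1.
#' @examples
#' m <- scc_fixture("basic")
#' evaluate_outcome(m, "X", c(E = "unexposed"))  # background mechanism: 1
#' evaluate_outcome(m, "U", c(E = "unexposed"))  # causal partner idle: 0
#' @export
evaluate_outcome <- function(model, profile, assignment) {
  assert_valid_model(model)
  profile <- as_profile(model, profile)
  assignment <- as_assignment(model, assignment)
  for (ca in model$causes) {
    if (cause_matches_assignment(ca, assignment) &&
        all(ca$components %in% profile)) {
      return(1L)
    }
  }
  0L
}

#' Potential outcomes of one individual across exposure conditions
#'
#' Applies [evaluate_outcome()] under each condition in turn; the resulting
#' vector is the individual's response type over that condition set.
#'
#' @param model A valid [scc_model()].
#' @param profile Character vector of component names present.
#' @param conditions Named list of assignments (see [scc_conditions()]).
#' @return Named integer vector of 0/1 outcomes, one per condition, in the
#'   given order.
#' @examples
#' m <- scc_fixture("basic")
#' potential_outcomes(m, "U", scc_conditions(m))  # the "causal" type: (1, 0)
#' @export
potential_outcomes <- function(model, profile, conditions) {
  stopifnot(is.list(conditions), length(conditions) > 0L)
  out <- vapply(conditions, function(a) evaluate_outcome(model, profile, a),
                integer(1))
  if (is.null(names(conditions))) {
    names(out) <- vapply(conditions, function(a) paste(a, collapse = "."),
                         character(1))
  }
  out
}

#' Canonical exposure conditions of a model
#'
#' Builds the named list of all exposure assignments obtained by crossing the
#' levels of the chosen variables: the first variable varies fastest, so for
#' an own-exposure crossed with an interference context the table reads
#' exposed-then-unexposed within each context, contexts in declaration order.
#' Condition names join the level identifiers with `"."`.
#'
#' @param model A valid [scc_model()].
#' @param variables Character vector of exposure-variable names; defaults to
#'   all declared variables in declaration order.
#' @return Named list of assignments (named character vectors).
#' @examples
#' scc_conditions(scc_fixture("interference"))
#' @export
scc_conditions <- function(model, variables = NULL) {
  assert_valid_model(model)
  variables <- variables %||% names(model$exposures)
  bad <- setdiff(variables, names(model$exposures))
  if (length(bad)) {
    rlang::abort(sprintf("unknown exposure variable(s): %s", paste(bad, collapse = ", ")))
  }
  levs <- lapply(model$exposures[variables], function(e) e$levels)
  grid <- expand.grid(levs, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fixed <- setdiff(names(model$exposures), variables)
  conds <- lapply(seq_len(nrow(grid)), function(i) {
    a <- stats::setNames(as.character(grid[i, , drop = TRUE]), variables)
    for (f in fixed) a[[f]] <- model$exposures[[f]]$reference
    a[names(model$exposures)]
  })
  names(conds) <- apply(grid, 1L, paste, collapse = ".")
  conds
}

exposed_level <- function(exposure) {
  setdiff(exposure$levels, exposure$reference)[1]
}

#' @export
print.scc_model <- function(x, ...) {
  cat(sprintf("<scc_model: %s>\n", x$name))
  for (e in x$exposures) {
    cat(sprintf("  exposure %s: %s (reference: %s)\n", e$name,
                paste(e$levels, collapse = ", "), e$reference))
  }
  cat(sprintf("  components: %s\n",
              paste(sprintf("%s=%.3g", x$components$component,
                            x$components$prevalence), collapse = ", ")))
  for (i in seq_along(x$causes)) {
    ca <- x$causes[[i]]
    parts <- c(sprintf("%s=%s", names(ca$literals), ca$literals), ca$components)
    cat(sprintf("  cause %d: {%s}\n", i, paste(parts, collapse = ", ")))
  }
  if (!is.null(x$joint)) cat("  joint profile distribution: explicit table\n")
  invisible(x)
}
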