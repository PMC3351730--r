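# One root seed drives every stage through deterministic sub-seeds, so the
# population, the arm assignment and the version draws are independently
# reproducible. Sub-seeds stay below 2^31 - 1.
sub_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stage) * 104729
  as.integer(s %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a synthetic population of component profiles
#'
#' Draws `n` individuals whose background component causes are independent
#' Bernoulli variables with the model's prevalences (or rows of the explicit
#' joint profile distribution when the model carries one). The same
#' `(model, n, seed)` always yields the identical population.
#'
#' @param model A valid [scc_model()].
#' @param n Positive number of individuals.
#' @param seed Integer seed.
#' @return A tibble of class `scc_population`, one logical column per
#'   component, one row per individual.
#' @examples
#' sample_population(scc_fixture("basic"), 5, seed = 1)
#' @export
sample_population <- function(model, n, seed) {
  assert_valid_model(model)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    rlang::abort("n must be a positive integer")
  }
  n <- as.integer(n)
  comps <- model$components$component
  pop <- with_seed(sub_seed(seed, 1L), {
    if (is.null(model$joint)) {
      cols <- lapply(seq_along(comps), function(j) {
        stats::runif(n) < model$components$prevalence[j]
      })
      tibble::as_tibble(stats::setNames(cols, comps))
    } else {
      rows <- sample.int(nrow(model$joint), n, replace = TRUE,
                         prob = model$joint$prob)
      tibble::as_tibble(lapply(stats::setNames(comps, comps), function(cp) {
        as.logical(model$joint[[cp]])[rows]
      }))
    }
  })
  attr(pop, "model_name") <- model$name
  attr(pop, "seed") <- as.integer(seed)
  class(pop) <- c("scc_population", class(pop))
  pop
}

# vectorized outcome evaluation over a logical profile matrix
population_outcomes <- function(model, mat, assignment) {
  n <- nrow(mat)
  out <- rep(FALSE, n)
  for (ca in model$causes) {
    if (!cause_matches_assignment(ca, assignment)) next
    req <- ca$components
    if (length(req) == 0L) return(rep(1L, n))
    out <- out | (rowSums(mat[, req, drop = FALSE]) == length(req))
  }
  as.integer(out)
}

#' Specify an idealized randomized trial
#'
#' Describes a single two-arm trial on a synthetic population: every
#' individual complies fully with their assigned condition and nobody is
#' lost to follow-up, so the arms differ only in the exposure (and in
#' whatever SUTVA violation the model encodes).
#'
#' @param seed Integer seed; required, drives assignment and version draws.
#' @param p_exposed Probability of assignment to the exposed arm.
#' @param exposure Name of the randomized exposure variable; defaults to the
#'   model's first declared variable.
#' @param versions Optional named weights over the exposure's non-reference
#'   levels: each exposed individual receives one version of treatment drawn
#'   from this distribution. Required when the exposure has more than two
#'   levels; an error for a binary exposure.
#' @param context Interference context rule for the remaining exposure
#'   variables. Either a named character vector fixing levels (e.g.
#'   `c(I = "others_exposed")`), or a list `list(variable =, threshold =)`
#'   setting that variable to its exposed level exactly when the realized
#'   share assigned to exposure reaches the threshold. Variables left
#'   unspecified sit at their reference level.
#' @return An object of class `scc_trial_spec`.
#' @export
trial_spec <- function(seed, p_exposed = 0.5, exposure = NULL,
                       versions = NULL, context = NULL) {
  if (missing(seed) || is.null(seed)) {
    rlang::abort("trial_spec requires an explicit seed")
  }
  if (!is.numeric(p_exposed) || p_exposed < 0 || p_exposed > 1) {
    rlang::abort("p_exposed must lie in [0, 1]")
  }
  if (!is.null(versions)) {
    if (is.null(names(versions)) ||
        any(versions < 0) || abs(sum(versions) - 1) > 1e-9) {
      rlang::abort("versions must be named, nonnegative and sum to 1")
    }
  }
  structure(list(seed = as.integer(seed), p_exposed = p_exposed,
                 exposure = exposure, versions = versions, context = context),
            class = "scc_trial_spec")
}

resolve_context <- function(model, exposure_name, spec, exposed_share) {
  others <- setdiff(names(model$exposures), exposure_name)
  ctx <- vapply(model$exposures[others], function(e) e$reference, character(1))
  if (is.null(spec$context)) return(ctx)
  if (is.list(spec$context)) {
    var <- spec$context$variable
    if (is.null(var) || !var %in% others) {
      rlang::abort("context rule must name a non-randomized exposure variable")
    }
    thr <- spec$context$threshold
    e <- model$exposures[[var]]
    ctx[[var]] <- if (exposed_share >= thr) exposed_level(e) else e$reference
    return(ctx)
  }
  fixed <- spec$context
  bad <- setdiff(names(fixed), others)
  if (length(bad)) {
    rlang::abort(sprintf("context fixes unknown/randomized variable(s): %s",
                         paste(bad, collapse = ", ")))
  }
  for (v in names(fixed)) {
    if (!fixed[[v]] %in% model$exposures[[v]]$levels) {
      rlang::abort(sprintf("'%s' is not a level of '%s'", fixed[[v]], v))
    }
    ctx[[v]] <- fixed[[v]]
  }
  ctx
}

#' Run one idealized randomized trial
#'
#' Assigns each individual to the exposed arm with probability
#' `spec$p_exposed`, draws a version of treatment for exposed individuals
#' when the spec carries a version distribution, resolves the interference
#' context, evaluates every outcome through the model, and contrasts the arm
#' risks. The analytic risk difference for the same version mixture and
#' context is computed alongside for comparison; each individual's true
#' response type (over all levels of the randomized exposure, at the
#' realized context) is recorded so exchangeability can be diagnosed.
#'
#' @param model A valid [scc_model()].
#' @param pop A population from [sample_population()].
#' @param spec A [trial_spec()].
#' @return An object of class `scc_trial`: per-individual `data`
#'   (`arm`, `level`, `outcome`, `type`), per-arm summary `arms`, realized
#'   `context`, `estimated_rd`, `true_rd`.
#' @examples
#' m <- apply_monotonicity(scc_fixture("basic"))
#' pop <- sample_population(m, 2000, seed = 7)
#' run_trial(m, pop, trial_spec(seed = 7))
#' @export
run_trial <- function(model, pop, spec) {
  assert_valid_model(model)
  stopifnot(inherits(spec, "scc_trial_spec"))
  exposure_name <- spec$exposure %||% names(model$exposures)[1]
  if (!exposure_name %in% names(model$exposures)) {
    rlang::abort(sprintf("unknown exposure variable '%s'", exposure_name))
  }
  evar <- model$exposures[[exposure_name]]
  nonref <- setdiff(evar$levels, evar$reference)
  if (!is.null(spec$versions)) {
    if (length(nonref) < 2L) {
      rlang::abort(sprintf(
        "exposure '%s' has a single exposed level: the model carries no versions of treatment",
        exposure_name))
    }
    bad <- setdiff(names(spec$versions), nonref)
    if (length(bad)) {
      rlang::abort(sprintf("version weight(s) over undeclared level(s): %s",
                           paste(bad, collapse = ", ")))
    }
  } else if (length(nonref) > 1L) {
    rlang::abort(sprintf(
      "exposure '%s' has several versions (%s): supply a version distribution",
      exposure_name, paste(nonref, collapse = ", ")))
  }

  n <- nrow(pop)
  mat <- as.matrix(tibble::as_tibble(pop)[, model$components$component, drop = FALSE])
  exposed <- with_seed(sub_seed(spec$seed, 2L), stats::runif(n) < spec$p_exposed)
  level <- rep(evar$reference, n)
  if (is.null(spec$versions)) {
    level[exposed] <- nonref[1]
  } else {
    level[exposed] <- with_seed(sub_seed(spec$seed, 3L), {
      sample(names(spec$versions), sum(exposed), replace = TRUE,
             prob = spec$versions)
    })
  }
  ctx <- resolve_context(model, exposure_name, spec, mean(exposed))

  # realized outcomes + full potential-outcome vector at the realized context
  po <- matrix(0L, n, length(evar$levels),
               dimnames = list(NULL, evar$levels))
  for (lv in evar$levels) {
    a <- c(stats::setNames(lv, exposure_name), ctx)[names(model$exposures)]
    po[, lv] <- population_outcomes(model, mat, a)
  }
  outcome <- po[cbind(seq_len(n), match(level, evar$levels))]
  type <- do.call(paste0, as.data.frame(po))

  data <- tibble::tibble(
    id = seq_len(n),
    arm = ifelse(exposed, "exposed", "unexposed"),
    level = level, outcome = outcome, type = type)
  arms <- data |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n = dplyr::n(), risk = mean(.data$outcome),
                     .groups = "drop")
  est_rd <- if (all(c("exposed", "unexposed") %in% arms$arm)) {
    arms$risk[arms$arm == "exposed"] - arms$risk[arms$arm == "unexposed"]
  } else {
    NA_real_
  }

  # analytic risk difference for the same version mixture at this context
  w <- spec$versions %||% stats::setNames(1, nonref[1])
  conds <- list()
  for (v in names(w)) {
    conds[[paste0("v.", v)]] <- c(stats::setNames(v, exposure_name), ctx)[names(model$exposures)]
  }
  conds[["v.ref"]] <- c(stats::setNames(evar$reference, exposure_name), ctx)[names(model$exposures)]
  ty <- enumerate_response_types(model, conds)
  true_rd <- sum(vapply(names(w), function(v) {
    w[[v]] * (risk_under(ty, paste0("v.", v)) - risk_under(ty, "v.ref"))
  }, numeric(1)))

  structure(
    list(data = data, arms = arms, n = n, context = ctx,
         estimated_rd = est_rd, true_rd = true_rd,
         spec = spec, model_name = model$name),
    class = "scc_trial")
}

#' @export
print.scc_trial <- function(x, ...) {
  cat(sprintf("<scc_trial: %s, n = %d>\n", x$model_name, x$n))
  if (length(x$context)) {
    cat(sprintf("  context: %s\n",
                paste(names(x$context), x$context, sep = "=", collapse = ", ")))
  }
  print(x$arms)
  cat(sprintf("  estimated RD: %.6f  analytic RD: %.6f\n",
              x$estimated_rd, x$true_rd))
  invisible(x)
}

#' Exchangeability diagnostic for a simulated trial
#'
#' Total-variation distance between the empirical response-type
#' distributions of the two arms — computable here because the simulation
#' knows each individual's true type. Randomization makes the arms
#' exchangeable, so the distance concentrates near 0; a large value signals
#' that the arms are not comparable and association would not equal
#' causation.
#'
#' @param result An `scc_trial` from [run_trial()].
#' @return Total-variation distance in `[0, 1]`.
#' @export
exchangeability_diagnostic <- function(result) {
  stopifnot(inherits(result, "scc_trial"))
  d <- result$data
  if (!all(c("exposed", "unexposed") %in% d$arm)) {
    rlang::abort("both arms must be nonempty to diagnose exchangeability")
  }
  types <- sort(unique(d$type))
  p_e <- tabulate(match(d$type[d$arm == "exposed"], types), length(types))
  p_u <- tabulate(match(d$type[d$arm == "unexposed"], types), length(types))
  sum(abs(p_e / sum(p_e) - p_u / sum(p_u))) / 2
}

#' Map how the estimated effect moves with the version or context mix
#'
#' Replicated trials across a grid of version distributions, interference
#' contexts, or assignment probabilities. When SUTVA holds the estimated
#' risk difference is flat across the grid (up to Monte Carlo error); when
#' unstable response types carry positive mass it tracks the analytic
#' mixture line — the study estimand itself depends on how the treatment was
#' operationalized or on who else was exposed.
#'
#' @param model A valid [scc_model()].
#' @param grid For `mode = "versions"` or `"context"`: list of named weight
#'   vectors (over version levels resp. context levels). For
#'   `mode = "assignment"`: numeric vector of exposure-assignment
#'   probabilities.
#' @param n Individuals per trial.
#' @param replicates Trials per grid point (fresh population each).
#' @param seed Root seed.
#' @param mode Grid interpretation; see `grid`.
#' @param variable Variable carrying the versions (defaults to the
#'   randomized exposure) or the context (defaults to the model's second
#'   exposure variable).
#' @param exposure Randomized exposure variable; defaults to the first
#'   declared variable.
#' @param p_exposed Assignment probability (ignored for
#'   `mode = "assignment"`).
#' @return A tibble of class `scc_bias_experiment`: one row per grid point
#'   with `point`, `mean_estimated_rd`, `sd_estimated_rd`, `analytic_rd`,
#'   `replicates`, `n`, and the per-replicate estimates as a list column.
#' @examples
#' m <- apply_monotonicity(scc_fixture("versions"))
#' sutva_bias_experiment(m, list(c(flat = 1, hilly = 0), c(flat = 0, hilly = 1)),
#'                       n = 2000, replicates = 2, seed = 1)
#' @export
sutva_bias_experiment <- function(model, grid, n, replicates = 1, seed,
                                  mode = c("versions", "context", "assignment"),
                                  variable = NULL, exposure = NULL,
                                  p_exposed = 0.5) {
  assert_valid_model(model)
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) {
    rlang::abort("sutva_bias_experiment requires an explicit seed")
  }
  if (replicates < 1) rlang::abort("replicates must be at least 1")
  if (mode == "assignment") grid <- as.list(grid)
  if (!is.list(grid) || length(grid) == 0L) {
    rlang::abort("grid must be a nonempty list")
  }
  grid <- unname(grid)
  exposure <- exposure %||% names(model$exposures)[1]
  if (mode == "context") {
    variable <- variable %||% setdiff(names(model$exposures), exposure)[1]
    if (is.na(variable)) {
      rlang::abort("context mode needs a second exposure variable")
    }
  }

  rows <- purrr::imap_dfr(grid, function(g, i) {
    i <- as.integer(i)
    ests <- vapply(seq_len(replicates), function(r) {
      s <- sub_seed(seed, i * 131071L + r)
      pop <- sample_population(model, n, seed = s)
      if (mode == "versions") {
        tr <- run_trial(model, pop, trial_spec(
          seed = s, p_exposed = p_exposed, exposure = exposure, versions = g))
        tr$estimated_rd
      } else if (mode == "assignment") {
        tr <- run_trial(model, pop, trial_spec(
          seed = s, p_exposed = g, exposure = exposure))
        tr$estimated_rd
      } else {
        sum(vapply(names(g)[g > 0], function(ctx) {
          tr <- run_trial(model, pop, trial_spec(
            seed = s, p_exposed = p_exposed, exposure = exposure,
            context = stats::setNames(ctx, variable)))
          g[[ctx]] * tr$estimated_rd
        }, numeric(1)))
      }
    }, numeric(1))
    analytic <- switch(mode,
      versions = overall_rd(mixture_effect(model, g, variable %||% exposure)),
      context = overall_rd(mixture_effect(model, g, variable, contrast = exposure)),
      assignment = {
        ty <- enumerate_response_types(
          model, scc_conditions(model, exposure))
        evar <- model$exposures[[exposure]]
        average_causal_rd(ty, exposed_level(evar), evar$reference)
      })
    lab <- if (mode == "assignment") sprintf("p=%g", g) else {
      paste(names(g), g, sep = "=", collapse = ",")
    }
    tibble::tibble(point = lab, mean_estimated_rd = mean(ests),
                   sd_estimated_rd = stats::sd(ests), analytic_rd = analytic,
                   replicates = replicates, n = as.integer(n),
                   estimates = list(ests))
  })
  attr(rows, "mode") <- mode
  attr(rows, "model_name") <- model$name
  class(rows) <- c("scc_bias_experiment", class(rows))
  rows
}
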