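#' Population risk under one exposure condition
#'
#' The risk of the outcome if the whole population were placed under the
#' given condition: the total probability of response types whose potential
#' outcome under that condition is 1 (for a binary contrast, the doomed plus
#' the causal types under exposure; the doomed plus the preventive types
#' under non-exposure).
#'
#' @param types An `scc_types` tibble, or any tibble with a `probability`
#'   column and 0/1 condition columns.
#' @param condition Condition column name.
#' @return A probability in `[0, 1]`.
#' @examples
#' ty <- enumerate_response_types(scc_fixture("basic"))
#' risk_under(ty, "exposed")
#' @export
risk_under <- function(types, condition) {
  if (!condition %in% names(types)) {
    rlang::abort(sprintf("condition '%s' not present in the type table", condition))
  }
  sum(types$probability[types[[condition]] == 1L])
}

#' Average causal risk difference
#'
#' The population average causal effect on the difference scale: risk if
#' everyone were under the exposed condition minus risk if everyone were
#' under the unexposed condition. For a two-condition binary contrast this
#' equals the proportion of causal types minus the proportion of preventive
#' types; under monotonicity it is the proportion of causal types alone.
#'
#' @inheritParams risk_under
#' @param exposed,unexposed Condition column names to contrast.
#' @return A signed difference in `[-1, 1]`.
#' @examples
#' ty <- enumerate_response_types(scc_fixture("basic"))
#' average_causal_rd(ty, "exposed", "unexposed")
#' @export
average_causal_rd <- function(types, exposed, unexposed) {
  risk_under(types, exposed) - risk_under(types, unexposed)
}

#' Decompose the observed effect over versions of treatment or contexts
#'
#' When the nominally single exposure hides several versions (or when the
#' effect depends on an interference context), the effect a study identifies
#' is a mixture: the weighted average of the per-version (per-context) risk
#' differences, with weights given by how versions or contexts are
#' distributed in that particular study. Version/context assignment is taken
#' to be independent of individuals' component profiles, as under
#' randomization, so the overall risk difference is exactly the
#' weight-averaged per-stratum risk difference.
#'
#' Two modes:
#' * version mode (`contrast = NULL`): `variable` is the exposure whose
#'   non-reference levels are the treatment versions; each stratum contrasts
#'   one version against the reference level.
#' * context mode (`contrast` given): `variable` is the interference-context
#'   variable (exposure of influential others); each stratum fixes one
#'   context level and contrasts `contrast`'s exposed level against its
#'   reference within that context.
#'
#' @param model A valid [scc_model()].
#' @param weights Named nonnegative numeric vector summing to 1: version
#'   levels (version mode) or context levels (context mode) mapped to their
#'   share.
#' @param variable Exposure-variable name carrying the versions or contexts;
#'   defaults to the first declared variable.
#' @param contrast Optional name of the binary exposure to contrast within
#'   each context (switches to context mode).
#' @return A tibble of class `scc_effect`: `stratum`, `weight`,
#'   `risk_exposed`, `risk_unexposed`, `rd`, with a final `overall` row
#'   holding the mixture.
#' @examples
#' m <- apply_monotonicity(scc_fixture("versions"))
#' mixture_effect(m, c(flat = 0.5, hilly = 0.5), "ride")
#' @export
mixture_effect <- function(model, weights, variable = names(model$exposures)[1],
                           contrast = NULL) {
  assert_valid_model(model)
  if (!variable %in% names(model$exposures)) {
    rlang::abort(sprintf("unknown exposure variable '%s'", variable))
  }
  var <- model$exposures[[variable]]
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    rlang::abort("weights must be named by level")
  }
  bad <- setdiff(names(weights), var$levels)
  if (length(bad)) {
    rlang::abort(sprintf("weight level(s) not declared for '%s': %s",
                         variable, paste(bad, collapse = ", ")))
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    rlang::abort("weights must be nonnegative and sum to 1")
  }

  base <- vapply(model$exposures, function(e) e$reference, character(1))
  if (is.null(contrast)) {
    if (any(names(weights) == var$reference)) {
      rlang::abort(sprintf(
        "version weights may not include the reference level '%s'", var$reference))
    }
    strata <- lapply(names(weights), function(v) {
      e <- base; e[[variable]] <- v
      list(exposed = e, unexposed = base)
    })
  } else {
    if (!contrast %in% names(model$exposures)) {
      rlang::abort(sprintf("unknown contrast variable '%s'", contrast))
    }
    cvar <- model$exposures[[contrast]]
    if (length(cvar$levels) != 2L) {
      rlang::abort("context mode requires a binary contrast variable")
    }
    strata <- lapply(names(weights), function(ctx) {
      e <- base; e[[variable]] <- ctx; e[[contrast]] <- exposed_level(cvar)
      u <- base; u[[variable]] <- ctx
      list(exposed = e, unexposed = u)
    })
  }
  names(strata) <- names(weights)

  conds <- list()
  for (s in names(strata)) {
    conds[[paste0(s, ".exposed")]] <- strata[[s]]$exposed
    conds[[paste0(s, ".unexposed")]] <- strata[[s]]$unexposed
  }
  ty <- enumerate_response_types(model, conds)

  out <- purrr::map_dfr(names(strata), function(s) {
    re <- risk_under(ty, paste0(s, ".exposed"))
    ru <- risk_under(ty, paste0(s, ".unexposed"))
    tibble::tibble(stratum = s, weight = unname(weights[[s]]),
                   risk_exposed = re, risk_unexposed = ru, rd = re - ru)
  })
  overall <- tibble::tibble(
    stratum = "overall", weight = 1,
    risk_exposed = sum(out$weight * out$risk_exposed),
    risk_unexposed = sum(out$weight * out$risk_unexposed),
    rd = sum(out$weight * out$rd))
  out <- dplyr::bind_rows(out, overall)
  attr(out, "mode") <- if (is.null(contrast)) "versions" else "context"
  attr(out, "variable") <- variable
  attr(out, "contrast") <- contrast
  class(out) <- c("scc_effect", class(out))
  out
}

#' Overall risk difference of an effect decomposition
#'
#' @param decomposition An `scc_effect` tibble from [mixture_effect()].
#' @return The overall (mixture) risk difference.
#' @export
overall_rd <- function(decomposition) {
  decomposition$rd[decomposition$stratum == "overall"]
}
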