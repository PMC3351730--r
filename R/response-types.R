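#' Enumerate the response types implied by a model
#'
#' Every one of the `2^k` component profiles (k declared background
#' components) is evaluated under each condition; profiles sharing an outcome
#' vector are grouped into one response type. Type probabilities come from
#' the independent component prevalences, or from the model's explicit joint
#' profile distribution when present. Rows are sorted by outcome vector,
#' descending lexicographically, so the all-ones ("doomed") vector comes
#' first and the all-zeros ("immune") vector last.
#'
#' @param model A valid [scc_model()] with at most 20 components.
#' @param conditions Named list of assignments; defaults to
#'   [scc_conditions()] over all exposure variables.
#' @return A tibble of class `scc_types`: `type` (outcome vector as a 0/1
#'   string), one integer 0/1 column per condition, `profiles` (list column
#'   of the component profiles mapping to the type), `probability`.
#' @examples
#' enumerate_response_types(scc_fixture("basic"))
#' @export
enumerate_response_types <- function(model, conditions = scc_conditions(model)) {
  assert_valid_model(model)
  stopifnot(is.list(conditions), length(conditions) > 0L)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    rlang::abort("conditions must be a named list of assignments")
  }
  comps <- model$components$component
  k <- length(comps)
  if (k > 20L) {
    rlang::abort(paste0(
      "model declares ", k, " components; exact enumeration is limited to ",
      "2^20 profiles. Use sample_population() / run_trial() for Monte Carlo ",
      "estimates instead."))
  }
  conditions <- lapply(conditions, function(a) as_assignment(model, a))

  # per condition: bit mask of required components for each matching cause
  comp_bit <- stats::setNames(bitwShiftL(1L, seq_len(k) - 1L), comps)
  cause_masks <- lapply(conditions, function(a) {
    hit <- Filter(function(ca) cause_matches_assignment(ca, a), model$causes)
    vapply(hit, function(ca) {
      if (length(ca$components) == 0L) 0L else sum(comp_bit[ca$components])
    }, integer(1))
  })

  n_prof <- bitwShiftL(1L, k)
  prof_ids <- seq_len(n_prof) - 1L
  outcomes <- vapply(cause_masks, function(masks) {
    if (length(masks) == 0L) return(rep(0L, n_prof))
    o <- rep(FALSE, n_prof)
    for (m in masks) o <- o | (bitwAnd(prof_ids, m) == m)
    as.integer(o)
  }, integer(n_prof))
  outcomes <- matrix(outcomes, nrow = n_prof,
                     dimnames = list(NULL, names(conditions)))

  prob <- profile_probabilities(model, prof_ids, comp_bit)
  key <- apply(outcomes, 1L, paste, collapse = "")
  prof_labels <- lapply(prof_ids, function(id) comps[bitwAnd(id, comp_bit) > 0L])

  groups <- split(seq_len(n_prof), key)
  groups <- groups[order(names(groups), method = "radix", decreasing = TRUE)]

  out <- tibble::tibble(
    type = names(groups),
    probability = unname(vapply(groups, function(i) sum(prob[i]), numeric(1))),
    profiles = unname(lapply(groups, function(i) prof_labels[i]))
  )
  vec_cols <- do.call(rbind, lapply(groups, function(i) outcomes[i[1], , drop = TRUE]))
  vec_cols <- tibble::as_tibble(matrix(as.integer(vec_cols), nrow = nrow(out),
                                       dimnames = list(NULL, names(conditions))))
  out <- dplyr::bind_cols(out["type"], vec_cols, out[c("profiles", "probability")])
  attr(out, "conditions") <- conditions
  attr(out, "model_name") <- model$name
  class(out) <- c("scc_types", class(out))
  out
}

profile_probabilities <- function(model, prof_ids, comp_bit) {
  comps <- model$components$component
  if (is.null(model$joint)) {
    prev <- model$components$prevalence
    prob <- rep(1, length(prof_ids))
    for (j in seq_along(comps)) {
      present <- bitwAnd(prof_ids, comp_bit[[j]]) > 0L
      prob <- prob * ifelse(present, prev[j], 1 - prev[j])
    }
    return(prob)
  }
  j <- model$joint
  jkey <- vapply(seq_len(nrow(j)), function(r) {
    sum(comp_bit[comps[as.logical(j[r, comps, drop = TRUE])]], 0L)
  }, numeric(1))
  prob <- rep(0, length(prof_ids))
  prob[match(jkey, prof_ids)] <- j$prob
  prob
}

#' Classify response types for a binary contrast
#'
#' Labels each response type by its potential outcomes under one exposed and
#' one unexposed condition: `(1,1)` doomed, `(1,0)` causal, `(0,1)`
#' preventive, `(0,0)` immune.
#'
#' @param types An `scc_types` tibble from [enumerate_response_types()].
#' @param exposed,unexposed Names of the two condition columns to contrast.
#' @return `types` with a `label` factor column added.
#' @examples
#' classify_binary(enumerate_response_types(scc_fixture("basic")),
#'                 "exposed", "unexposed")
#' @export
classify_binary <- function(types, exposed, unexposed) {
  for (cond in c(exposed, unexposed)) {
    if (!cond %in% names(types)) {
      rlang::abort(sprintf("condition '%s' not present in the type table", cond))
    }
  }
  lab <- c("immune", "preventive", "causal", "doomed")
  idx <- 2L * types[[exposed]] + types[[unexposed]] + 1L
  types$label <- factor(lab[idx], levels = c("doomed", "causal", "preventive", "immune"))
  types
}

#' Impose monotonicity on an exposure
#'
#' Monotonicity assumes the exposure is never preventive. Distributionally,
#' that means nobody carries the causal partners that act only with the
#' exposure's reference level: every component appearing exclusively in
#' causes that contain the reference-level literal has its prevalence set to
#' 0. Model structure is untouched, so the "grey row" types remain printable
#' with probability 0, and re-applying the transform is a no-op.
#'
#' @param model A valid [scc_model()].
#' @param exposures Exposure-variable name(s) to make monotone; defaults to
#'   all declared variables.
#' @return A new `scc_model`; the input is not modified.
#' @examples
#' m <- apply_monotonicity(scc_fixture("basic"), "E")
#' m$components
#' @export
apply_monotonicity <- function(model, exposures = NULL) {
  assert_valid_model(model)
  exposures <- exposures %||% names(model$exposures)
  bad <- setdiff(exposures, names(model$exposures))
  if (length(bad)) {
    rlang::abort(sprintf("unknown exposure variable(s): %s", paste(bad, collapse = ", ")))
  }
  zero <- character()
  for (var in exposures) {
    ref <- model$exposures[[var]]$reference
    for (comp in model$components$component) {
      appearances <- Filter(function(ca) comp %in% ca$components, model$causes)
      if (length(appearances) == 0L) next
      only_ref <- all(vapply(appearances, function(ca) {
        var %in% names(ca$literals) && identical(unname(ca$literals[var]), ref)
      }, logical(1)))
      if (only_ref) zero <- c(zero, comp)
    }
  }
  zero <- unique(zero)
  model$components$prevalence[model$components$component %in% zero] <- 0
  if (!is.null(model$joint) && length(zero)) {
    keep <- !Reduce(`|`, lapply(zero, function(z) as.logical(model$joint[[z]])),
                    rep(FALSE, nrow(model$joint)))
    total <- sum(model$joint$prob[keep])
    if (total <= 0) {
      rlang::abort("monotonicity removes all mass from the joint profile distribution")
    }
    model$joint <- model$joint[keep, , drop = FALSE]
    model$joint$prob <- model$joint$prob / total
  }
  model
}

#' Stability of response types across interference or version contexts
#'
#' Partitions the condition set into contrast groups — one
#' (exposed, unexposed) pair per context, e.g. the own-exposure contrast when
#' influential others are unexposed versus when they are exposed — and flags
#' each response type. A type has stable potential outcomes when its
#' sub-vector is identical in every group; it has a stable causal effect when
#' the within-group risk difference (exposed minus unexposed) is identical in
#' every group. Stable potential outcomes imply a stable effect, never the
#' converse. Aggregates count only types carrying positive probability.
#'
#' @param types An `scc_types` tibble from [enumerate_response_types()].
#' @param contrast_groups Named list; each element a character vector of two
#'   condition names, exposed first.
#' @return An object of class `scc_stability` with elements `types` (the
#'   input plus `stable_potential_outcomes` and `stable_causal_effect`
#'   columns), `groups`, `unstable_type_count`, `unstable_probability_mass`.
#' @examples
#' m <- apply_monotonicity(scc_fixture("interference"))
#' ty <- enumerate_response_types(m)
#' stability_report(ty, list(
#'   others_unexposed = c("exposed.others_unexposed", "unexposed.others_unexposed"),
#'   others_exposed   = c("exposed.others_exposed", "unexposed.others_exposed")))
#' @export
stability_report <- function(types, contrast_groups) {
  if (!is.list(contrast_groups) || length(contrast_groups) == 0L) {
    rlang::abort("contrast_groups must be a nonempty named list of condition pairs")
  }
  for (g in contrast_groups) {
    if (length(g) != 2L) {
      rlang::abort("each contrast group must hold exactly one (exposed, unexposed) pair")
    }
    missing <- setdiff(g, names(types))
    if (length(missing)) {
      rlang::abort(sprintf("condition '%s' not present in the type table", missing[1]))
    }
  }
  sub <- lapply(contrast_groups, function(g) {
    cbind(types[[g[1]]], types[[g[2]]])
  })
  ref <- sub[[1]]
  stable_po <- Reduce(`&`, lapply(sub, function(s) {
    s[, 1] == ref[, 1] & s[, 2] == ref[, 2]
  }))
  ref_rd <- ref[, 1] - ref[, 2]
  stable_ce <- Reduce(`&`, lapply(sub, function(s) (s[, 1] - s[, 2]) == ref_rd))
  types$stable_potential_outcomes <- stable_po
  types$stable_causal_effect <- stable_ce
  pos <- types$probability > 0
  structure(
    list(types = types, groups = contrast_groups,
         unstable_type_count = sum(!stable_po & pos),
         unstable_probability_mass = sum(types$probability[!stable_po])),
    class = "scc_stability")
}

#' Probability mass of unstable potential outcomes
#'
#' Total probability of the component profiles whose response type changes
#' across the contrast groups — the share of the population for whom the set
#' of potential outcomes depends on the version of treatment received or on
#' the exposure of influential others. Zero exactly when SUTVA holds for the
#' given contrasts.
#'
#' @inheritParams stability_report
#' @param model A valid [scc_model()].
#' @param conditions Named list of assignments covering every condition the
#'   contrast groups mention; defaults to [scc_conditions()].
#' @return A probability in `[0, 1]`.
#' @examples
#' m <- apply_monotonicity(scc_fixture("basic"))
#' unstable_profile_mass(m, list(main = c("exposed", "unexposed")))  # 0
#' @export
unstable_profile_mass <- function(model, contrast_groups,
                                  conditions = scc_conditions(model)) {
  rep <- stability_report(enumerate_response_types(model, conditions),
                          contrast_groups)
  rep$unstable_probability_mass
}

#' Profiles with unstable potential outcomes
#'
#' @inheritParams unstable_profile_mass
#' @return List of component profiles (character vectors) belonging to
#'   response types whose potential outcomes are unstable across the
#'   contrast groups.
#' @export
unstable_profiles <- function(model, contrast_groups,
                              conditions = scc_conditions(model)) {
  rep <- stability_report(enumerate_response_types(model, conditions),
                          contrast_groups)
  unstable <- rep$types$profiles[!rep$types$stable_potential_outcomes]
  unlist(unstable, recursive = FALSE)
}

#' @export
print.scc_stability <- function(x, ...) {
  cat(sprintf("<scc_stability: %d contrast group(s)>\n", length(x$groups)))
  cat(sprintf("  unstable types (positive mass): %d\n", x$unstable_type_count))
  cat(sprintf("  unstable probability mass: %.6f\n", x$unstable_probability_mass))
  print(x$types, ...)
  invisible(x)
}
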