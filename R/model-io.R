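#' Read a model specification file
#'
#' Model specifications are YAML with four sections: `name`; `exposures`, a
#' list of `{name, levels, reference}` entries; `components`, a map from
#' component name to prevalence; `causes`, a list of `{when, requires}`
#' entries where `when` maps exposure variables to the level the cause needs
#' (omit `when` for causes that fire regardless of exposure) and `requires`
#' lists the component causes. An optional `joint` section (list of rows
#' with one TRUE/FALSE entry per component plus `prob`) replaces the
#' independent prevalences. See the packaged fixtures for worked files.
#'
#' @param path Path to a YAML model file.
#' @return A validated [scc_model()].
#' @examples
#' read_scc_model(system.file("extdata", "basic.yaml", package = "sccsutva"))
#' @export
read_scc_model <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no model file at '%s'", path))
  spec <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rlang::abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  })
  if (!is.list(spec) || is.null(spec$exposures) || is.null(spec$causes)) {
    rlang::abort(sprintf(
      "'%s' is not a model specification (needs exposures/components/causes)", path))
  }
  exposures <- lapply(spec$exposures, function(e) {
    exposure_variable(e$name, unlist(e$levels),
                      reference = e$reference %||% e$levels[[length(e$levels)]])
  })
  components <- unlist(spec$components) %||% stats::setNames(numeric(), character())
  causes <- lapply(spec$causes, function(ca) {
    sufficient_cause(literals = unlist(ca$when) %||% character(),
                     components = unlist(ca$requires) %||% character())
  })
  joint <- NULL
  if (!is.null(spec$joint)) {
    joint <- dplyr::bind_rows(lapply(spec$joint, tibble::as_tibble))
  }
  model <- scc_model(spec$name %||% basename(path), exposures, components,
                     causes, joint = joint)
  v <- validate_model(model)
  if (length(v)) {
    rlang::abort(c(sprintf("'%s' is not a valid model:", path),
                   stats::setNames(v, rep("x", length(v)))))
  }
  model
}

#' Write a model specification file
#'
#' Inverse of [read_scc_model()]: the written file loads back to a model
#' with identical enumeration output for every condition set.
#'
#' @param model A valid [scc_model()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_scc_model <- function(model, path) {
  assert_valid_model(model)
  spec <- list(
    name = model$name,
    exposures = lapply(unname(model$exposures), function(e) {
      list(name = e$name, levels = as.list(e$levels), reference = e$reference)
    }),
    components = as.list(stats::setNames(model$components$prevalence,
                                         model$components$component)),
    causes = lapply(model$causes, function(ca) {
      out <- list()
      if (length(ca$literals)) out$when <- as.list(ca$literals)
      if (length(ca$components)) out$requires <- as.list(ca$components)
      out
    })
  )
  if (!is.null(model$joint)) {
    spec$joint <- lapply(seq_len(nrow(model$joint)), function(i) {
      as.list(model$joint[i, , drop = FALSE])
    })
  }
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Packaged example models
#'
#' Three small models spanning the SUTVA landscape:
#' * `basic` — one binary exposure `E`, no SUTVA violation: causes
#'   `E+U`, `unexposed+W`, `X`.
#' * `versions` — unrepresented versions of treatment: exposure `ride`
#'   with levels `flat`/`hilly`/`none` and causes `flat+U1`, `hilly+U2`,
#'   `none+W`, `X`.
#' * `interference` — interference between units: own exposure `E` crossed
#'   with the exposure `I` of influential others; causes `X`, `E+U1`,
#'   `I+U2`, `E+I+U3`, `unexposed+W1`, `others_unexposed+W2`.
#'
#' Default prevalences are documented in each spec file and are free
#' parameters: override them by editing `model$components$prevalence`.
#'
#' @param name One of `"basic"`, `"versions"`, `"interference"`.
#' @return A validated [scc_model()].
#' @examples
#' scc_fixture("versions")
#' @export
scc_fixture <- function(name) {
  available <- scc_fixtures()
  if (length(name) != 1L || !name %in% available) {
    rlang::abort(sprintf("unknown fixture '%s'; available: %s",
                         paste(name, collapse = ","),
                         paste(available, collapse = ", ")))
  }
  read_scc_model(system.file("extdata", paste0(name, ".yaml"),
                             package = "sccsutva", mustWork = TRUE))
}

#' @rdname scc_fixture
#' @export
scc_fixtures <- function() {
  sort(sub("\\.yaml$", "",
           dir(system.file("extdata", package = "sccsutva"), pattern = "\\.yaml$")))
}

#' Condition set for pairwise (spousal) interference
#'
#' When interference runs within pairs — e.g. both spouses appear in the
#' study and each spouse's effect may depend on the other's exposure — a
#' stable causal contrast requires recoding to four exposure conditions
#' rather than two: own exposure crossed with the partner's. This returns
#' that crossed condition set.
#'
#' @param model A valid [scc_model()].
#' @param own Name of the individual's own (binary) exposure variable.
#' @param others Name of the partner's / influential others' (binary)
#'   exposure variable.
#' @return Named list of four assignments.
#' @examples
#' length(interference_conditions(scc_fixture("interference"), "E", "I"))
#' @export
interference_conditions <- function(model, own = names(model$exposures)[1],
                                    others = names(model$exposures)[2]) {
  assert_valid_model(model)
  for (v in c(own, others)) {
    if (is.na(v) || !v %in% names(model$exposures)) {
      rlang::abort("own and others must name declared exposure variables")
    }
    if (length(model$exposures[[v]]$levels) != 2L) {
      rlang::abort(sprintf("pairwise recoding needs a binary variable; '%s' is not", v))
    }
  }
  scc_conditions(model, c(own, others))
}

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a response-type table as delimited text
#'
#' Tab-separated, one row per response type: outcome vector string, the
#' per-condition 0/1 outcomes, the label when present, the defining
#' component profiles (`+`-joined, `;`-separated, empty profile shown as
#' `-`), and the probability with 6 decimal places.
#'
#' @param types An `scc_types` tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_type_table <- function(types, path) {
  conds <- names(attr(types, "conditions"))
  out <- tibble::as_tibble(types)[, c("type", conds)]
  if ("label" %in% names(types)) out$label <- as.character(types$label)
  out$profiles <- vapply(types$profiles, function(ps) {
    paste(vapply(ps, function(p) if (length(p)) paste(p, collapse = "+") else "-",
                 character(1)), collapse = ";")
  }, character(1))
  out$probability <- fmt6(types$probability)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an effect decomposition as delimited text
#'
#' Tab-separated with columns stratum, weight, risk_exposed,
#' risk_unexposed, rd; the overall mixture row comes last. Numbers carry 6
#' decimal places.
#'
#' @param decomposition An `scc_effect` tibble from [mixture_effect()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(decomposition, path) {
  out <- tibble::as_tibble(decomposition)
  for (col in c("weight", "risk_exposed", "risk_unexposed", "rd")) {
    out[[col]] <- fmt6(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
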