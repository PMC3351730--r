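#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an SCC model into one row per sufficient cause
#'
#' @param x An [scc_model()].
#' @param ... Unused.
#' @return A tibble with columns `cause`, `literals`, `components`.
#' @export
tidy.scc_model <- function(x, ...) {
  purrr::imap_dfr(x$causes, function(ca, i) {
    tibble::tibble(
      cause = as.integer(i),
      literals = paste(names(ca$literals), ca$literals, sep = "=",
                       collapse = ","),
      components = paste(ca$components, collapse = ","))
  })
}

#' One-row summary of an SCC model
#'
#' @param x An [scc_model()].
#' @param ... Unused.
#' @return A tibble with the model name and its element counts.
#' @export
glance.scc_model <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_exposures = length(x$exposures),
    n_components = nrow(x$components),
    n_causes = length(x$causes),
    n_conditions = prod(vapply(x$exposures, function(e) length(e$levels),
                               numeric(1))),
    joint_distribution = !is.null(x$joint))
}

#' Tidy a simulated trial into its per-arm, per-level summary
#'
#' @param x An `scc_trial` from [run_trial()].
#' @param ... Unused.
#' @return A tibble with one row per (arm, received level): `n`, `risk`.
#' @export
tidy.scc_trial <- function(x, ...) {
  x$data |>
    dplyr::group_by(.data$arm, .data$level) |>
    dplyr::summarise(n = dplyr::n(), risk = mean(.data$outcome),
                     .groups = "drop")
}

#' One-row summary of a simulated trial
#'
#' @param x An `scc_trial` from [run_trial()].
#' @param ... Unused.
#' @return A tibble with arm risks, estimated and analytic risk difference,
#'   and the exchangeability total-variation diagnostic.
#' @export
glance.scc_trial <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, n = x$n,
    risk_exposed = x$arms$risk[x$arms$arm == "exposed"],
    risk_unexposed = x$arms$risk[x$arms$arm == "unexposed"],
    estimated_rd = x$estimated_rd, true_rd = x$true_rd,
    tv_exchangeability = exchangeability_diagnostic(x))
}

#' @export
tidy.scc_stability <- function(x, ...) tibble::as_tibble(x$types)

#' @export
glance.scc_stability <- function(x, ...) {
  tibble::tibble(
    n_types = nrow(x$types),
    n_contrast_groups = length(x$groups),
    unstable_type_count = x$unstable_type_count,
    unstable_probability_mass = x$unstable_probability_mass)
}

#' Plot a response-type distribution
#'
#' Bar chart of the probability mass on each response type (outcome vector),
#' coloured by the doomed/causal/preventive/immune label when the table has
#' been through [classify_binary()].
#'
#' @param object An `scc_types` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scc_types <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$type <- factor(df$type, levels = df$type)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$probability))
  p <- if ("label" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$label))
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "response type (outcome vector)", y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot how the estimated effect tracks the version/context mixture
#'
#' One point per grid point: mean estimated risk difference across
#' replicates (with a +/- 2 SD ribbon when replicates > 1) against the
#' analytic mixture risk difference shown as open diamonds. Under SUTVA the
#' points are flat; under a violation they move with the mixture.
#'
#' @param object An `scc_bias_experiment` from [sutva_bias_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scc_bias_experiment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$point <- factor(df$point, levels = df$point)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$point)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_estimated_rd),
                        size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$analytic_rd),
                        shape = 5, size = 3, colour = "firebrick")
  if (any(object$replicates > 1)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_estimated_rd - 2 * .data$sd_estimated_rd,
                   ymax = .data$mean_estimated_rd + 2 * .data$sd_estimated_rd),
      width = 0.15)
  }
  p + ggplot2::labs(x = sprintf("grid point (%s)", attr(object, "mode")),
                    y = "risk difference") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
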