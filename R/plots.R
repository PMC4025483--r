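#' Plot eigengene temporal patterns
#'
#' Line plot of the requested eigengenes across stages, one line per
#' pattern, on the unit-norm eigengene scale.
#'
#' @param object An [eigen_decompose()] result.
#' @param patterns Which patterns to draw (default the top 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eigengene_fit
#' @export
autoplot.eigengene_fit <- function(object, patterns = 1:3, ...) {
  patterns <- intersect(patterns, seq_along(object$singular_values))
  data <- tidy(object, "eigengenes") %>%
    filter(.data$pattern %in% patterns) %>%
    mutate(pattern = factor(.data$pattern))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$stage, y = .data$value,
    group = .data$pattern, colour = .data$pattern
  )) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "stage", y = "eigengene value", colour = "pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of eigenexpression fractions
#'
#' @param fit An [eigen_decompose()] result.
#' @return A ggplot object; the subtitle reports the entropy.
#' @export
plot_fractions <- function(fit) {
  if (!inherits(fit, "eigengene_fit")) {
    abort("`fit` must be an `eigengene_fit`.")
  }
  data <- tidy(fit, "fractions")
  ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$pattern), y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "eigengene pattern", y = "eigenexpression fraction",
      subtitle = sprintf("Shannon entropy d = %.3f", fit$entropy)
    ) +
    ggplot2::theme_minimal()
}

#' Box-plot panels of metabolite time courses
#'
#' Draws the five-number summaries from [summarize_timecourse()] in the
#' conventional style: a box from the first to the third quartile, the
#' median as the bar inside, whiskers spanning the minimum to the maximum,
#' and an asterisk over timepoints that differ significantly from baseline.
#'
#' @param summary Output of [summarize_timecourse()].
#' @param metabolites Which metabolites to draw (default: all present).
#' @return A ggplot object, faceted by metabolite with free y scales.
#' @export
plot_metabolite_boxes <- function(summary, metabolites = NULL) {
  require_columns(summary, c("metabolite", "timepoint", "min", "q1", "median",
                             "q3", "max", "significant"), "`summary`")
  if (!is.null(metabolites)) {
    summary <- filter(summary, .data$metabolite %in% metabolites)
  }
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$timepoint)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$min, ymax = .data$max), width = 0.25
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      fill = "grey85", linewidth = 0.3
    ) +
    ggplot2::geom_text(
      data = filter(summary, .data$significant),
      ggplot2::aes(y = .data$max, label = "*"), vjust = -0.2, size = 5
    ) +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::labs(x = "stage", y = "relative abundance (baseline = 100)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of nutrient-store levels
#'
#' @param stores Output of [analyze_stores()].
#' @return A ggplot object: mean with SEM error bars per timepoint, faceted
#'   by analyte, asterisks marking significant differences from baseline.
#' @export
plot_store_series <- function(stores) {
  require_columns(stores, c("analyte", "timepoint", "mean", "sem",
                            "significant"), "`stores`")
  ggplot2::ggplot(stores, ggplot2::aes(x = .data$timepoint, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.25
    ) +
    ggplot2::geom_text(
      data = filter(stores, .data$significant),
      ggplot2::aes(y = .data$mean + .data$sem, label = "*"),
      vjust = -0.2, size = 5
    ) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "stage", y = "fold of baseline mean") +
    ggplot2::theme_minimal()
}
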