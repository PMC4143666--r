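#' Manhattan plot of association results
#'
#' @param results Association result tibble (any subset of methods).
#' @param threshold Optional significance threshold drawn as a horizontal
#'   line (e.g. [bonferroni_threshold()]).
#' @return A ggplot object, faceted by method.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  dat <- manhattan_export(results)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6,
                                          y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, colour = "grey30") +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed", colour = "firebrick")
  }
  gg
}

#' Quantile-quantile plot of association p-values
#'
#' Observed versus expected -log10 p under the uniform null, per method,
#' annotated with the genomic-control inflation factor.
#'
#' @param results Association result tibble.
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  dat <- results |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(
      expected = -log10(stats::ppoints(dplyr::n())),
      observed = -log10(.data$p)
    ) |>
    dplyr::ungroup()
  lab <- dat |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(lambda = genomic_lambda(.data$p), .groups = "drop") |>
    dplyr::mutate(label = sprintf("lambda == %.3f", .data$lambda))
  ggplot2::ggplot(dat, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_text(data = lab, parse = TRUE,
                       ggplot2::aes(x = 0.5, y = Inf, label = .data$label),
                       hjust = 0, vjust = 1.5) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_lmm BLUP distribution of the fitted random intercepts.
#' @param object A `kinlong_fit` object.
#' @method autoplot kinlong_fit
#' @export
autoplot.kinlong_fit <- function(object, ...) {
  dat <- blup(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$blup)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "predicted random intercept (BLUP)", y = "individuals") +
    ggplot2::theme_minimal()
}
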