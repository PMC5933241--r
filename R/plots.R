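#' Plot observed occurrence rates against the unbiased reference
#'
#' The occurrence-rate profile plot: one point per word for the observed
#' dataset, the exact unbiased curve as a line, and (optionally) the
#' finite-sample confidence band from [tu_replicate_ci()] as dashed lines.
#'
#' @param data A sequence dataset.
#' @param k Window length.
#' @param ci Optional tibble from [tu_replicate_ci()].
#' @return A ggplot object.
#' @examples
#' plot_occurrence_rates(generate_bernoulli(60, seed = 1))
#' @export
plot_occurrence_rates <- function(data, k = 4, ci = NULL) {
  obs <- occurrence_rate(data, k)
  exact <- tu_reference(n = nchar(validate_dataset(data)$block[1]), k = k)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$word)) +
    ggplot2::geom_line(
      data = exact,
      ggplot2::aes(y = .data$rate, group = 1, linetype = "exact TU")
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate, shape = "observed")) +
    ggplot2::labs(x = "subsequence", y = "occurrence rate",
                  linetype = NULL, shape = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(ci)) {
    p <- p +
      ggplot2::geom_line(data = ci, ggplot2::aes(y = .data$lower, group = 1),
                         linetype = "dashed", colour = "grey40") +
      ggplot2::geom_line(data = ci, ggplot2::aes(y = .data$upper, group = 1),
                         linetype = "dashed", colour = "grey40")
  }
  p
}

#' @method autoplot tu_reference
#' @export
autoplot.tu_reference <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("rate", "expected_frequency", "mass_at_0"),
                              names_to = "statistic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$word, y = .data$value,
                                     group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "subsequence", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot perturbation_curve
#' @export
autoplot.perturbation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$param)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_median)) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "perturbation parameter",
                  y = "correlation with exact TU rates") +
    ggplot2::theme_minimal()
}

#' @method autoplot beta_lookup
#' @export
autoplot.beta_lookup <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$beta, y = .data$rate,
                               colour = .data$word)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "boost parameter", y = "occurrence rate",
                  colour = "subsequence") +
    ggplot2::theme_minimal()
}

#' @method autoplot boost_fit
#' @export
autoplot.boost_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals, ggplot2::aes(x = .data$word)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted, group = 1,
                                    linetype = "model")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     shape = "observed")) +
    ggplot2::labs(
      x = "subsequence", y = "occurrence rate",
      title = paste0("pair ", object$pair, ", beta = ",
                     signif(object$beta, 3), ", RMSE = ",
                     signif(object$rmse, 3)),
      linetype = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot mimicry_comparison
#' @export
autoplot.mimicry_comparison <- function(object, ...) {
  rates <- attr(object, "rates")
  long <- tidyr::pivot_longer(rates, c("stimulus", "exact"),
                              names_to = "reference", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$word)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$generated)) +
    ggplot2::facet_wrap(~reference) +
    ggplot2::labs(x = "subsequence", y = "occurrence rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
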