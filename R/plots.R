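# ggplot2 views of series and results.

#' Plot a multivariate series
#'
#' Raw scores per variable over time, optionally shaded by ground-truth
#' phase.
#'
#' @param data Series data frame.
#' @return A ggplot.
#' @export
plot_series <- function(data) {
  vars <- series_vars(data)
  df <- tibble::as_tibble(data)
  if (!"t" %in% names(df)) df$t <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, dplyr::all_of(vars),
                              names_to = "variable", values_to = "score")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$score))
  if ("phase" %in% names(data)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$phase),
                                             group = 1))
    p <- p + ggplot2::labs(colour = "phase")
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = "score") + ggplot2::theme_minimal()
}

#' @describeIn running_autocorrelations Running autocorrelations per
#'   variable against the window's median occasion.
#' @param object A `running_stats` tibble.
#' @param ... Unused.
#' @export
autoplot.running_stats <- function(object, ...) {
  vars <- series_vars(object)
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(vars),
                              names_to = "variable",
                              values_to = "autocorrelation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$autocorrelation,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (window median)", y = "running autocorrelation") +
    ggplot2::theme_minimal()
}

#' @describeIn kcp_ar Running autocorrelations with the detected change
#'   points as dashed vertical lines.
#' @param object A `kcp_ar` object.
#' @export
autoplot.kcp_ar <- function(object, ...) {
  p <- autoplot.running_stats(object$running)
  if (length(object$change_points)) {
    p <- p + ggplot2::geom_vline(xintercept = object$change_points,
                                 linetype = "dashed")
  }
  p + ggplot2::labs(
    title = sprintf("KCP-AR: K = %d (p = %.3g)", object$selected_k,
                    object$p_value))
}

#' @describeIn fit_rsar Posterior regime probabilities over time with the
#'   hard assignments along the top.
#' @param object An `rsar` object.
#' @export
autoplot.rsar <- function(object, ...) {
  probs <- tidyr::pivot_longer(object$posterior,
                               dplyr::starts_with("p_regime"),
                               names_to = "regime", values_to = "probability",
                               names_prefix = "p_regime")
  ggplot2::ggplot(probs, ggplot2::aes(x = .data$t, y = .data$probability,
                                      fill = .data$regime)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "time", y = "posterior probability", fill = "regime",
                  title = sprintf("Regime-switching AR(1), R = %d",
                                  object$R)) +
    ggplot2::theme_minimal()
}

#' @describeIn select_regimes AIC and BIC against the number of regimes.
#' @param object An `rsar_selection` object.
#' @export
autoplot.rsar_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("aic", "bic"),
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$regimes, y = .data$value,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$table$regimes) +
    ggplot2::labs(x = "number of regimes", y = "information criterion") +
    ggplot2::theme_minimal()
}
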