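#' Plot estimated against true first coalescent times
#'
#' Log10 scatter of estimates against genealogical truth with the identity
#' line, optionally overlaying the idealized frequency-based comparator
#' (every variant of a frequency class plotted at its class mean).
#'
#' @param pairs paired tibble with `tc` (truth) and `t_c` (estimate), e.g.
#'   the `pairs` attribute of [evaluate_estimates()].
#' @param comparator overlay the frequency-based comparator values.
#' @return A ggplot.
#' @export
plot_truth_scatter <- function(pairs, comparator = FALSE) {
  pairs <- dplyr::filter(pairs, .data$t_c > 0, .data$tc > 0)
  p <- ggplot2::ggplot(pairs,
                       ggplot2::aes(x = log10(.data$tc), y = log10(.data$t_c))) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40",
                         linetype = 2) +
    ggplot2::labs(x = "true log10 t_c (generations)",
                  y = "estimated log10 t_c (generations)")
  if (comparator) {
    cmp <- frequency_comparator(dplyr::select(pairs, "k", "tc"))
    over <- dplyr::left_join(pairs, cmp[, c("k", "tau")], by = "k")
    p <- p + ggplot2::geom_point(data = over,
                                 ggplot2::aes(y = .data$tau),
                                 colour = "red", alpha = 0.2, size = 0.4)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.tc_performance <- function(object, ...) {
  tb <- tidy(object)
  long <- tidyr::pivot_longer(tb, c("rmse", "bias", "r"),
                              names_to = "metric", values_to = "value")
  long$stratum <- factor(long$stratum, levels = tb$stratum)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "t_c recovery (log10 scale metrics)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.tc_estimate <- function(object, n_grid = 200, ...) {
  b <- log10(object$bounds)
  grid <- seq(b[1], b[2], length.out = n_grid)
  ll <- vapply(grid, function(l) {
    composite_loglik(object$observations, 10^l, object$params)
  }, numeric(1))
  df <- tibble::tibble(log10_tc = grid, loglik = ll)
  ggplot2::ggplot(df, ggplot2::aes(.data$log10_tc, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$t_c), colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "log10 t_c (generations)",
                  y = "composite log-likelihood")
}

#' Plot singleton phasing accuracy against tract-length ratio
#'
#' @param accuracy tibble from [phasing_accuracy_by_ratio()].
#' @return A ggplot.
#' @export
plot_phasing_accuracy <- function(accuracy) {
  ggplot2::ggplot(accuracy,
                  ggplot2::aes(x = log10(.data$ratio_mid),
                               y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "log10 tract-length ratio (longer/shorter)",
                  y = "phasing accuracy")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
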