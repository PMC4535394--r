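#' Plot a simulation summary
#'
#' Faceted comparison of the two methods across true response rates: mean
#' confidence-interval width among stage-2 trials, coverage (with the
#' nominal level marked), rejection rate, and absolute bias of the point
#' estimate.
#'
#' @param object A [run_study()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simon_sim_summary
#' @export
autoplot.simon_sim_summary <- function(object, ...) {
  cfg <- attr(object, "config")
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object),
    cols = c("width", "coverage_pct", "power_pct", "abs_bias"),
    names_to = "quantity", values_to = "value")
  long$quantity <- factor(
    long$quantity,
    levels = c("width", "coverage_pct", "power_pct", "abs_bias"),
    labels = c("Mean CI width (stage-2 trials)", "Coverage (%)",
               "Rejection rate (%)", "Absolute bias"))
  ref <- data.frame(
    quantity = factor("Coverage (%)",
                      levels = levels(long$quantity)),
    y = 100 * (if (is.null(cfg)) 0.90 else cfg$level))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pi_true, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(quantity ~ design_id, scales = "free_y",
                        labeller = ggplot2::labeller(
                          design_id = function(i) paste("Design", i))) +
    ggplot2::labs(x = "True response rate", y = NULL, colour = "Method") +
    ggplot2::theme_bw()
}

#' Plot p-value functions for one observed trial
#'
#' Draws the likelihood-ratio mid-p value and (where defined) the
#' Koyama-Chen p-value function across null response rates, with the
#' acceptance threshold `1 - level`. The rates at which each curve crosses
#' the threshold are the confidence limits of the corresponding method.
#'
#' @param outcome A [trial_outcome()].
#' @param level Confidence level whose threshold is drawn.
#' @param n Number of grid points.
#' @return A ggplot object.
#' @export
plot_pvalue_function <- function(outcome, level = 0.90, n = 201) {
  stopifnot(inherits(outcome, "trial_outcome"))
  grid <- seq(0.002, 0.998, length.out = n)
  curves <- list(
    tibble::tibble(pi0 = grid, method = "LR mid-p",
                   p = vapply(grid, function(p) lr_pvalue(outcome, p),
                              numeric(1))))
  kc_ok <- outcome$m == 2L && outcome$x1 <= outcome$design$rt
  if (kc_ok) {
    curves$kc <- tibble::tibble(pi0 = grid, method = "KC",
                                p = kc_pvalue_function(outcome, grid))
  }
  df <- dplyr::bind_rows(curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi0, y = .data$p,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 - level, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Null response rate", y = "p-value", colour = NULL) +
    ggplot2::theme_bw()
}
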