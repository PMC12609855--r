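#' Calibration plot
#'
#' Observed event proportion against predicted risk with the identity
#' line; points carry their binomial CIs (bin mode) or the loess band.
#'
#' @param curve A [calibration_curve()] or a `validation_report`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(curve) {
  if (inherits(curve, "validation_report")) curve <- curve$curve
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0, colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, NA), ylim = c(0, NA)) +
    ggplot2::labs(x = "Predicted probability",
                  y = "Observed proportion",
                  title = "Calibration plot") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' Non-parametric (empirical) ROC curve.
#'
#' @param y Binary outcome vector.
#' @param p Predicted risks.
#' @return A ggplot object.
#' @export
plot_roc <- function(y, p) {
  check_two_classes(y)
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  pts <- vapply(thr, function(t) {
    pos <- p >= t
    c(fpr = sum(pos & y == 0) / sum(y == 0),
      tpr = sum(pos & y == 1) / sum(y == 1))
  }, numeric(2))
  df <- data.frame(fpr = pts["fpr", ], tpr = pts["tpr", ])
  a <- auroc(y, p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AuROC %.2f; 95%% CI %.2f, %.2f)",
                                  a$value, a$ci_low, a$ci_high)) +
    ggplot2::theme_minimal()
}

#' Decision-curve plots
#'
#' Net benefit of the model against the screen-all and screen-none
#' strategies, or the net reduction in investigations per 100
#' participants, across threshold probabilities.
#'
#' @param dc A [decision_curve()].
#' @param what `"net_benefit"` or `"net_reduction"`.
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(dc, what = c("net_benefit",
                                             "net_reduction")) {
  what <- match.arg(what)
  df <- as.data.frame(dc)
  if (what == "net_benefit") {
    long <- rbind(
      data.frame(threshold = df$threshold, value = df$nb_model,
                 strategy = "model"),
      data.frame(threshold = df$threshold, value = df$nb_all,
                 strategy = "screen all"),
      data.frame(threshold = df$threshold, value = df$nb_none,
                 strategy = "screen none")
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                       y = .data$value,
                                       colour = .data$strategy)) +
      ggplot2::geom_line() +
      ggplot2::coord_cartesian(
        ylim = c(-0.05, max(0.05, max(long$value)))) +
      ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                    colour = NULL, title = "Decision curve analysis") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                     y = .data$avoided_per100)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                          colour = "grey50") +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "Threshold probability",
                    y = "Net investigations avoided per 100",
                    title = "Net reduction in investigations") +
      ggplot2::theme_minimal()
  }
}
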