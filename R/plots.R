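#' Plot a summary ROC curve
#'
#' Curve in ROC space with the pooled summary point; study points can be
#' overlaid (sized by sample size) by passing the fit.
#'
#' @param object An `sroc` object from [sroc_curve()].
#' @param fit Optional `bivariate_fit` whose per-study points to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sroc
#' @export
autoplot.sroc <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "Sensitivity",
                  title = if (object$degenerate) "Summary point (degenerate sROC)"
                          else sprintf("Summary ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    pts <- dplyr::mutate(fit$data,
                         fpr = .data$fp / (.data$fp + .data$tn),
                         sens = .data$tp / (.data$tp + .data$fn),
                         size = .data$tp + .data$fp + .data$fn + .data$tn)
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(.data$fpr, .data$sens,
                                              size = .data$size),
                                 alpha = 0.4, show.legend = FALSE)
  }
  if (!object$degenerate) {
    p <- p + ggplot2::geom_line(data = object$curve,
                                ggplot2::aes(.data$fpr, .data$sensitivity),
                                linewidth = 0.8, colour = "#2c6fbb")
  }
  p + ggplot2::geom_point(data = object$summary_point,
                          ggplot2::aes(.data$fpr, .data$sensitivity),
                          shape = 18, size = 4, colour = "#b2182b")
}

#' Deeks' funnel plot
#'
#' Log diagnostic odds ratio against 1/sqrt(effective sample size), with
#' the fitted asymmetry regression line; the y axis is reversed so large
#' studies sit at the top, as the funnel is conventionally drawn.
#'
#' @param object A `deeks_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deeks_test
#' @export
autoplot.deeks_test <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$lndor, .data$inv_sqrt_ess)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1 / object$slope,
                         intercept = -object$intercept / object$slope) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log diagnostic odds ratio",
                  y = "1 / sqrt(effective sample size)",
                  title = sprintf("Deeks' funnel plot (slope %.2f, p = %.3f)",
                                  object$slope, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Fagan nomogram
#'
#' Draws the two-axis rendition of Bayes' theorem in odds form: a line
#' from the pretest probability through the likelihood ratio to the
#' posttest probability.
#'
#' @param object A `fagan_result` from [fagan_posttest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fagan_result
#' @export
autoplot.fagan_result <- function(object, ...) {
  seg <- tibble(x = 0, xend = 1,
                y = qlogis(object$pretest),
                yend = qlogis(object$posttest),
                label = sprintf("LR = %.3g", object$lr))
  ticks <- c(0.001, 0.01, 0.05, 0.2, 0.5, 0.8, 0.95, 0.99)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = -.data$y, yend = .data$yend,
                                       colour = .data$label)) +
    ggplot2::scale_y_continuous(
      breaks = -qlogis(ticks), labels = ticks,
      sec.axis = ggplot2::sec_axis(~ .x, breaks = qlogis(ticks),
                                   labels = ticks,
                                   name = "posttest probability"),
      name = "pretest probability (inverted)") +
    ggplot2::scale_x_continuous(breaks = NULL, name = NULL) +
    ggplot2::labs(colour = NULL, title = "Fagan nomogram") +
    ggplot2::theme_minimal()
}
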