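#' Plot a registration loss trace
#'
#' Objective value per iteration, coloured by scale.  The drop after each
#' scale transition is the signature of the coarse-to-fine schedule: each
#' refinement exposes detail the coarser resolution could not represent,
#' and the loss starts decreasing again.
#'
#' @param object a `registration_result`.
#' @param log_y log-scale the objective axis?
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.registration_result <- function(object, log_y = TRUE, ...) {
  tr <- object$loss_trace
  tr$step <- seq_len(nrow(tr))
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$objective,
                                        colour = factor(.data$scale))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration (all scales)", y = "objective (mm²)",
                  colour = "scale") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname autoplot.registration_result
#' @export
plot_loss_trace <- function(object, log_y = TRUE) autoplot(object, log_y = log_y)

#' Plot the variance spectrum of an SSM
#'
#' Per-mode variance and cumulative explained variance.
#'
#' @param object an `ssm_model`.
#' @param n_modes how many leading modes to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_model <- function(object, n_modes = 15L, ...) {
  td <- tidy(object)
  td <- td[seq_len(min(n_modes, nrow(td))), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$variance_fraction), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::labs(x = "mode", y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Plot intrinsic SSM metrics
#'
#' Generalisation (mm^2), specificity (mm) and compactness (fraction)
#' against the number of modes, one panel per metric.
#'
#' @param object an `ssm_metrics` tibble from [evaluate_ssm()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_metrics <- function(object, ...) {
  df <- rbind(
    data.frame(K = object$K, value = object$G_mm2,
               metric = "generalisation G(K) [mm²]", region = object$region),
    data.frame(K = object$K, value = object$S_mm,
               metric = "specificity S(K) [mm]", region = object$region),
    data.frame(K = object$K, value = object$C_fraction,
               metric = "compactness C(K)", region = object$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$value,
                                   colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of modes K", y = NULL) +
    ggplot2::theme_minimal()
}
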