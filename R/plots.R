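#' Plot an entropy track
#'
#' Relative entropy along the sequence; positions below zero are more
#' conserved than the protein average (and hence more disease-prone when
#' mutated).
#'
#' @param object An `entropy_track` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$RS)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue position", y = "Relative entropy RS (nats)") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `entvar_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entvar_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Plot a saturation scan as a substitution heat map
#'
#' @param object A `saturation_scan`.
#' @param cutoff Optional cutoff drawn into the colour scale midpoint.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_scan <- function(object, cutoff = 0.45, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mutant_aa,
                                       fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = cutoff, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "Residue position", y = "Mutant residue",
                  fill = "Score") +
    ggplot2::theme_minimal()
}

#' Plot a hot-spot threshold curve
#'
#' @param object A `threshold_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$threshold, y = .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hot-spot fraction threshold", y = "Mean attribute") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
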