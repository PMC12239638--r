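#' Plot a Procrustes alignment
#'
#' Aligned configurations as grey points with the consensus shape overlaid.
#'
#' @param object A `gpa_alignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gpa_alignment <- function(object, ...) {
  ggplot2::ggplot(object$aligned, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = object$consensus, colour = "black", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes alignment",
                  subtitle = paste(nrow(object$meta), "configurations"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot genotype shape-displacement vectors on the consensus
#'
#' Arrows from each consensus landmark to its displaced position under an
#' allele substitution (magnified for display, as is conventional).
#'
#' @param alignment A `gpa_alignment` providing the consensus.
#' @param vectors Output of [shape_effect_vectors()].
#' @return A ggplot.
#' @export
plot_shape_effects <- function(alignment, vectors) {
  cons <- dplyr::inner_join(alignment$consensus, vectors, by = "landmark")
  ggplot2::ggplot(cons, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + .data$dx, yend = .data$y + .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "red3"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Shape displacement per allele substitution",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot animal-model fixed effects
#'
#' Coefficients with approximate 95% intervals (estimate +/- 1.96 se),
#' intercept omitted.
#'
#' @param object An `animal_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.animal_model <- function(object, ...) {
  dat <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                                          xmax = .data$estimate + 1.96 * .data$se)) +
    ggplot2::labs(title = paste("Fixed effects:", object$trait %||% "trait"),
                  x = "estimate (cm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a variance decomposition
#'
#' Medians with 95% simulation intervals, one panel per statistic.
#'
#' @param object A `variance_decomposition` (rows may span several traits).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$median, y = .data$trait)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~statistic, scales = "free_x") +
    ggplot2::labs(x = "median (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
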