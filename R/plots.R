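#' Plot a set of IRRA spectra
#'
#' One panel per polarization, colour per angle of incidence.
#'
#' @param x A spectra tibble.
#' @return A ggplot object.
#' @export
plot_spectra <- function(x) {
  x <- validate_spectra(x)
  ggplot2::ggplot(x, ggplot2::aes(.data$wavenumber, .data$ra,
                                  colour = factor(.data$angle_deg))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~polarization, labeller = ggplot2::label_both) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "RA",
                  colour = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.orientation_fit <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(.data$gamma, .data$ssd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$gamma_best, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = expression(gamma ~ (degrees)), y = "SSD") +
    ggplot2::theme_minimal()
  if (!is.null(object$ci_95) && !isTRUE(object$unconstrained)) {
    p <- p + ggplot2::annotate("rect", xmin = object$ci_95[1],
                               xmax = object$ci_95[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "blue")
  }
  p
}

#' @export
autoplot.insertion_analysis <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$pi0, .data$delta_pi)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = expression(pi[0] ~ (mN ~ m^-1)),
                  y = expression(Delta * pi ~ (mN ~ m^-1))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectra_pca <- function(object, ...) {
  sc <- object$scores
  f <- object$explained_variance_fraction
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * f[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * f[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qcmd_trace <- function(object, overtone = 3, ...) {
  d <- object[object$overtone == overtone, ]
  ev <- qcmd_events(object)
  long <- tidyr::pivot_longer(as_tibble(d), c("delta_f", "delta_d"),
                              names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = ev, ggplot2::aes(xintercept = .data$time_min),
                        linetype = 3, colour = "grey50") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
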