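#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an aggregated isotope distribution
#'
#' Stick plot of q_j against the center mass, annotated with the most
#' abundant variant.
#'
#' @param object An `iso_aggregated` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iso_aggregated <- function(object, ...) {
  jstar <- most_abundant_variant(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center_mass, y = .data$q)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$center_mass, yend = 0)) +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$j == jstar),
      colour = "red", size = 2) +
    ggplot2::labs(
      x = "center mass (Da)", y = "probability",
      title = attr(object, "formula"),
      subtitle = paste0("most abundant variant: j = ", jstar)) +
    ggplot2::theme_minimal()
}

#' Plot a fine-structure cluster
#'
#' Stick plot of the enumerated fine peaks of one aggregated variant.
#'
#' @param object An `iso_fine` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iso_fine <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mass, y = .data$probability)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mass, yend = 0)) +
    ggplot2::labs(
      x = "mass (Da)", y = "probability",
      title = paste0(attr(object, "formula"), ", j = ", attr(object, "j")),
      subtitle = paste0(nrow(object), " fine peaks, captured ",
                        signif(attr(object, "captured"), 4),
                        " of q_j = ", signif(attr(object, "q_j"), 4))) +
    ggplot2::theme_minimal()
}

#' Plot a rendered profile spectrum
#'
#' @param object An `iso_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iso_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mass, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mass (Da)", y = "intensity (1/Da)") +
    ggplot2::theme_minimal()
}

#' Plot a binned distribution
#'
#' @param object An `iso_binned` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iso_binned <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                       y = .data$fraction)) +
    ggplot2::geom_col(width = object$upper[1] - object$lower[1]) +
    ggplot2::labs(x = "mass (Da)", y = "fraction") +
    ggplot2::theme_minimal()
}
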