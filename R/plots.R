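# ggplot2 quick looks.

#' Plot a simulated trajectory
#'
#' Compartments against time, with the detected peak and inflection marked
#' when present.
#'
#' @param object An `epi_trajectory`.
#' @param mark_features Mark `D` (dashed) and `L` (dotted) vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epi_trajectory
#' @export
autoplot.epi_trajectory <- function(object, mark_features = TRUE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "compartment", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                          colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "population",
                  colour = NULL)
  if (mark_features) {
    ft <- transient_features(object)
    if (ft$found_D)
      p <- p + ggplot2::geom_vline(xintercept = ft$D, linetype = "dashed")
    if (ft$found_L)
      p <- p + ggplot2::geom_vline(xintercept = ft$L, linetype = "dotted")
  }
  p
}

#' Plot an analytic infection curve
#'
#' @param object An `epi_curve`.
#' @param n Number of sample points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epi_curve
#' @export
autoplot.epi_curve <- function(object, n = 1001L, ...) {
  df <- sample_curve(object, n)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$I)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "infectious")
}

#' Compare a curve with its matched log-normal references
#'
#' Overlays the normalized curve with the unit-mass log-normal densities at
#' the entropy-matching and variance-matching widths from
#' [match_reference()].
#'
#' @param x An `epi_curve` or `epi_trajectory`.
#' @param match Optionally a precomputed `epi_match`.
#' @param n Number of sample points.
#' @return A ggplot object.
#' @export
plot_reference_match <- function(x, match = NULL, n = 1001L) {
  m <- match %||% match_reference(x)
  cv <- resolve_curve(x)
  tt <- seq(cv$support[1L], cv$support[2L], length.out = n)
  mass <- quad_t(cv$I, cv$support[1L], cv$support[2L])$value
  df <- dplyr::bind_rows(
    tibble::tibble(t = tt, density = cv$I(tt) / mass, curve = "normalized infection"),
    tibble::tibble(t = tt, density = lognormal_pdf(m$D, m$sigma_rm, tt),
                   curve = "entropy-matched reference"),
    tibble::tibble(t = tt, density = lognormal_pdf(m$D, m$sigma_rmv, tt),
                   curve = "variance-matched reference"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$density,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "density", colour = NULL)
}

#' @importFrom rlang .data
NULL
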