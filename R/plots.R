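# ggplot2 autoplot methods for the main result types.

#' Plot per-residue contact probabilities
#'
#' @param object a `contact_summary`.
#' @param threshold optional horizontal guide (e.g. 0.5).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.contact_summary <- function(object, threshold = 0.5, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$resnum, y = .data$p_contact)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = "residue number", y = "contact probability") +
    ggplot2::ylim(0, 1)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a 2D radial distribution function
#'
#' @param object an `rdf_profile`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.rdf_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "r (Å)",
                  y = sprintf("g2D(r), %s", attr(object, "species")))
}

#' Plot a residence-time histogram
#'
#' @param object a `residence_summary`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.residence_summary <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_left_ps + .data$bin_right_ps) / 2e3,
                                  y = .data$count)) +
    ggplot2::geom_col(width = (h$bin_right_ps[1] - h$bin_left_ps[1]) / 1e3,
                      fill = "darkorange") +
    ggplot2::labs(x = "t_res (ns)", y = "events")
}

#' Plot a helix-tilt time series
#'
#' @param object an `orientation_series`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.orientation_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_ps / 1e3, y = .data$theta_deg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "tilt from membrane normal (deg)") +
    ggplot2::ylim(0, 90)
}
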