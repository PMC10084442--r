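#' Map MLGs in space
#'
#' Fruitbody map in the style of a genet atlas: ramets of repeated MLGs
#' share a colour; singleton MLGs are drawn as crosses.
#'
#' @param data Output of [assign_mlgs()] (positioned rows only are
#'   drawn).
#' @return A ggplot.
#' @export
plot_mlg_map <- function(data) {
  stopifnot("mlg_id" %in% names(data))
  d <- data[!is.na(data$x) & !is.na(data$y), , drop = FALSE]
  n_by <- table(d$mlg_id)
  d$kind <- ifelse(n_by[d$mlg_id] > 1, "repeated MLG", "singleton")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(
      data = d[d$kind == "repeated MLG", ],
      ggplot2::aes(colour = .data$mlg_id), size = 2) +
    ggplot2::geom_point(
      data = d[d$kind == "singleton", ], shape = 4, size = 2,
      colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "MLG") +
    ggplot2::theme_minimal()
}

#' @describeIn spatial_autocorrelation Correlogram: per-class mean
#'   kinship against mean pair distance, with significant classes
#'   filled.
#' @param object,... Autoplot arguments.
#' @export
autoplot.clonering_sgs <- function(object, ...) {
  d <- object$by_class
  d$significant <- d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_dist, .data$mean_fij)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance (m)", y = expression(mean~F[ij]),
                  fill = "p < 0.05",
                  subtitle = sprintf("b = %.4g,  Sp = %.3f", object$b, object$Sp)) +
    ggplot2::theme_minimal()
}

#' @describeIn ring_growth_rate Mean annual ring radius with the fitted
#'   growth line.
#' @param object,... Autoplot arguments.
#' @export
autoplot.clonering_ring <- function(object, ...) {
  ggplot2::ggplot(object$by_year, ggplot2::aes(.data$year, .data$mean_radius)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "year", y = "mean radius (m)", size = "fruitbodies",
                  subtitle = sprintf("growth %.2f m/yr", object$rate)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_standard_curve Standard-curve points and fit.
#' @param object,... Autoplot arguments.
#' @export
autoplot.clonering_stdcurve <- function(object, ...) {
  d <- object$points
  ggplot2::ggplot(d, ggplot2::aes(log10(.data$copies), .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "log10 copies / reaction", y = "Cq",
                  subtitle = sprintf("slope %.3f, eff. %.0f%%, R² %.4f",
                                     object$slope, 100 * object$efficiency,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_fairy_ring Map of simulated fruitbodies by year.
#' @param object,... Autoplot arguments.
#' @export
autoplot.clonering_sim <- function(object, ...) {
  ggplot2::ggplot(object$gleba,
                  ggplot2::aes(.data$x, .data$y,
                               colour = factor(.data$year))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "year") +
    ggplot2::theme_minimal()
}
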