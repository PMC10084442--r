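#' Radial growth rate of a fairy ring
#'
#' A radially expanding genet fruits on an annulus whose radius grows
#' roughly linearly with time. Given fruitbody positions over two or more
#' seasons, the estimator computes each year's mean distance to the ring
#' centre and fits mean radius on calendar year by least squares; the
#' slope is the outward growth rate in metres per year. The centre
#' defaults to a least-squares circle fit over all fruitbodies (centroid
#' fallback below 6 points); supplying the centre makes the estimate
#' translation-invariant by construction.
#'
#' @param data Tibble with `x`, `y`, `year` (rows without coordinates are
#'   dropped).
#' @param center Optional numeric `c(x, y)` ring centre in metres.
#' @return A list of class `clonering_ring`: `rate` (m/yr), `center`,
#'   `by_year` tibble (`year`, `n`, `mean_radius`), and the `lm` fit.
#' @export
ring_growth_rate <- function(data, center = NULL) {
  ok <- !is.na(data$x) & !is.na(data$y)
  data <- data[ok, , drop = FALSE]
  if (dplyr::n_distinct(data$year) < 2) {
    abort("Growth rate needs fruitbodies from at least 2 distinct years.")
  }
  if (is.null(center)) center <- fit_circle_center(data$x, data$y)
  r <- sqrt((data$x - center[1])^2 + (data$y - center[2])^2)
  by_year <- tibble::tibble(year = data$year, radius = r) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n = dplyr::n(), mean_radius = mean(.data$radius),
                     .groups = "drop") |>
    dplyr::arrange(.data$year)
  fit <- lm(mean_radius ~ year, data = by_year)
  structure(list(rate = unname(coef(fit)[2]), center = center,
                 by_year = by_year, fit = fit),
            class = "clonering_ring")
}

#' @export
print.clonering_ring <- function(x, ...) {
  cat(sprintf("Fairy-ring growth: %.3f m/yr (centre %.2f, %.2f; %d years)\n",
              x$rate, x$center[1], x$center[2], nrow(x$by_year)))
  invisible(x)
}

#' @export
tidy.clonering_ring <- function(x, ...) x$by_year

#' @export
glance.clonering_ring <- function(x, ...) {
  tibble::tibble(rate = x$rate, center_x = x$center[1], center_y = x$center[2],
                 n_years = nrow(x$by_year),
                 r_squared = summary(x$fit)$r.squared)
}

# Least-squares circle (Coope/Kasa linearisation); centroid below 6 points.
fit_circle_center <- function(x, y) {
  if (length(x) < 6) return(c(mean(x), mean(y)))
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  c(sol[1], sol[2])
}

#' Age of a fairy-ring genet from its radius
#'
#' Assuming constant radial growth from a point origin, the mycelium's
#' age is the ring radius divided by the annual growth rate, reported in
#' whole years (floor).
#'
#' @param radius Ring radius in metres (> 0).
#' @param rate Radial growth rate in metres per year (> 0).
#' @return Integer age in whole years.
#' @export
#' @examples
#' ring_age(4, 0.30)  # 13
ring_age <- function(radius, rate) {
  if (any(radius <= 0) || any(rate <= 0)) {
    abort("Radius and growth rate must be positive.")
  }
  as.integer(floor(radius / rate))
}
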