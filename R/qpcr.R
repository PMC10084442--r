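#' Fit a qPCR standard curve
#'
#' Least-squares fit of quantification cycle on log10 template copy
#' number, `Cq ~ log10(copies)`. Amplification efficiency is
#' `10^(-1/slope) - 1` (1 = perfect doubling per cycle, slope -3.3219).
#' The curve is flagged reliable only when `R^2 >= 0.997` and efficiency
#' lies within 90%-110%.
#'
#' @param points Tibble/data frame with columns `copies` (template copies
#'   per reaction) and `cq`; at least 3 dilution points.
#' @return A list of class `clonering_stdcurve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency` (fraction), `reliable`, `monotone`,
#'   `points`.
#' @export
#' @examples
#' pts <- data.frame(copies = 10^(2:7), cq = 38 - 3.3219 * (2:7))
#' fit_standard_curve(pts)
fit_standard_curve <- function(points) {
  stopifnot(all(c("copies", "cq") %in% names(points)))
  if (nrow(points) < 3) abort("Standard curve needs at least 3 dilution points.")
  lc <- log10(points$copies)
  fit <- lm(points$cq ~ lc)
  slope <- unname(coef(fit)[2])
  eff <- 10^(-1 / slope) - 1
  r2 <- 1 - sum(fit$residuals^2) / sum((points$cq - mean(points$cq))^2)
  ord <- order(lc)
  monotone <- all(diff(points$cq[ord]) < 0)
  if (!monotone) warn("Cq values are not monotone decreasing in copy number.")
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2, efficiency = eff,
                 reliable = r2 >= 0.997 && eff >= 0.90 && eff <= 1.10,
                 monotone = monotone,
                 points = tibble::as_tibble(points)),
            class = "clonering_stdcurve")
}

#' @export
print.clonering_stdcurve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, R^2 %.4f, efficiency %.1f%% [%s]\n",
              x$slope, x$r_squared, 100 * x$efficiency,
              if (x$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' @export
glance.clonering_stdcurve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 reliable = x$reliable)
}

#' Absolute quantification of ITS copies from Cq triplicates
#'
#' Inverts the standard curve per replicate, averages the
#' back-transformed copy numbers, and scales reaction copies to copies
#' per gram of dried soil:
#' `copies/g = copies/reaction * dilution * (elution_ul / template_ul) / soil_g`.
#' Defaults encode the extraction used for the transect survey: 250 mg
#' dried soil, 100 ul eluate, 5 ul template per reaction at 1:10
#' dilution. Triplicate quality is the coefficient of variation
#' `(sd/mean) * 100` on the back-transformed copy numbers, flagged above
#' `cv_max`.
#'
#' @param curve A reliable [fit_standard_curve()] result (pass
#'   `force = TRUE` to quantify on an unreliable curve).
#' @param cq Numeric vector of replicate Cq values (conventionally 3).
#' @param dilution Template dilution factor (default 10, i.e. 1:10).
#' @param soil_g Grams of dried soil extracted (default 0.25).
#' @param elution_ul Elution volume in ul (default 100).
#' @param template_ul Template volume per reaction in ul (default 5).
#' @param cv_max CV percentage above which the triplicate is flagged
#'   (default 15).
#' @param force Quantify even on an unreliable curve (default `FALSE`).
#' @return A one-row tibble: `copies_reaction`, `copies_per_g`,
#'   `cv_percent`, `cv_flag`, `mycelium_ug_per_g`.
#' @export
quantify_soil <- function(curve, cq, dilution = 10, soil_g = 0.25,
                          elution_ul = 100, template_ul = 5,
                          cv_max = 15, force = FALSE) {
  stopifnot(inherits(curve, "clonering_stdcurve"))
  if (!curve$reliable && !force) {
    abort("Standard curve is unreliable; pass force = TRUE to quantify anyway.")
  }
  copies <- 10^((cq - curve$intercept) / curve$slope)
  m <- mean(copies)
  cv <- if (length(copies) > 1 && m > 0) 100 * sd(copies) / m else 0
  per_g <- m * dilution * (elution_ul / template_ul) / soil_g
  tibble::tibble(copies_reaction = m,
                 copies_per_g = per_g,
                 cv_percent = cv,
                 cv_flag = cv > cv_max,
                 mycelium_ug_per_g = copies_to_mass(per_g))
}

#' Convert ITS copies per gram soil to mycelium mass
#'
#' Uses the calibration 1 g of dried soil mycelium = 9.37e10 ITS copies;
#' the result is expressed in micrograms of dried mycelium per gram of
#' dried soil.
#'
#' @param copies_per_g ITS copies per gram dried soil (>= 0).
#' @param copies_per_g_mycelium Calibration constant (default 9.37e10).
#' @return Micrograms of dried mycelium per gram of dried soil.
#' @export
#' @examples
#' copies_to_mass(9.37e10)  # 1e6 ug/g, i.e. 1 g mycelium per g soil
copies_to_mass <- function(copies_per_g, copies_per_g_mycelium = 9.37e10) {
  if (any(copies_per_g < 0)) abort("Copy numbers must be non-negative.")
  copies_per_g / copies_per_g_mycelium * 1e6
}

#' Mating-type co-occurrence in soil samples
#'
#' Among MAT-PCR-positive soil samples, tallies how many carry one versus
#' both idiomorphs (overall and per site when a `site` column is
#' present), and locates contiguous single-idiomorph patches: maximal
#' runs of consecutive positions along a transect where only one, and
#' always the same, idiomorph is detected.
#'
#' @param data Tibble with logical `mat11`, `mat12` columns; optional
#'   `site`, and `transect` + `position` for patch detection (positions
#'   are ordered within transect).
#' @return A list of class `clonering_matco`: `summary` (one row overall
#'   and per site: `n_positive`, `n_both`, `percent_both`), `patches`
#'   (one row per single-MAT run: `transect`, `mat`, `start`, `end`,
#'   `length`).
#' @export
mat_cooccurrence <- function(data) {
  pos <- data[data$mat11 | data$mat12, , drop = FALSE]
  summarise_grp <- function(d, label) {
    tibble::tibble(group = label,
                   n_positive = nrow(d),
                   n_both = sum(d$mat11 & d$mat12),
                   percent_both = if (nrow(d)) 100 * sum(d$mat11 & d$mat12) / nrow(d)
                                  else NA_real_)
  }
  summary <- summarise_grp(pos, "pooled")
  if ("site" %in% names(data) && nrow(pos)) {
    per_site <- dplyr::bind_rows(lapply(split(pos, pos$site), function(d)
      summarise_grp(d, d$site[1])))
    summary <- dplyr::bind_rows(summary, per_site)
  }
  patches <- tibble::tibble(transect = character(), mat = character(),
                            start = numeric(), end = numeric(), length = integer())
  if (all(c("transect", "position") %in% names(data)) && nrow(data)) {
    for (tr in unique(data$transect)) {
      d <- data[data$transect == tr, , drop = FALSE]
      d <- d[order(d$position), , drop = FALSE]
      state <- ifelse(d$mat11 & !d$mat12, "MAT1-1",
                      ifelse(d$mat12 & !d$mat11, "MAT1-2", "none"))
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values != "none"
      if (any(keep)) {
        patches <- dplyr::bind_rows(patches, tibble::tibble(
          transect = as.character(tr), mat = r$values[keep],
          start = d$position[starts[keep]], end = d$position[ends[keep]],
          length = r$lengths[keep]))
      }
    }
  }
  structure(list(summary = summary, patches = patches),
            class = "clonering_matco")
}

#' @export
print.clonering_matco <- function(x, ...) {
  cat("Mating-type co-occurrence in MAT-positive soil samples\n")
  print(x$summary, ...)
  if (nrow(x$patches)) {
    cat("Single-idiomorph patches:\n")
    print(x$patches, ...)
  }
  invisible(x)
}
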