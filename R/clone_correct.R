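#' Clone-correct a genotyped dataset
#'
#' Collapses each significant MLG (a true clone) to a single representative
#' placed at the arithmetic-mean centroid of its positioned ramets, so a
#' genet sampled many times is counted once in downstream population
#' statistics. Ramets of repeated MLGs whose P_sex is non-significant are
#' retained as distinct genotypes (repetition could have arisen by chance),
#' as are singletons.
#'
#' @param data Output of [assign_mlgs()].
#' @param significance Output of [p_sex_significance()] on the same data,
#'   or `NULL` if `data` already carries a `significant` column. MLGs with
#'   `significant = NA` (singletons) are retained as-is.
#' @return A genotype tibble; representatives of collapsed clones carry
#'   their `mlg_id` as `sample_id` and the centroid as position (`NA` when
#'   no ramet was positioned — such genets drop out of spatial statistics
#'   only).
#' @export
clone_correct <- function(data, significance = NULL) {
  stopifnot("mlg_id" %in% names(data))
  if (!is.null(significance)) {
    data <- dplyr::left_join(
      data, significance[, c("mlg_id", "significant")], by = "mlg_id")
  }
  if (!"significant" %in% names(data)) {
    abort("Provide `significance` or a `significant` column.")
  }
  sig <- !is.na(data$significant) & data$significant
  keep <- data[!sig, , drop = FALSE]

  reps <- data[sig, , drop = FALSE] |>
    dplyr::group_by(.data$mlg_id) |>
    dplyr::mutate(
      .pos = !is.na(.data$x) & !is.na(.data$y),
      .cx = mean(.data$x[.data$.pos]),
      .cy = mean(.data$y[.data$.pos])) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(sample_id = .data$mlg_id,
                  x = ifelse(is.nan(.data$.cx), NA_real_, .data$.cx),
                  y = ifelse(is.nan(.data$.cy), NA_real_, .data$.cy)) |>
    dplyr::select(-".pos", -".cx", -".cy")

  out <- dplyr::bind_rows(keep, reps)
  out[order(match(out$mlg_id, unique(data$mlg_id))), , drop = FALSE]
}
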