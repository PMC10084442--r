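#' Assign multilocus genotypes (MLGs)
#'
#' Partitions resolved records into exact-match groups over the full SSR
#' profile plus the mating-type idiomorph: two haploid samples belong to
#' the same MLG only if they agree at every scored locus including MAT.
#' MLG identifiers are assigned deterministically in first-seen row order.
#'
#' @param data A genotype tibble (unresolved rows are dropped with a
#'   warning).
#' @param loci Optional SSR locus subset.
#' @return The resolved rows with an `mlg_id` column (`"MLG001"`, ...)
#'   prepended after `sample_id`.
#' @export
#' @examples
#' gt <- simulate_fairy_ring(ring_sim_config(seed = 1))
#' head(assign_mlgs(gt$gleba))
assign_mlgs <- function(data, loci = NULL) {
  loci <- ssr_loci(data, loci)
  if ("resolved" %in% names(data) && !all(data$resolved)) {
    warn(paste0("Dropping ", sum(!data$resolved), " unresolved record(s)."))
    data <- data[data$resolved, , drop = FALSE]
  }
  if (!nrow(data)) abort("No resolved records.")
  key <- do.call(paste, c(data[, loci, drop = FALSE], list(data$mat), sep = "|"))
  idx <- match(key, unique(key))
  data$mlg_id <- sprintf("MLG%03d", idx)
  dplyr::relocate(data, "mlg_id", .after = "sample_id")
}

#' Summarise MLGs: ramets, centroid, subrange, roles, years
#'
#' One row per MLG with its ramet count, the arithmetic-mean centroid of
#' positioned ramets, the clonal subrange (largest pairwise distance
#' between ramets, 0 for singletons), the sex roles it was observed in
#' (maternal = gleba or ECM tissue, paternal = inferred from ascospores)
#' and the calendar years it spans.
#'
#' @param data Output of [assign_mlgs()].
#' @return A tibble with one row per MLG, ordered by `mlg_id`.
#' @export
mlg_summary <- function(data) {
  stopifnot("mlg_id" %in% names(data))
  data |>
    dplyr::group_by(.data$mlg_id) |>
    dplyr::summarise(
      n_ramets = dplyr::n(),
      centroid_x = mean(.data$x[!is.na(.data$x) & !is.na(.data$y)]),
      centroid_y = mean(.data$y[!is.na(.data$x) & !is.na(.data$y)]),
      subrange = clonal_subrange(.data$x, .data$y),
      maternal = any(.data$role %in% c("gleba", "ecm")),
      paternal = any(.data$role == "ascospore"),
      first_year = min(.data$year),
      last_year = max(.data$year),
      n_years = dplyr::n_distinct(.data$year),
      mat = .data$mat[1],
      .groups = "drop")
}

#' Clonal subrange: farthest distance between ramets of one MLG
#'
#' @param x,y Coordinates of the ramets (metres); `NA` positions are
#'   excluded.
#' @return Maximum pairwise Euclidean distance; 0 for a singleton (or when
#'   fewer than two ramets are positioned).
#' @export
#' @examples
#' clonal_subrange(c(0, 3, 0), c(0, 0, 4))  # 5
clonal_subrange <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  max(dist(cbind(x[ok], y[ok])))
}
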