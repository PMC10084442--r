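#' Locus panel definitions
#'
#' A panel describes the markers a genotype table is scored at: a set of
#' haploid SSR loci (integer fragment-size alleles) plus the single
#' mating-type locus of a heterothallic ascomycete, carrying one of the two
#' idiomorphs `MAT1-1` / `MAT1-2`.
#'
#' @param ssr Character vector of SSR locus names (unique).
#' @param mat Name of the mating-type column, or `NULL` for an SSR-only
#'   panel. The mating-type locus always has exactly the two idiomorphs.
#' @param domains Optional named list mapping SSR locus names to the vector
#'   of admissible allele labels (positive integers). Loci without an entry
#'   accept any positive integer allele.
#'
#' @return A tibble of class `clonering_panel` with columns `locus`, `kind`
#'   (`"SSR"` or `"MAT"`) and a list-column `domain`.
#' @export
#' @examples
#' locus_panel(ssr = c("aest07", "aest18"), mat = "mat")
locus_panel <- function(ssr, mat = "mat", domains = NULL) {
  if (anyDuplicated(ssr)) {
    abort("SSR locus names must be unique within a panel.")
  }
  if (!is.null(domains)) {
    bad <- setdiff(names(domains), ssr)
    if (length(bad)) {
      abort(paste0("Domain given for unknown locus: ", paste(bad, collapse = ", ")))
    }
    ok <- vapply(domains, function(d) all(d == as.integer(d)) && all(d > 0), logical(1))
    if (!all(ok)) abort("SSR allele domains must be positive integers.")
  }
  dom <- lapply(ssr, function(l) {
    if (!is.null(domains) && l %in% names(domains)) as.integer(domains[[l]]) else NULL
  })
  out <- tibble::tibble(
    locus = c(ssr, if (!is.null(mat)) mat),
    kind = c(rep("SSR", length(ssr)), if (!is.null(mat)) "MAT"),
    domain = c(dom, if (!is.null(mat)) list(mat_idiomorphs()))
  )
  class(out) <- c("clonering_panel", class(out))
  out
}

#' @rdname locus_panel
#' @export
mat_idiomorphs <- function() c("MAT1-1", "MAT1-2")

# Columns of a genotype table that are never locus columns.
reserved_cols <- function() {
  c("sample_id", "site", "year", "role", "x", "y", "mat",
    "resolved", "mlg_id", "n_ramets", "significant", "p_gen", "p_sex")
}

#' Identify SSR locus columns of a genotype table
#'
#' Locus columns are every column that is not part of the fixed sample
#' schema (`sample_id`, `site`, `year`, `role`, `x`, `y`, `mat`, and the
#' columns added by analysis steps). Pass `loci` explicitly to restrict an
#' analysis to a sub-panel (e.g. when some markers were dropped for one
#' tissue type).
#'
#' @param data A genotype tibble.
#' @param loci Optional character vector naming the SSR locus columns.
#' @return Character vector of locus column names.
#' @export
ssr_loci <- function(data, loci = NULL) {
  if (!is.null(loci)) {
    missing <- setdiff(loci, names(data))
    if (length(missing)) {
      abort(paste0("Locus columns not found: ", paste(missing, collapse = ", ")))
    }
    return(loci)
  }
  setdiff(names(data), reserved_cols())
}

sample_roles <- function() c("gleba", "ascospore", "ecm", "soil")
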