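#' Read a haploid genotype table
#'
#' Reads a delimited text table with one row per georeferenced sample:
#' columns `sample_id`, `site`, `year`, `role` (one of gleba, ascospore,
#' ecm, soil), `x`, `y` (planar metres; may be empty), one integer column
#' per SSR locus and one `mat` column (`MAT1-1`/`MAT1-2`). Rows with any
#' missing SSR allele or a missing mating type are kept but flagged
#' `resolved = FALSE`: only unambiguously resolved genotypes (including the
#' mating type) enter genetic analyses, mirroring the whole-sample
#' exclusion rule used for fragment-analysis data.
#'
#' @param path Path to a delimited text file.
#' @param panel Optional [locus_panel()]. When given, locus columns are
#'   taken from the panel and alleles are checked against any declared
#'   domains; otherwise every non-schema column is treated as an SSR locus.
#' @param missing Character string coding missing calls (default `"NA"`).
#' @param delim Field delimiter (default comma).
#'
#' @return A genotype tibble with a logical `resolved` column and the
#'   panel attached as attribute `"panel"` when supplied.
#' @export
read_genotype_table <- function(path, panel = NULL, missing = "NA", delim = ",") {
  raw <- readr::read_delim(path, delim = delim, na = missing,
                           show_col_types = FALSE, progress = FALSE)
  as_genotype_table(raw, panel = panel)
}

#' Validate and flag an in-memory genotype table
#'
#' @param data A data frame with the genotype-table schema.
#' @inheritParams read_genotype_table
#' @return A genotype tibble with a `resolved` flag.
#' @export
as_genotype_table <- function(data, panel = NULL) {
  need <- c("sample_id", "site", "year", "role", "mat")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Genotype table lacks required columns: ", paste(miss, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    abort(paste0("Duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  bad_role <- setdiff(unique(data$role), sample_roles())
  if (length(bad_role)) {
    abort(paste0("Unknown role label: ", paste(bad_role, collapse = ", ")))
  }
  if (!"x" %in% names(data)) data$x <- NA_real_
  if (!"y" %in% names(data)) data$y <- NA_real_
  data$x <- as.numeric(data$x)
  data$y <- as.numeric(data$y)
  if (any(is.infinite(data$x) | is.infinite(data$y), na.rm = TRUE)) {
    abort("Coordinates must be finite planar metres.")
  }

  loci <- if (!is.null(panel)) panel$locus[panel$kind == "SSR"] else ssr_loci(data)
  miss <- setdiff(loci, names(data))
  if (length(miss)) {
    abort(paste0("Panel locus columns missing from table: ", paste(miss, collapse = ", ")))
  }
  for (l in loci) data[[l]] <- as.integer(data[[l]])

  bad_mat <- !is.na(data$mat) & !data$mat %in% mat_idiomorphs()
  if (any(bad_mat)) {
    abort(paste0("Invalid mating-type idiomorph: ",
                 paste(unique(data$mat[bad_mat]), collapse = ", ")))
  }
  if (!is.null(panel)) {
    for (i in which(panel$kind == "SSR")) {
      dom <- panel$domain[[i]]
      if (is.null(dom)) next
      l <- panel$locus[i]
      out_of_dom <- !is.na(data[[l]]) & !data[[l]] %in% dom
      if (any(out_of_dom)) {
        abort(paste0("Allele outside declared domain at ", l, ": ",
                     paste(unique(data[[l]][out_of_dom]), collapse = ", ")))
      }
    }
  }

  genic <- data[, loci, drop = FALSE]
  data$resolved <- complete.cases(genic) & !is.na(data$mat)
  if (!is.null(panel)) attr(data, "panel") <- panel
  data
}

#' Write a genotype table back to delimited text
#'
#' Inverse of [read_genotype_table()]: round-trips every schema and locus
#' column (the derived `resolved` flag is recomputed on read).
#'
#' @param data A genotype tibble.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(data, path, delim = ",") {
  out <- data[, setdiff(names(data), "resolved"), drop = FALSE]
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Export resolved genotypes in Genepop format
#'
#' Writes a Genepop 4.x haploid file with one `POP` block per site and
#' 3-digit allele codes. The mating-type locus is exported as a pseudo-locus
#' coded `001` (`MAT1-1`) / `002` (`MAT1-2`). Allele fragment sizes that fit
#' in three digits are used verbatim (zero-padded); otherwise alleles are
#' recoded by rank per locus.
#'
#' @param data A genotype tibble (only resolved records are exported).
#' @param path Output file path.
#' @param loci Optional SSR locus subset (default: all locus columns).
#' @param title Title line for the file header.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(data, path, loci = NULL, title = "clonering haploid export") {
  loci <- ssr_loci(data, loci)
  data <- data[data$resolved, , drop = FALSE]
  if (!nrow(data)) abort("No resolved records to export.")

  code_locus <- function(a) {
    lev <- sort(unique(a))
    if (length(lev) > 999) abort("More than 999 distinct alleles at one locus.")
    if (max(lev) <= 999) sprintf("%03d", a) else sprintf("%03d", match(a, lev))
  }
  codes <- vapply(loci, function(l) code_locus(data[[l]]), character(nrow(data)))
  codes <- matrix(codes, nrow = nrow(data))
  mat_code <- sprintf("%03d", match(data$mat, mat_idiomorphs()))
  codes <- cbind(codes, mat_code)

  lines <- c(title, loci, "mat")
  for (s in unique(data$site)) {
    lines <- c(lines, "POP")
    idx <- which(data$site == s)
    lines <- c(lines, paste0(data$sample_id[idx], " ,  ",
                             apply(codes[idx, , drop = FALSE], 1, paste, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Summarise dataset structure and quality
#'
#' Report-only validation: lists unresolved records, duplicated
#' coordinates, loci monomorphic within each site, and per-site sample
#' counts by role and year.
#'
#' @param data A genotype tibble.
#' @param loci Optional SSR locus subset.
#' @return A list of tibbles of class `clonering_validation`:
#'   `unresolved`, `duplicate_coordinates`, `monomorphic_loci`,
#'   `sample_counts`.
#' @export
validate_dataset <- function(data, loci = NULL) {
  loci <- ssr_loci(data, loci)
  empty <- !nrow(data)

  unresolved <- data[!empty & !data$resolved,
                     intersect(c("sample_id", "site", "year", "role"), names(data)),
                     drop = FALSE]

  pos <- data[!is.na(data$x) & !is.na(data$y), , drop = FALSE]
  dup_xy <- pos |>
    dplyr::group_by(.data$site, .data$x, .data$y) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(sample_ids = paste(.data$sample_id, collapse = ";"),
                     n = dplyr::n(), .groups = "drop")

  res <- data[data$resolved, , drop = FALSE]
  mono <- res |>
    tidyr::pivot_longer(dplyr::all_of(loci), names_to = "locus", values_to = "allele") |>
    dplyr::group_by(.data$site, .data$locus) |>
    dplyr::summarise(n_alleles = dplyr::n_distinct(.data$allele), .groups = "drop") |>
    dplyr::filter(.data$n_alleles == 1)

  counts <- data |>
    dplyr::count(.data$site, .data$year, .data$role, name = "n_samples")

  structure(
    list(unresolved = tibble::as_tibble(unresolved),
         duplicate_coordinates = dup_xy,
         monomorphic_loci = mono,
         sample_counts = counts),
    class = "clonering_validation")
}

#' @export
print.clonering_validation <- function(x, ...) {
  cat("Genotype dataset validation\n")
  cat("  unresolved records:     ", nrow(x$unresolved), "\n")
  cat("  duplicate coordinates:  ", nrow(x$duplicate_coordinates), "\n")
  cat("  monomorphic site:locus: ", nrow(x$monomorphic_loci), "\n")
  print(x$sample_counts, ...)
  invisible(x)
}
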