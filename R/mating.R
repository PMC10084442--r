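#' Infer paternal genotypes from pooled ascospore extracts
#'
#' Ascospore DNA extracted from a fruitbody is a mixture of the two
#' parental haploid genomes (pooled post-meiosis spores), so each SSR
#' locus shows one or two alleles. The paternal contribution follows by
#' Mendelian subtraction against the maternal (gleba) genotype: with two
#' alleles the paternal allele is the one differing from the maternal;
#' with a single allele equal to the maternal one, the father carries the
#' same allele. Because the species is heterothallic, the paternal mating
#' type is always the idiomorph opposite to the maternal one. A fruitbody
#' is rejected (contamination or sample mismatch) when any spore allele
#' set lacks the maternal allele or holds more than two alleles.
#'
#' @param gleba Genotype tibble of maternal (gleba) records; matched to
#'   spore profiles by `sample_id`.
#' @param spores Spore-extract tibble: `fruitbody_id` plus one character
#'   column per locus with `"/"`-separated allele labels (e.g. `"152"` or
#'   `"148/152"`).
#' @param loci Optional SSR locus subset.
#' @return A tibble with one row per fruitbody: `fruitbody_id`,
#'   `accepted`, `reason` (`NA` when accepted), the inferred paternal
#'   allele per locus, and paternal `mat`.
#' @export
infer_paternal <- function(gleba, spores, loci = NULL) {
  loci <- ssr_loci(gleba, loci)
  miss <- setdiff(loci, names(spores))
  if (length(miss)) {
    abort(paste0("Spore table lacks loci: ", paste(miss, collapse = ", ")))
  }
  m <- match(spores$fruitbody_id, gleba$sample_id)
  out <- tibble::tibble(fruitbody_id = spores$fruitbody_id,
                        accepted = !is.na(m),
                        reason = ifelse(is.na(m), "no matching gleba record", NA))
  pat <- matrix(NA_integer_, nrow(spores), length(loci),
                dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    l <- loci[j]
    sets <- strsplit(as.character(spores[[l]]), "/", fixed = TRUE)
    for (i in seq_len(nrow(spores))) {
      if (!out$accepted[i]) next
      s <- suppressWarnings(as.integer(sets[[i]]))
      mom <- gleba[[l]][m[i]]
      if (!length(s) || anyNA(s)) {
        out$accepted[i] <- FALSE
        out$reason[i] <- paste0("unreadable spore alleles at ", l)
      } else if (length(unique(s)) > 2) {
        out$accepted[i] <- FALSE
        out$reason[i] <- paste0(">2 alleles at ", l, " (contamination)")
      } else if (!mom %in% s) {
        out$accepted[i] <- FALSE
        out$reason[i] <- paste0("maternal allele absent at ", l)
      } else {
        s <- unique(s)
        pat[i, j] <- if (length(s) == 2) s[s != mom] else mom
      }
    }
  }
  for (j in seq_along(loci)) out[[loci[j]]] <- ifelse(out$accepted, pat[, j], NA)
  out$mat <- ifelse(out$accepted,
                    ifelse(gleba$mat[m] == "MAT1-1", "MAT1-2", "MAT1-1"),
                    NA)
  out
}

#' Assemble zygotes from maternal genotypes and paternal inferences
#'
#' A zygote is the reconstructed diploid of a fruitbody: the maternal
#' haplotype (gleba) paired with the inferred paternal haplotype. Only
#' fruitbodies with an accepted paternal inference are included;
#' unmatched ids are skipped with a message.
#'
#' @param gleba Genotype tibble of maternal records.
#' @param paternal Output of [infer_paternal()].
#' @param loci Optional SSR locus subset.
#' @return A long tibble of class `clonering_zygotes`: `fruitbody_id`,
#'   `locus`, `maternal`, `paternal` allele, plus `mat_maternal`,
#'   `mat_paternal` carried per fruitbody.
#' @export
build_zygotes <- function(gleba, paternal, loci = NULL) {
  loci <- ssr_loci(gleba, loci)
  ok <- paternal[paternal$accepted, , drop = FALSE]
  skipped <- nrow(paternal) - nrow(ok)
  if (skipped) message(skipped, " fruitbodies without accepted paternal inference skipped.")
  m <- match(ok$fruitbody_id, gleba$sample_id)
  mom <- gleba[m, , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    tibble::tibble(
      fruitbody_id = ok$fruitbody_id[i],
      locus = loci,
      maternal = as.integer(unlist(mom[i, loci])),
      paternal = as.integer(unlist(ok[i, loci])),
      mat_maternal = mom$mat[i],
      mat_paternal = ok$mat[i])
  })
  class(out) <- c("clonering_zygotes", class(out))
  out
}

#' Inbreeding coefficient of reconstructed zygotes
#'
#' `F_is = 1 - mean(Ho) / mean(He)` over loci, where observed
#' heterozygosity `Ho` is the fraction of zygotes with two distinct
#' alleles at the locus and expected heterozygosity `He = 1 - sum p^2`
#' comes from the zygote allele pool (two alleles per zygote).
#' Values near 0 indicate random mating; positive values inbreeding
#' (mates more related than random); negative values heterozygote excess.
#' Monomorphic loci contribute 0 to both means.
#'
#' @param zygotes Output of [build_zygotes()].
#' @param unbiased Apply the `2n/(2n - 1)` small-sample correction to `He`
#'   (default `FALSE`, matching the plain ratio-of-means definition).
#' @return A list of class `clonering_fis`: `fis`, `ho` (mean), `he`
#'   (mean), `by_locus` tibble, `n_zygotes`.
#' @export
fis <- function(zygotes, unbiased = FALSE) {
  n_zyg <- dplyr::n_distinct(zygotes$fruitbody_id)
  if (n_zyg < 2) abort("F_is requires at least 2 zygotes.")
  by_locus <- zygotes |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n = dplyr::n(),
      ho = mean(.data$maternal != .data$paternal),
      he = {
        pool <- c(.data$maternal, .data$paternal)
        h <- 1 - sum((table(pool) / length(pool))^2)
        if (unbiased) h * length(pool) / (length(pool) - 1) else h
      },
      .groups = "drop")
  if (all(by_locus$he == 0)) {
    abort("All loci monomorphic in the zygote set; F_is undefined.")
  }
  mh_o <- mean(by_locus$ho)
  mh_e <- mean(by_locus$he)
  structure(list(fis = 1 - mh_o / mh_e, ho = mh_o, he = mh_e,
                 by_locus = by_locus, n_zygotes = n_zyg),
            class = "clonering_fis")
}

#' @export
print.clonering_fis <- function(x, ...) {
  cat(sprintf("F_is = %.3f  (mean Ho = %.3f, mean He = %.3f, %d zygotes)\n",
              x$fis, x$ho, x$he, x$n_zygotes))
  invisible(x)
}

#' @export
glance.clonering_fis <- function(x, ...) {
  tibble::tibble(fis = x$fis, mean_ho = x$ho, mean_he = x$he,
                 n_zygotes = x$n_zygotes, n_loci = nrow(x$by_locus))
}

#' @export
tidy.clonering_fis <- function(x, ...) x$by_locus

#' Detect hermaphroditic MLGs
#'
#' A hermaphrodite is a genet observed acting in both sex roles: maternal
#' (gleba or ECM tissue) and paternal (inferred from ascospore extracts).
#' Reports each such MLG with its role-specific years and overall
#' persistence; the hermaphrodite fraction of all MLGs is available via
#' [glance()].
#'
#' @param data Output of [assign_mlgs()] covering maternal records and
#'   paternal inferences (the latter entered as `role = "ascospore"`
#'   rows).
#' @param significance Optional [p_sex_significance()] output; when given,
#'   only MLGs flagged as significant clones qualify (a hermaphrodite is
#'   necessarily a repeated MLG).
#' @return A tibble of hermaphroditic MLGs with `mlg_id`, `n_ramets`,
#'   `first_year`, `last_year`, `span_years`; attribute `"n_mlgs_total"`.
#' @export
detect_hermaphrodites <- function(data, significance = NULL) {
  stopifnot("mlg_id" %in% names(data))
  n_total <- dplyr::n_distinct(data$mlg_id)
  herm <- data |>
    dplyr::group_by(.data$mlg_id) |>
    dplyr::summarise(
      n_ramets = dplyr::n(),
      maternal = any(.data$role %in% c("gleba", "ecm")),
      paternal = any(.data$role == "ascospore"),
      first_year = min(.data$year),
      last_year = max(.data$year),
      .groups = "drop") |>
    dplyr::filter(.data$maternal & .data$paternal) |>
    dplyr::mutate(span_years = .data$last_year - .data$first_year + 1L) |>
    dplyr::select(-"maternal", -"paternal")
  if (!is.null(significance)) {
    sig_ids <- significance$mlg_id[!is.na(significance$significant) &
                                     significance$significant]
    herm <- herm[herm$mlg_id %in% sig_ids, , drop = FALSE]
  }
  attr(herm, "n_mlgs_total") <- n_total
  class(herm) <- c("clonering_herm", class(herm))
  herm
}

#' @export
glance.clonering_herm <- function(x, ...) {
  n_total <- attr(x, "n_mlgs_total")
  tibble::tibble(n_hermaphrodites = nrow(x), n_mlgs = n_total,
                 percent = 100 * nrow(x) / n_total)
}

#' Interannual persistence of MLGs
#'
#' Per-MLG first and last observation year, span in calendar years
#' (`last - first + 1`), and ramet counts per year and sex role.
#'
#' @param data Output of [assign_mlgs()].
#' @return A tibble with one row per MLG (`mlg_id`, `n_ramets`,
#'   `first_year`, `last_year`, `span_years`); per-year per-role ramet
#'   counts are attached as the attribute `"by_year"` (long tibble).
#' @export
persistence_table <- function(data) {
  stopifnot("mlg_id" %in% names(data))
  out <- data |>
    dplyr::group_by(.data$mlg_id) |>
    dplyr::summarise(n_ramets = dplyr::n(),
                     first_year = min(.data$year),
                     last_year = max(.data$year),
                     .groups = "drop") |>
    dplyr::mutate(span_years = .data$last_year - .data$first_year + 1L)
  attr(out, "by_year") <- dplyr::count(data, .data$mlg_id, .data$year,
                                       .data$role, name = "n")
  out
}
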