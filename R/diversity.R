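#' Genotypic richness R
#'
#' `R = (G - 1)/(N - 1)` where `G` is the number of genets (MLGs) and `N`
#' the number of ramets (samples): 0 when a single clone makes up the
#' whole sample, 1 when every sample is its own genet.
#'
#' @param N Number of ramets (>= 2).
#' @param G Number of MLGs (1 <= G <= N).
#' @return Richness in \[0, 1\].
#' @export
#' @examples
#' genotypic_richness(66, 34)   # 0.508 to 3 d.p.
#' genotypic_richness(205, 2)   # 0.005 to 3 d.p.
genotypic_richness <- function(N, G) {
  stopifnot(all(N >= 2), all(G >= 1), all(G <= N))
  (G - 1) / (N - 1)
}

#' Adapted Simpson genotypic diversity D*
#'
#' Unbiased Simpson index on MLG ramet counts:
#' `D* = 1 - sum n_i (n_i - 1) / (N (N - 1))` — the probability that two
#' samples drawn without replacement belong to different genets. 0 when
#' all samples are one clone, 1 when all are distinct.
#'
#' @param counts Integer vector of ramets per MLG (sum >= 2).
#' @return Diversity in \[0, 1\].
#' @export
#' @examples
#' simpson_diversity(c(3, 1))  # 0.5
simpson_diversity <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 2) abort("Simpson diversity requires at least 2 ramets.")
  1 - sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Simpson evenness ED*
#'
#' Rescales `D*` between its minimum and maximum attainable values at the
#' observed `(N, G)` (a Fager-type correction): the minimum comes from the
#' maximally skewed composition (`G - 1` singletons and one clone of
#' `N - G + 1` ramets), the maximum from the most even composition
#' (counts differing by at most one). 1 means all MLGs occur at equal
#' frequency.
#'
#' @param counts Integer vector of ramets per MLG with `G >= 2` MLGs.
#' @return Evenness in \[0, 1\]; exactly 1 for equal counts. When the
#'   bounds coincide (e.g. all singletons, where only one composition
#'   exists) the index is 1.
#' @export
#' @examples
#' simpson_evenness(c(2, 2, 2))  # 1
simpson_evenness <- function(counts) {
  counts <- counts[counts > 0]
  G <- length(counts)
  if (G < 2) abort("Evenness is undefined for a single MLG.")
  N <- sum(counts)
  d <- simpson_diversity(counts)
  d_min <- simpson_diversity(c(rep(1, G - 1), N - G + 1))
  base <- N %/% G
  even <- c(rep(base + 1, N %% G), rep(base, G - N %% G))
  d_max <- simpson_diversity(even)
  if (d_max == d_min) return(1)
  (d - d_min) / (d_max - d_min)
}

#' Unbiased gene diversity uHe
#'
#' Per-locus `uHe = n/(n - 1) * (1 - sum p_i^2)` (the unbiased expected
#' heterozygosity of the allele-frequency profile), with the mean over
#' loci as the headline value. Conventionally computed on clone-corrected
#' data so a dominant clone does not drown out the allele pool.
#'
#' @param freqs Frequency table from [allele_frequencies()] (carries the
#'   per-locus sample size `n`).
#' @return A tibble with one row per locus (`locus`, `n`, `uHe`) plus the
#'   over-locus mean as attribute `"mean"` and via [glance()].
#' @export
#' @examples
#' gt <- tibble::tibble(sample_id = as.character(1:4), site = "A",
#'                      year = 2019L, role = "gleba", x = 0, y = 0,
#'                      L1 = c(1L, 1L, 2L, 2L), mat = "MAT1-1", resolved = TRUE)
#' unbiased_gene_diversity(allele_frequencies(gt, clone_corrected = FALSE))
unbiased_gene_diversity <- function(freqs) {
  out <- freqs |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n = .data$n[1],
                     uHe = .data$n[1] / (.data$n[1] - 1) * (1 - sum(.data$freq^2)),
                     .groups = "drop")
  if (any(out$n < 2)) abort("uHe requires n >= 2 genotypes per locus.")
  attr(out, "mean") <- mean(out$uHe)
  class(out) <- c("clonering_uhe", class(out))
  out
}

#' @export
glance.clonering_uhe <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x), mean_uHe = attr(x, "mean"))
}

#' Clonal diversity summary per group
#'
#' The site/role-level genotypic-diversity table: sample count `N`, number
#' of genotypic units `G`, richness `R`, Simpson diversity `D*`, evenness
#' `ED*`, mean unbiased gene diversity `uHe` (clone-corrected), and the
#' site-level clonal subrange (largest subrange over MLGs). Significant
#' MLGs count as one genotypic unit; each ramet of a non-significant
#' repeated MLG counts as its own unit, consistent with treating those
#' repeats as chance identity.
#'
#' @param data Output of [assign_mlgs()].
#' @param significance Output of [p_sex_significance()], or `NULL` to
#'   treat every repeated MLG as significant.
#' @param loci Optional SSR locus subset.
#' @param group Optional column name(s) to summarise by (e.g. `"role"`,
#'   `c("site", "role")`).
#' @return A tibble with columns `N`, `G`, `R`, `D_star`, `ED_star`,
#'   `uHe`, `subrange` (one row per group).
#' @export
diversity_summary <- function(data, significance = NULL, loci = NULL, group = NULL) {
  loci <- ssr_loci(data, loci)
  if (!"mlg_id" %in% names(data)) data <- assign_mlgs(data, loci)
  if (is.null(significance)) {
    significance <- data |>
      dplyr::count(.data$mlg_id, name = "n_ramets") |>
      dplyr::mutate(significant = ifelse(.data$n_ramets >= 2, TRUE, NA))
  }
  data <- dplyr::left_join(data, significance[, c("mlg_id", "significant")],
                           by = "mlg_id")
  one_group <- function(d) {
    # genotypic units: significant MLG -> 1 unit (its ramets pooled);
    # everything else -> one unit per ramet
    sig <- !is.na(d$significant) & d$significant
    unit <- ifelse(sig, d$mlg_id, paste0(d$mlg_id, ".", seq_len(nrow(d))))
    counts <- as.integer(table(unit))
    N <- nrow(d)
    G <- length(counts)
    uhe <- tryCatch({
      cc <- clone_correct(d, NULL)
      glance(unbiased_gene_diversity(
        allele_frequencies(cc, loci, clone_corrected = FALSE)))$mean_uHe
    }, error = function(e) NA_real_)
    sub <- d |>
      dplyr::group_by(.data$mlg_id) |>
      dplyr::summarise(s = clonal_subrange(.data$x, .data$y), .groups = "drop")
    tibble::tibble(
      N = N, G = G,
      R = if (N >= 2) genotypic_richness(N, G) else NA_real_,
      D_star = if (N >= 2) simpson_diversity(counts) else NA_real_,
      ED_star = if (G >= 2) simpson_evenness(counts) else NA_real_,
      uHe = uhe,
      subrange = max(sub$s))
  }
  if (is.null(group)) return(one_group(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup()
}
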